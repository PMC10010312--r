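#' Construct an ExpressionMatrix
#'
#' @param values numeric gene x sample matrix with rownames (gene IDs) and
#'   colnames (sample IDs).
#' @param layer `"counts"` for raw counts, `"log_normalized"` for the
#'   normalized log2 layer produced by [normalizeExpression()].
#' @return an [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(rpois(20, 10), nrow = 5,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' em <- ExpressionMatrix(m, layer = "counts")
#' exprLayer(em)
#' @export
ExpressionMatrix <- function(values, layer = c("counts", "log_normalized")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry gene rownames and sample colnames")
  se <- SummarizedExperiment(assays = SimpleList(expr = values))
  new("ExpressionMatrix", se, layer = layer)
}

#' @rdname ExpressionMatrix-class
#' @aliases exprLayer exprValues geneIds sampleIds
#' @export
setMethod("exprLayer", "ExpressionMatrix", function(x) x@layer)

#' @rdname ExpressionMatrix-class
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) assay(x, "expr"))

#' @rdname ExpressionMatrix-class
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x))

#' @rdname ExpressionMatrix-class
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x))

setMethod("show", "ExpressionMatrix", function(object) {
  cat("ExpressionMatrix:", nrow(object), "genes x", ncol(object),
      "samples [layer:", paste0(object@layer, "]\n"))
})

.assert_layer <- function(m, layer, what) {
  if (!is(m, "ExpressionMatrix"))
    stop(what, " expects an ExpressionMatrix")
  if (!identical(exprLayer(m), layer))
    stop(what, " requires the '", layer, "' layer, got '", exprLayer(m), "'")
  invisible(m)
}

#' Read / write the gene x sample TSV dialect
#'
#' Tab-separated text with the gene identifier in the first column and one
#' column per sample; the header row carries sample identifiers.
#'
#' @param path file path.
#' @param layer layer tag of the values in the file.
#' @return `readExpressionTSV` returns an [ExpressionMatrix-class];
#'   `writeExpressionTSV` returns `path` invisibly.
#' @export
readExpressionTSV <- function(path, layer = c("counts", "log_normalized")) {
  layer <- match.arg(layer)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  ExpressionMatrix(m, layer = layer)
}

#' @rdname readExpressionTSV
#' @param m an [ExpressionMatrix-class].
#' @export
writeExpressionTSV <- function(m, path) {
  v <- exprValues(m)
  df <- data.frame(gene_id = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
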