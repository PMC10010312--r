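#' Filter genes by minimum expression count
#'
#' Retains genes with at least `min_count` reads in at least `min_samples`
#' samples (defaults 10 reads / 5 samples), the standard low-expression
#' filter applied before normalization.
#'
#' @param m an [ExpressionMatrix-class] on the counts layer.
#' @param min_count minimum read count.
#' @param min_samples minimum number of samples reaching `min_count`.
#' @return list with `expression` (filtered counts) and `report` (list with
#'   `n_genes_in`, `n_genes_out`, `removed_gene_ids`).
#' @export
filterMinExpression <- function(m, min_count = 10, min_samples = 5) {
  .assert_layer(m, "counts", "filterMinExpression")
  v <- exprValues(m)
  keep <- rowSums(v >= min_count) >= min_samples
  if (!any(keep)) stop("no gene passes the minimum-expression filter")
  report <- list(n_genes_in = nrow(v), n_genes_out = sum(keep),
                 removed_gene_ids = rownames(v)[!keep])
  list(expression = ExpressionMatrix(v[keep, , drop = FALSE], "counts"),
       report = report)
}

#' Restrict the gene universe to an allowed list
#'
#' Intersects the matrix genes with an explicit allowed list (e.g. Ensembl
#' protein-coding identifiers supplied as a one-ID-per-line file), preserving
#' matrix order. Works on either layer.
#'
#' @param m an [ExpressionMatrix-class].
#' @param allowed_genes non-empty character vector of permitted gene IDs.
#' @return list with `expression` and `report` as in [filterMinExpression()].
#' @export
restrictGeneUniverse <- function(m, allowed_genes) {
  stopifnot(is(m, "ExpressionMatrix"))
  if (length(allowed_genes) == 0L) stop("'allowed_genes' is empty")
  keep <- geneIds(m) %in% allowed_genes
  if (!any(keep))
    stop("no overlap between matrix genes and the allowed gene list")
  v <- exprValues(m)
  report <- list(n_genes_in = nrow(v), n_genes_out = sum(keep),
                 removed_gene_ids = rownames(v)[!keep])
  list(expression = ExpressionMatrix(v[keep, , drop = FALSE],
                                     layer = exprLayer(m)),
       report = report)
}

#' Log-transform, upper-quartile scale and median-center an expression matrix
#'
#' The canonical normalization applied before every downstream analysis:
#'
#' 1. `v = log2(1 + count)`;
#' 2. per-sample upper-quartile scaling: each sample's values are divided by
#'    that sample's 75th percentile of `v` over genes with `v > 0` (linear
#'    interpolation, [stats::quantile()] type 7) and multiplied by the global
#'    mean of those percentiles, making scales comparable across samples;
#' 3. per-gene median centering: each gene's across-sample median is
#'    subtracted, so every gene's median is 0 afterwards.
#'
#' Scaling precedes centering: centering first would destroy the zero-median
#' property of the output.
#'
#' @param m an [ExpressionMatrix-class] on the counts layer with at least two
#'   samples.
#' @return an [ExpressionMatrix-class] on the `log_normalized` layer.
#' @export
normalizeExpression <- function(m) {
  .assert_layer(m, "counts", "normalizeExpression")
  if (ncol(m) < 2L) stop("normalization requires at least 2 samples")
  v <- log2(1 + exprValues(m))
  zero_samples <- colSums(v > 0) == 0L
  if (any(zero_samples))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(v)[zero_samples], collapse = ", "))
  uq <- vapply(seq_len(ncol(v)), function(j) {
    x <- v[, j]
    stats::quantile(x[x > 0], 0.75, names = FALSE, type = 7)
  }, numeric(1))
  v <- sweep(v, 2, mean(uq) / uq, `*`)
  med <- apply(v, 1, stats::median)
  v <- v - med
  ExpressionMatrix(v, layer = "log_normalized")
}
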