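#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of gene identifiers.
#'   Duplicates within a set are collapsed (first occurrence kept).
#' @param provenance optional named character vector of free-text provenance,
#'   one entry per set; defaults to empty strings.
#' @return a [GeneSetCollection-class].
#' @export
GeneSetCollection <- function(sets, provenance = NULL) {
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(provenance)) {
    provenance <- rep("", length(sets))
    names(provenance) <- names(sets)
  }
  new("GeneSetCollection", sets = sets,
      provenance = provenance[names(sets)])
}

#' @rdname GeneSetCollection-class
#' @aliases geneSets
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname GeneSetCollection-class
#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' @rdname GeneSetCollection-class
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @rdname GeneSetCollection-class
#' @param i set name or index.
#' @export
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

setMethod("show", "GeneSetCollection", function(object) {
  sizes <- vapply(object@sets, length, integer(1))
  cat("GeneSetCollection:", length(object@sets), "sets,",
      "sizes", min(sizes), "-", max(sizes), "\n")
})

#' Read / write GMT gene-set files
#'
#' Standard tab-separated GMT: set name, description, then gene identifiers.
#' Reading goes through [fgsea::gmtPathways()]; descriptions read that way
#' are not retained (GMT descriptions are free text, stored in `provenance`
#' on write).
#'
#' @param path file path.
#' @return `readGMT` returns a [GeneSetCollection-class]; `writeGMT` returns
#'   `path` invisibly.
#' @export
readGMT <- function(path) {
  GeneSetCollection(fgsea::gmtPathways(path))
}

#' @rdname readGMT
#' @param collection a [GeneSetCollection-class].
#' @export
writeGMT <- function(collection, path) {
  stopifnot(is(collection, "GeneSetCollection"))
  prov <- collection@provenance
  prov[!nzchar(prov)] <- "na"
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, gsub("\t", " ", prov[[nm]]), collection[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Default single-gene immune marker signatures
#'
#' The packaged default collection of 40 immune marker genes scored in the
#' renal-cancer immunotherapy analysis: 28 singleton sets for individual
#' checkpoint, IL2-receptor, chemokine, interferon-response and T-cell
#' activation markers, plus one 12-gene type I interferon set. Multi-gene
#' immune cell-type signatures (Charoentong/Bindea-style) are not shipped
#' because their memberships are user-supplied; provide them as GMT input.
#'
#' @return a [GeneSetCollection-class] with 29 sets covering 40 genes.
#' @export
defaultImmuneSignatures <- function() {
  singletons <- c(
    "CD274", "PDCD1", "PDCD1LG2", "CTLA4", "IL2RA", "IL2RB", "IL2RG",
    "CXCL9", "CXCL10", "IFI27", "IFIT1", "IFIT2", "IFIT3", "MX1", "MX2",
    "OAS2", "STAT1", "STAT2", "STAT3", "STAT4", "STAT5A", "TBX21",
    "ITGA1", "ITGAE", "CD28", "TNFRSF9", "CD40", "NFAT5"
  )
  type1_ifn <- c("IFNA14", "IFNA13", "IFNA6", "IFNA7", "IFNA5", "IFNA4",
                 "IFNA1", "IFNA2", "IFNA16", "IFNAB1", "IFNK", "IL6")
  sets <- c(as.list(setNames(singletons, singletons)),
            list(Type_I_IFN = type1_ifn))
  prov <- setNames(c(rep("single-gene immune marker", length(singletons)),
                     "type I interferon gene family"), names(sets))
  GeneSetCollection(sets, provenance = prov)
}
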