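#' Score gene-set signatures per sample
#'
#' The signature score of a sample is the unweighted arithmetic mean of the
#' normalized expression values of the set's genes present in the matrix.
#' Genes absent from the matrix are dropped from their set (the drop fraction
#' is reported via a warning and the `dropped` attribute); sets with no gene
#' present are removed with a warning.
#'
#' @param norm an [ExpressionMatrix-class] on the `log_normalized` layer.
#' @param collection a [GeneSetCollection-class].
#' @return a [SignatureScores-class] (signatures x samples). Attribute
#'   `dropped` maps each scored set to its number of absent genes.
#' @export
scoreSignatures <- function(norm, collection) {
  .assert_layer(norm, "log_normalized", "scoreSignatures")
  stopifnot(is(collection, "GeneSetCollection"))
  v <- exprValues(norm)
  present <- lapply(geneSets(collection), intersect, y = rownames(v))
  n_present <- lengths(present)
  if (all(n_present == 0L))
    stop("no gene of any set is present in the matrix")
  if (any(n_present == 0L))
    warning("dropping set(s) with no gene in the matrix: ",
            paste(names(present)[n_present == 0L], collapse = ", "))
  dropped <- lengths(geneSets(collection)) - n_present
  present <- present[n_present > 0L]
  s <- t(vapply(present,
                function(g) colMeans(v[g, , drop = FALSE]),
                numeric(ncol(v))))
  rownames(s) <- names(present)
  out <- new("SignatureScores", scores = s)
  attr(out, "dropped") <- dropped[n_present > 0L]
  out
}

#' @rdname SignatureScores-class
#' @aliases scores
#' @export
setMethod("scores", "SignatureScores", function(x) x@scores)

setMethod("show", "SignatureScores", function(object) {
  cat("SignatureScores:", nrow(object@scores), "signatures x",
      ncol(object@scores), "samples\n")
})

.wilcox_two_sample <- function(x, y) {
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- length(x) <= 10L && length(y) <= 10L && !ties
  w <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(w$statistic), p = w$p.value, exact = exact)
}

.pooled_t <- function(x, y, s0 = 0) {
  n1 <- length(x); n2 <- length(y)
  sp <- sqrt((sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2))
  (mean(x) - mean(y)) / (sp * sqrt(1 / n1 + 1 / n2) + s0)
}

#' Compare signature scores between responders and non-responders
#'
#' Per signature: a two-sided Wilcoxon rank-sum test (exact enumeration when
#' both groups have at most 10 samples and the data are untied; otherwise
#' the normal approximation with tie correction and continuity correction),
#' a two-sample pooled-variance t statistic with the convention positive =
#' higher in responders, and the responder-minus-nonresponder mean
#' difference. A display flag marks signatures with p < 0.05, the threshold
#' used when annotating comparison plots.
#'
#' @param sig_scores a [SignatureScores-class].
#' @param labels logical (TRUE = responder) or two-level factor per sample,
#'   in the score matrix's sample order; the first factor level is treated
#'   as the responder group.
#' @return data.frame with one row per signature: `signature`, `n_responder`,
#'   `n_nonresponder`, `wilcoxon_statistic`, `wilcoxon_p`, `exact`,
#'   `t_statistic`, `mean_difference`, `display`.
#' @export
compareGroups <- function(sig_scores, labels) {
  stopifnot(is(sig_scores, "SignatureScores"))
  s <- scores(sig_scores)
  if (is.factor(labels) || is.character(labels)) {
    labels <- factor(labels)
    if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
    labels <- labels == levels(labels)[1]
  }
  labels <- as.logical(labels)
  if (length(labels) != ncol(s))
    stop("one label per sample required")
  if (anyNA(labels)) stop("labels must not be missing")
  if (!any(labels) || all(labels)) stop("both groups must be non-empty")
  rows <- lapply(rownames(s), function(nm) {
    x <- s[nm, labels]; y <- s[nm, !labels]
    w <- .wilcox_two_sample(x, y)
    data.frame(signature = nm,
               n_responder = length(x), n_nonresponder = length(y),
               wilcoxon_statistic = w$statistic, wilcoxon_p = w$p,
               exact = w$exact,
               t_statistic = .pooled_t(x, y),
               mean_difference = mean(x) - mean(y),
               display = w$p < 0.05,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Quadrant labels for the T-effector / myeloid signature scatter
#'
#' Dichotomizes each sample's T-effector and myeloid-inflammation scores at
#' the cohort threshold (default: per-cohort median; scores equal to the
#' threshold count as HIGH) and emits the scatter table underlying the
#' Teff/Myeloid quadrant analysis.
#'
#' @param sig_scores a [SignatureScores-class].
#' @param teff_name,myeloid_name signature names present in `sig_scores`.
#' @param response optional per-sample response annotation carried through.
#' @param threshold `"median"` or a named numeric vector
#'   `c(teff = ..., myeloid = ...)`.
#' @return data.frame: `sample_id`, `teff`, `myeloid`, `response`,
#'   `quadrant` (one of `Teff_HIGH/Myeloid_HIGH`, `Teff_HIGH/Myeloid_LOW`,
#'   `Teff_LOW/Myeloid_HIGH`, `Teff_LOW/Myeloid_LOW`).
#' @export
teffMyeloidQuadrants <- function(sig_scores, teff_name = "teff",
                                 myeloid_name = "myeloid",
                                 response = NULL, threshold = "median") {
  stopifnot(is(sig_scores, "SignatureScores"))
  s <- scores(sig_scores)
  missing_sig <- setdiff(c(teff_name, myeloid_name), rownames(s))
  if (length(missing_sig))
    stop("signature(s) not found: ", paste(missing_sig, collapse = ", "))
  teff <- s[teff_name, ]; mye <- s[myeloid_name, ]
  if (identical(threshold, "median")) {
    thr <- c(teff = stats::median(teff), myeloid = stats::median(mye))
  } else thr <- threshold[c("teff", "myeloid")]
  t_high <- teff >= thr["teff"]; m_high <- mye >= thr["myeloid"]
  quadrant <- paste0("Teff_", ifelse(t_high, "HIGH", "LOW"),
                     "/Myeloid_", ifelse(m_high, "HIGH", "LOW"))
  data.frame(sample_id = colnames(s), teff = teff, myeloid = mye,
             response = if (is.null(response)) NA else response,
             quadrant = quadrant, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Hypergeometric overrepresentation analysis
#'
#' One-sided hypergeometric upper-tail test of the overlap between a query
#' gene list and every set of a collection within a stated gene universe,
#' with Benjamini-Hochberg adjustment across sets. Query genes outside the
#' universe are dropped with a warning; set membership is counted within the
#' universe.
#'
#' @param query_genes character vector of query gene IDs.
#' @param collection a [GeneSetCollection-class].
#' @param universe character vector, the gene universe.
#' @return data.frame sorted by raw p: `set_name`, `overlap_count`,
#'   `set_size`, `query_size`, `universe_size`, `p_hypergeometric`,
#'   `p_adjusted`.
#' @export
overrepresentation <- function(query_genes, collection, universe) {
  stopifnot(is(collection, "GeneSetCollection"))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty gene universe")
  query_genes <- unique(as.character(query_genes))
  outside <- setdiff(query_genes, universe)
  if (length(outside))
    warning("dropping ", length(outside), " query gene(s) outside the universe")
  query <- intersect(query_genes, universe)
  n <- length(query); N <- length(universe)
  rows <- lapply(names(collection), function(nm) {
    set_in_universe <- intersect(collection[[nm]], universe)
    K <- length(set_in_universe)
    k <- length(intersect(set_in_universe, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, overlap_count = k, set_size = K,
               query_size = n, universe_size = N, p_hypergeometric = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_hypergeometric, method = "BH")
  out[order(out$p_hypergeometric), , drop = FALSE]
}
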