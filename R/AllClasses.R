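#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
#' @importFrom stats setNames predict
NULL

#' Gene-by-sample expression matrix with a layer tag
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single gene x sample assay together with a `layer` tag stating whether the
#' values are raw counts or normalized log2 expression. The counts layer is
#' validated to contain non-negative whole numbers; gene and sample
#' identifiers must be unique.
#'
#' @slot layer character, either `"counts"` or `"log_normalized"`.
#' @export
setClass("ExpressionMatrix",
  contains = "SummarizedExperiment",
  representation(layer = "character")
)

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (length(object@layer) != 1L ||
      !object@layer %in% c("counts", "log_normalized"))
    msg <- c(msg, "layer must be 'counts' or 'log_normalized'")
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msg <- c(msg, "gene and sample identifiers are required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate gene identifiers")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample identifiers")
  if (length(assays(object)) != 1L)
    msg <- c(msg, "exactly one assay expected")
  v <- assay(object)
  if (!is.numeric(v)) msg <- c(msg, "assay must be numeric")
  if (identical(object@layer, "counts") && is.numeric(v)) {
    if (any(v < 0) || any(v != round(v)))
      msg <- c(msg, "counts layer must hold non-negative integers")
  }
  if (length(msg)) msg else TRUE
})

#' Per-sample clinical annotation table
#'
#' A [S4Vectors::DataFrame] subclass with one row per sample carrying best
#' response (`CR`, `PR`, `SD`, `PD` or `NA`), the clinical-benefit flag
#' (complete/partial response or stable disease lasting at least six months),
#' and right-censored overall and progression-free survival endpoints.
#'
#' @export
setClass("ClinicalTable", contains = "DFrame")

.clinical_cols <- c("sample_id", "best_response", "clinical_benefit",
                    "os_months", "os_event", "pfs_months", "pfs_event")

setValidity("ClinicalTable", function(object) {
  msg <- character()
  missing_cols <- setdiff(.clinical_cols, colnames(object))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(object$sample_id))
    msg <- c(msg, "duplicate sample_id")
  br <- object$best_response
  if (!all(br %in% c("CR", "PR", "SD", "PD") | is.na(br)))
    msg <- c(msg, "best_response must be CR, PR, SD, PD or NA")
  for (col in c("os_months", "pfs_months")) {
    x <- object[[col]]
    if (!is.numeric(x) || any(x < 0, na.rm = TRUE))
      msg <- c(msg, paste(col, "must be non-negative"))
  }
  for (col in c("os_event", "pfs_event")) {
    if (!is.logical(object[[col]]))
      msg <- c(msg, paste(col, "must be logical"))
  }
  if (!is.logical(object$clinical_benefit))
    msg <- c(msg, "clinical_benefit must be logical (NA allowed)")
  bad <- !is.na(object$clinical_benefit) & object$clinical_benefit &
    (is.na(br) | !br %in% c("CR", "PR", "SD"))
  if (any(bad))
    msg <- c(msg, "clinical_benefit TRUE requires best_response CR, PR or SD")
  if (length(msg)) msg else TRUE
})

#' Named gene-set collection
#'
#' Named lists of gene identifiers (immune cell-type signatures, the
#' T-effector and myeloid-inflammation programs, subtype gene lists) with
#' free-text provenance per set. Duplicate genes within a set are collapsed;
#' empty sets are rejected.
#'
#' @slot sets named list of character vectors.
#' @slot provenance named character vector, one entry per set.
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", provenance = "character")
)

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (length(object@sets) == 0L) msg <- c(msg, "collection is empty")
  if (is.null(names(object@sets)) || any(!nzchar(names(object@sets))))
    msg <- c(msg, "every set must be named")
  if (anyDuplicated(names(object@sets)))
    msg <- c(msg, "duplicate set names")
  if (!all(vapply(object@sets, is.character, logical(1))))
    msg <- c(msg, "gene identifiers must be character")
  if (any(vapply(object@sets, length, integer(1)) == 0L))
    msg <- c(msg, "empty gene set")
  if (length(object@provenance) != length(object@sets))
    msg <- c(msg, "provenance length must match number of sets")
  if (length(msg)) msg else TRUE
})

#' Per-sample signature score matrix
#'
#' Signatures x samples matrix of mean-expression signature scores, as
#' produced by [scoreSignatures()]. All scores are finite.
#'
#' @slot scores numeric matrix, signatures in rows, samples in columns.
#' @export
setClass("SignatureScores", representation(scores = "matrix"))

setValidity("SignatureScores", function(object) {
  s <- object@scores
  msg <- character()
  if (!is.numeric(s)) msg <- c(msg, "scores must be numeric")
  if (is.null(rownames(s)) || is.null(colnames(s)))
    msg <- c(msg, "signature and sample names are required")
  if (anyDuplicated(rownames(s)) || anyDuplicated(colnames(s)))
    msg <- c(msg, "duplicate signature or sample names")
  if (is.numeric(s) && !all(is.finite(s)))
    msg <- c(msg, "scores must be finite")
  if (length(msg)) msg else TRUE
})

#' Nearest-centroid classifier model
#'
#' A fitted nearest-centroid model: the selected genes, per-class centroid
#' means, per-gene pooled within-class standard deviations, the standard
#' deviation offset `s0` stabilising the standardized distance, the distance
#' kind, and (when produced by cross-validated training) the CV trace of
#' accuracy against gene-count.
#'
#' @slot selected_genes ordered character vector of model genes.
#' @slot class_labels character vector of class names; ties in prediction are
#'   broken toward the first.
#' @slot centroids numeric matrix, classes x genes.
#' @slot pooled_sd per-gene pooled within-class standard deviation.
#' @slot s0 non-negative standard deviation offset added to every pooled SD.
#' @slot distance_kind `"standardized"` or `"euclidean"`.
#' @slot cv_trace data.frame with columns `n_genes`, `cv_accuracy` (may have
#'   zero rows for directly fitted models).
#' @slot chosen_n_genes integer, equals `length(selected_genes)`.
#' @export
setClass("CentroidModel",
  representation(
    selected_genes = "character",
    class_labels = "character",
    centroids = "matrix",
    pooled_sd = "numeric",
    s0 = "numeric",
    distance_kind = "character",
    cv_trace = "data.frame",
    chosen_n_genes = "integer"
  )
)

setValidity("CentroidModel", function(object) {
  msg <- character()
  g <- object@selected_genes
  if (!identical(colnames(object@centroids), g))
    msg <- c(msg, "centroid columns must match selected_genes")
  if (!identical(rownames(object@centroids), object@class_labels))
    msg <- c(msg, "centroid rows must match class_labels")
  if (length(object@class_labels) < 2L)
    msg <- c(msg, "at least two classes required")
  if (length(object@pooled_sd) != length(g))
    msg <- c(msg, "pooled_sd must have one value per gene")
  if (any(object@pooled_sd + object@s0 <= 0))
    msg <- c(msg, "pooled_sd + s0 must be positive for every gene")
  if (length(object@s0) != 1L || object@s0 < 0)
    msg <- c(msg, "s0 must be a single non-negative value")
  if (!object@distance_kind %in% c("standardized", "euclidean"))
    msg <- c(msg, "distance_kind must be 'standardized' or 'euclidean'")
  if (object@chosen_n_genes != length(g))
    msg <- c(msg, "chosen_n_genes must equal length(selected_genes)")
  if (nrow(object@cv_trace) &&
      !all(c("n_genes", "cv_accuracy") %in% colnames(object@cv_trace)))
    msg <- c(msg, "cv_trace needs n_genes and cv_accuracy columns")
  if (length(msg)) msg else TRUE
})

#' Simulation configuration for synthetic immunotherapy cohorts
#'
#' Parameters of the negative-binomial cohort generator: cohort size, gene
#' universe, responder fraction, planted expression programs (name, size,
#' log2 effect in responders), the log-normal distribution of per-gene
#' baseline means, NB dispersion, and the survival model (exponential
#' baseline, immune-high log hazard ratio, censoring rate).
#'
#' @export
setClass("SimConfig",
  representation(
    n_samples = "integer",
    n_genes = "integer",
    responder_fraction = "numeric",
    program_specs = "list",
    baseline_log_mean = "numeric",
    dispersion = "numeric",
    survival_spec = "numeric",
    weibull_shape = "numeric",
    cr_fraction = "numeric",
    sd_fraction = "numeric",
    sd_benefit_fraction = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@n_samples < 1L) msg <- c(msg, "n_samples must be positive")
  if (object@n_genes < 1L) msg <- c(msg, "n_genes must be positive")
  rf <- object@responder_fraction
  if (rf <= 0 || rf >= 1)
    msg <- c(msg, "responder_fraction must lie in (0, 1)")
  if (object@dispersion <= 0) msg <- c(msg, "dispersion must be positive")
  if (length(object@baseline_log_mean) != 2L ||
      object@baseline_log_mean[2] <= 0)
    msg <- c(msg, "baseline_log_mean must be (mu, sigma) with sigma > 0")
  sv <- object@survival_spec
  if (length(sv) != 3L || sv[1] <= 0 || sv[3] < 0 || sv[3] > 1)
    msg <- c(msg, paste("survival_spec must be (baseline_median_months,",
                        "log_hazard_ratio, censoring_rate in [0,1])"))
  for (p in object@program_specs) {
    if (!is.list(p) || !all(c("name", "n_genes", "effect") %in% names(p))) {
      msg <- c(msg, "each program spec needs name, n_genes, effect")
      next
    }
    if (p$n_genes < 1L || p$n_genes > object@n_genes)
      msg <- c(msg, paste0("program '", p$name,
                           "' larger than the gene universe"))
  }
  total <- sum(vapply(object@program_specs,
                      function(p) as.integer(p$n_genes %||% 0L), integer(1)))
  if (total > object@n_genes)
    msg <- c(msg, "program genes exceed the gene universe")
  if (object@weibull_shape <= 0) msg <- c(msg, "weibull_shape must be positive")
  for (f in c("cr_fraction", "sd_fraction", "sd_benefit_fraction")) {
    x <- slot(object, f)
    if (x < 0 || x > 1) msg <- c(msg, paste(f, "must lie in [0, 1]"))
  }
  if (length(msg)) msg else TRUE
})

#' Planted ground truth of a synthetic cohort
#'
#' Records what the generator planted: per-sample responder labels, the gene
#' list of every expression program, the realized log2 effects, and the
#' immune-high flag (top half of samples by planted-program score) used by
#' the survival model.
#'
#' @export
setClass("SimTruth",
  representation(
    responder_labels = "logical",
    program_genes = "list",
    realized_effects = "numeric",
    immune_high = "logical"
  )
)

setValidity("SimTruth", function(object) {
  msg <- character()
  if (length(object@immune_high) != length(object@responder_labels))
    msg <- c(msg, "immune_high and responder_labels lengths differ")
  if (!identical(names(object@program_genes), names(object@realized_effects)))
    msg <- c(msg, "program_genes and realized_effects names differ")
  if (length(msg)) msg else TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a
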