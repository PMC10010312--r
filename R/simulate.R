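#' Construct a simulation configuration
#'
#' Defaults emulate the shape of a retrospective high-dose IL2 renal-cancer
#' cohort: 35 evaluable samples, 37% objective responders split CR:PR = 1:12,
#' non-responders split SD:PD = 6:16, a 2,000-gene universe with
#' negative-binomial counts (log-normal baseline means, dispersion 0.15), a
#' planted immune program of 40 genes at 1.0 log2-unit effect in responders
#' (20 elevated, 20 depleted), and exponential survival (median 30 months)
#' in which immune-high tumors carry a hazard ratio of 2 with 20% independent
#' censoring.
#'
#' @param n_samples cohort size.
#' @param n_genes size of the gene universe.
#' @param responder_fraction fraction of samples assigned CR/PR, in (0, 1).
#' @param program_specs list of planted expression programs; each element is
#'   a list with `name`, `n_genes`, `effect` (log2 fold change in
#'   responders). Program gene lists are disjoint and drawn from genes above
#'   the 25th percentile of baseline mean (signature genes are expressed
#'   genes).
#' @param baseline_log_mean `(mu, sigma)` of per-gene baseline means on the
#'   log2 scale.
#' @param dispersion negative-binomial dispersion `phi` (> 0), with
#'   `var = mu + phi * mu^2`.
#' @param survival_spec `(baseline_median_months, log_hazard_ratio_for_immune_high,
#'   censoring_rate in [0,1])`.
#' @param weibull_shape Weibull shape of the survival baseline; 1 (default)
#'   gives the exponential model.
#' @param cr_fraction fraction of responders labelled CR (rest PR).
#' @param sd_fraction fraction of non-responders labelled SD (rest PD).
#' @param sd_benefit_fraction fraction of SD patients whose stable disease
#'   lasts at least six months and therefore counts as clinical benefit.
#' @param seed integer seed; identical configurations give identical cohorts.
#' @return a [SimConfig-class].
#' @export
SimConfig <- function(n_samples = 35L,
                      n_genes = 2000L,
                      responder_fraction = 0.37,
                      program_specs = list(
                        list(name = "immune_up", n_genes = 20L, effect = 1),
                        list(name = "immune_down", n_genes = 20L, effect = -1)
                      ),
                      baseline_log_mean = c(mu = 5, sigma = 2),
                      dispersion = 0.15,
                      survival_spec = c(baseline_median_months = 30,
                                        log_hazard_ratio = log(2),
                                        censoring_rate = 0.2),
                      weibull_shape = 1,
                      cr_fraction = 1 / 13,
                      sd_fraction = 6 / 22,
                      sd_benefit_fraction = 2 / 6,
                      seed = 1L) {
  new("SimConfig",
      n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
      responder_fraction = responder_fraction,
      program_specs = program_specs,
      baseline_log_mean = unname(baseline_log_mean),
      dispersion = dispersion,
      survival_spec = unname(survival_spec),
      weibull_shape = weibull_shape,
      cr_fraction = cr_fraction, sd_fraction = sd_fraction,
      sd_benefit_fraction = sd_benefit_fraction,
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@n_samples, "samples,", object@n_genes, "genes,",
      sprintf("%.0f%% responders,", 100 * object@responder_fraction),
      length(object@program_specs), "planted program(s), seed",
      object@seed, "\n")
})

#' @rdname SimTruth-class
#' @aliases responderLabels programGenes immuneHigh
#' @export
setMethod("responderLabels", "SimTruth", function(x) x@responder_labels)

#' @rdname SimTruth-class
#' @export
setMethod("programGenes", "SimTruth", function(x) x@program_genes)

#' @rdname SimTruth-class
#' @export
setMethod("immuneHigh", "SimTruth", function(x) x@immune_high)

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", length(object@responder_labels), "samples,",
      sum(object@responder_labels), "responders; programs:",
      paste(sprintf("%s(%d genes, %.2g)", names(object@program_genes),
                    lengths(object@program_genes), object@realized_effects),
            collapse = ", "), "\n")
})

# run expr under a private RNG stream seeded from `seed`, restoring the
# caller's stream afterwards
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# event/censoring draws on the cumulative-hazard scale: H(t) = (t/b)^k * exp(lp).
# With censoring exponential on the same scale at rate c/(1-c), each sample is
# censored before its event with probability exactly `censoring_rate`.
.draw_weibull_ph <- function(n, median_months, shape, lp) {
  b <- median_months / log(2)^(1 / shape)
  e <- stats::rexp(n)
  b * (e / exp(lp))^(1 / shape)
}

#' Simulate a synthetic immunotherapy cohort
#'
#' Draws a paired expression + clinical cohort with the statistical structure
#' the downstream analysis assumes: negative-binomial counts with
#' gene-specific log-normal means, planted expression programs whose means
#' are shifted by `2^effect` in responders, best response assigned
#' deterministically from the responder labels (CR/PR for responders, SD/PD
#' otherwise), and right-censored OS/PFS from a proportional-hazards Weibull
#' model (exponential by default) in which the immune-high half of the
#' cohort — the top half of samples by planted-program score — carries the
#' configured log hazard ratio.
#'
#' @param config a [SimConfig-class].
#' @return list with elements `expression` ([ExpressionMatrix-class], counts
#'   layer), `clinical` ([ClinicalTable-class]) and `truth`
#'   ([SimTruth-class]).
#' @examples
#' cohort <- simulateCohort(SimConfig(n_samples = 12, n_genes = 100, seed = 7))
#' cohort$expression
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  .with_seed(config@seed, .simulate_cohort_impl(config))
}

.simulate_cohort_impl <- function(config) {
  n <- config@n_samples
  p <- config@n_genes
  gene_ids <- sprintf("g%04d", seq_len(p))
  sample_ids <- sprintf("S%03d", seq_len(n))

  mu_log2 <- stats::rnorm(p, config@baseline_log_mean[1],
                          config@baseline_log_mean[2])
  names(mu_log2) <- gene_ids

  # program genes come from the expressed part of the universe (above the
  # 25th percentile of baseline mean): curated signatures track expressed genes
  eligible <- gene_ids[mu_log2 >= stats::quantile(mu_log2, 0.25)]
  program_genes <- list()
  effects <- numeric()
  for (spec in config@program_specs) {
    k <- as.integer(spec$n_genes)
    if (k > length(eligible))
      stop("program '", spec$name, "' larger than the eligible gene universe")
    g <- sample(eligible, k)
    eligible <- setdiff(eligible, g)
    program_genes[[spec$name]] <- g
    effects[spec$name] <- spec$effect
  }

  n_resp <- max(1L, min(n - 1L, round(config@responder_fraction * n)))
  responder <- rep(FALSE, n)
  responder[sample.int(n, n_resp)] <- TRUE
  names(responder) <- sample_ids

  mu <- matrix(2^mu_log2, nrow = p, ncol = n,
               dimnames = list(gene_ids, sample_ids))
  for (nm in names(program_genes))
    mu[program_genes[[nm]], responder] <-
      mu[program_genes[[nm]], responder] * 2^effects[nm]

  counts <- matrix(stats::rnbinom(p * n, mu = as.vector(mu),
                                  size = 1 / config@dispersion),
                   nrow = p, ncol = n,
                   dimnames = list(gene_ids, sample_ids))

  # best response: responders split CR/PR, non-responders split SD/PD,
  # deterministically given the labels
  best <- character(n)
  ri <- which(responder); ni <- which(!responder)
  n_cr <- round(length(ri) * config@cr_fraction)
  best[ri] <- c(rep("CR", n_cr), rep("PR", length(ri) - n_cr))
  n_sd <- round(length(ni) * config@sd_fraction)
  best[ni] <- c(rep("SD", n_sd), rep("PD", length(ni) - n_sd))

  benefit <- best %in% c("CR", "PR")
  sd_i <- which(best == "SD")
  n_sd_benefit <- round(length(sd_i) * config@sd_benefit_fraction)
  benefit[sd_i[seq_len(n_sd_benefit)]] <- TRUE

  # immune-high = top half of samples by planted-program score (first program)
  if (length(program_genes)) {
    score <- colMeans(log2(1 + counts[program_genes[[1]], , drop = FALSE]))
  } else {
    score <- colMeans(log2(1 + counts))
  }
  high <- rep(FALSE, n)
  high[order(score, decreasing = TRUE)[seq_len(ceiling(n / 2))]] <- TRUE
  names(high) <- sample_ids

  med <- config@survival_spec[1]
  lhr <- config@survival_spec[2]
  cens <- config@survival_spec[3]
  shape <- config@weibull_shape
  lp <- lhr * high
  death <- .draw_weibull_ph(n, med, shape, lp)
  prog <- .draw_weibull_ph(n, med / 4, shape, lp)
  censor <- if (cens > 0) {
    .draw_weibull_ph(n, med, shape, lp + log(cens / (1 - cens)))
  } else rep(Inf, n)
  os_months <- pmin(death, censor)
  os_event <- death <= censor
  pfs_months <- pmin(prog, death, censor)
  pfs_event <- pmin(prog, death) <= censor

  clinical <- ClinicalTable(data.frame(
    sample_id = sample_ids, best_response = best,
    clinical_benefit = benefit,
    os_months = round(os_months, 4), os_event = os_event,
    pfs_months = round(pfs_months, 4), pfs_event = pfs_event,
    immune_high = high, stringsAsFactors = FALSE))

  truth <- new("SimTruth", responder_labels = responder,
               program_genes = program_genes, realized_effects = effects,
               immune_high = high)

  list(expression = ExpressionMatrix(counts, layer = "counts"),
       clinical = clinical, truth = truth)
}

#' Default configurations for contrasting IL2-like and anti-PD-1-like cohorts
#'
#' Both carry a 26-gene T-effector program elevated in responders (+1 log2
#' unit); the 6-gene myeloid-inflammation program is elevated in responders
#' of the IL2-like cohort (+1) and depleted in responders of the
#' anti-PD-1-like cohort (-1) — the direction flip between the two therapy
#' classes.
#'
#' @param cohort `"il2"` or `"pd1"`.
#' @param seed integer seed.
#' @param myeloid_effect absolute log2 effect of the myeloid program.
#' @param teff_effect log2 effect of the T-effector program (both cohorts).
#' @param ... further arguments passed to [SimConfig()].
#' @return a [SimConfig-class].
#' @export
contrastingConfig <- function(cohort = c("il2", "pd1"), seed = 1L,
                              myeloid_effect = 1, teff_effect = 1, ...) {
  cohort <- match.arg(cohort)
  sign <- if (cohort == "il2") 1 else -1
  SimConfig(program_specs = list(
    list(name = "teff", n_genes = 26L, effect = teff_effect),
    list(name = "myeloid", n_genes = 6L, effect = sign * myeloid_effect)
  ), seed = seed, ...)
}

#' Simulate contrasting IL2-like and anti-PD-1-like cohorts
#'
#' Generates two cohorts sharing a `"myeloid"` program name so that the
#' direction of the responder myeloid contrast can flip between them while
#' the effector program stays positive in both.
#'
#' @param config_il2,config_pd1 [SimConfig-class] objects; both must plant a
#'   program named `"myeloid"`. Defaults come from [contrastingConfig()].
#' @return named list `il2`, `pd1`, each a [simulateCohort()] result.
#' @export
simulateContrastingCohorts <- function(config_il2 = contrastingConfig("il2", seed = 1L),
                                       config_pd1 = contrastingConfig("pd1", seed = 2L)) {
  for (cfg in list(config_il2, config_pd1)) {
    nms <- vapply(cfg@program_specs, function(p) p$name, character(1))
    if (!"myeloid" %in% nms)
      stop("both configurations must plant a shared 'myeloid' program")
  }
  list(il2 = simulateCohort(config_il2), pd1 = simulateCohort(config_pd1))
}

#' Write simulation ground truth as JSON
#'
#' @param truth a [SimTruth-class].
#' @param path output file.
#' @export
writeSimTruthJSON <- function(truth, path) {
  stopifnot(is(truth, "SimTruth"))
  jsonlite::write_json(list(
    responder_labels = truth@responder_labels,
    program_genes = truth@program_genes,
    realized_effects = as.list(truth@realized_effects),
    immune_high = truth@immune_high
  ), path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}
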