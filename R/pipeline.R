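#' Read a pipeline run configuration from YAML
#'
#' Loads a run configuration and fills every omitted field with the package
#' default (minimum-expression filter 10 reads / 5 samples, candidate
#' percentiles 0.25 / 0.70, gene grid 4..100 by 2, standardized distance,
#' OS + PFS endpoints). Exactly one of `sim` (simulator parameters) or the
#' input paths `counts` + `clinical` must be provided.
#'
#' @param path YAML file path.
#' @return a validated run-configuration list for [runPipeline()].
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  .complete_run_config(cfg)
}

.complete_run_config <- function(cfg) {
  defaults <- list(
    sim = NULL, counts = NULL, clinical = NULL, coding_genes = NULL,
    gmt = NULL, min_count = 10, min_samples = 5,
    median_percentile = 0.25, variance_percentile = 0.70,
    gene_grid = seq(4L, 100L, by = 2L), s0 = 0,
    distance_kind = "standardized",
    endpoints = c("os", "pfs"), seed = 1L)
  cfg <- utils::modifyList(defaults, cfg[!vapply(cfg, is.null, logical(1))])
  has_sim <- !is.null(cfg$sim)
  has_paths <- !is.null(cfg$counts) && !is.null(cfg$clinical)
  if (has_sim == has_paths)
    stop("provide exactly one of 'sim' or input paths 'counts' + 'clinical'")
  cfg
}

.stage <- function(name, log_con, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  cat(sprintf("[%s] done in %.2fs\n", name,
              proc.time()[["elapsed"]] - t0), file = log_con)
  res
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/load -> preprocess -> signature scoring and group
#' comparison -> cross-validated response classifier -> clinical outcome
#' statistics, writing every stage's outputs plus a machine-readable
#' manifest to `outdir`. Re-running with an identical configuration and seed
#' reproduces all outputs byte-identically (stage wall times go to
#' `run_log.txt`, which is excluded from the manifest).
#'
#' @param config configuration list (see [readRunConfig()]); may also be a
#'   [SimConfig-class], which is wrapped as `list(sim = config)`.
#' @param outdir output directory, created if needed.
#' @param seed optional integer overriding the configured seed.
#' @return the manifest, invisibly: `seed`, `files`, `metrics`.
#' @export
runPipeline <- function(config, outdir, seed = NULL) {
  if (is(config, "SimConfig")) config <- list(sim = config)
  config <- .complete_run_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(outdir, "run_log.txt"), open = "wt")
  on.exit(close(log_con))
  out <- function(f) file.path(outdir, f)
  files <- character()
  metrics <- list()

  # -- input ----------------------------------------------------------------
  truth <- NULL
  input <- .stage("input", log_con, {
    if (!is.null(config$sim)) {
      sim_cfg <- if (is(config$sim, "SimConfig")) config$sim
                 else do.call(SimConfig, config$sim)
      sim_cfg@seed <- as.integer(config$seed)
      cohort <- simulateCohort(sim_cfg)
      writeExpressionTSV(cohort$expression, out("counts.tsv"))
      writeClinicalCSV(cohort$clinical, out("clinical.csv"))
      writeSimTruthJSON(cohort$truth, out("sim_truth.json"))
      truth <- cohort$truth
      c(cohort, list(files = c("counts.tsv", "clinical.csv",
                               "sim_truth.json")))
    } else {
      list(expression = readExpressionTSV(config$counts, layer = "counts"),
           clinical = readClinicalCSV(config$clinical), files = character())
    }
  })
  files <- c(files, input$files)
  counts <- input$expression
  clinical <- input$clinical

  # -- preprocess -----------------------------------------------------------
  norm <- .stage("preprocess", log_con, {
    flt <- filterMinExpression(counts, config$min_count, config$min_samples)
    if (!is.null(config$coding_genes)) {
      allowed <- readLines(config$coding_genes)
      flt <- restrictGeneUniverse(flt$expression, allowed)
    }
    jsonlite::write_json(flt$report, out("filter_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    nm <- normalizeExpression(flt$expression)
    writeExpressionTSV(nm, out("normalized.tsv"))
    files <- c(files, "filter_report.json", "normalized.tsv")
    metrics$n_genes_filtered <- flt$report$n_genes_out
    nm
  })

  responder <- responderFromResponse(clinical)

  # -- signatures -----------------------------------------------------------
  .stage("signatures", log_con, {
    collection <- if (!is.null(config$gmt)) {
      readGMT(config$gmt)
    } else if (!is.null(truth)) {
      GeneSetCollection(programGenes(truth))
    } else NULL
    if (!is.null(collection)) {
      sig <- scoreSignatures(norm, collection)
      utils::write.table(
        data.frame(signature = rownames(scores(sig)), scores(sig),
                   check.names = FALSE),
        out("signature_scores.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      cmp <- compareGroups(sig, responder)
      utils::write.table(cmp, out("signature_comparisons.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      files <- c(files, "signature_scores.tsv", "signature_comparisons.tsv")
      metrics$n_signatures_displayed <- sum(cmp$display)
    }
    invisible(NULL)
  })

  # -- classifier -----------------------------------------------------------
  model <- .stage("classifier", log_con, {
    mdl <- trainResponseClassifier(
      norm, responder,
      median_percentile = config$median_percentile,
      variance_percentile = config$variance_percentile,
      gene_grid = config$gene_grid, s0 = config$s0,
      distance_kind = config$distance_kind)
    writeCentroidModel(mdl, out("response_model.json"))
    utils::write.table(cvTrace(mdl), out("cv_trace.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, "response_model.json", "cv_trace.tsv")
    metrics$cv_accuracy <- max(cvTrace(mdl)$cv_accuracy)
    metrics$chosen_n_genes <- mdl@chosen_n_genes
    mdl
  })

  # -- outcomes -------------------------------------------------------------
  .stage("outcomes", log_con, {
    rates <- responseRates(clinical)
    metrics$orr_percent <- unname(rates$percent["orr"])
    results <- list(response_rates = rates[c("n_evaluable", "orr",
                                             "disease_control",
                                             "clinical_benefit_rate")])
    group <- if ("immune_high" %in% colnames(clinical))
      clinical$immune_high else predict(model, norm)$class ==
        model@class_labels[1]
    for (ep in config$endpoints) {
      tm <- clinical[[paste0(ep, "_months")]]
      ev <- clinical[[paste0(ep, "_event")]]
      km <- kaplanMeier(tm, ev)
      utils::write.table(
        data.frame(time = km$time, surv = km$surv, n_risk = km$n_risk,
                   n_event = km$n_event),
        out(paste0("km_", ep, ".tsv")), sep = "\t", quote = FALSE,
        row.names = FALSE)
      files <- c(files, paste0("km_", ep, ".tsv"))
      results[[ep]] <- list(
        km_median = km$median,
        logrank = logrankTest(tm, ev, group),
        cox = coxPH(tm, ev, data.frame(immune_high = as.numeric(group))))
    }
    jsonlite::write_json(results, out("outcomes.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
    files <- c(files, "outcomes.json")
    invisible(NULL)
  })

  manifest <- list(package_version = as.character(utils::packageVersion("immunocentroid")),
                   seed = config$seed, files = sort(unique(files)),
                   metrics = metrics)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
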