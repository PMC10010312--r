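#' Construct a ClinicalTable
#'
#' Validates and wraps a per-sample clinical annotation table. Extra columns
#' (molecular covariates, subtype calls) are kept and available to the
#' association statistics in the outcomes functions.
#'
#' @param df a data.frame or DataFrame with columns `sample_id`,
#'   `best_response` (CR/PR/SD/PD or NA), `clinical_benefit` (logical, NA
#'   allowed), `os_months`, `os_event`, `pfs_months`, `pfs_event`.
#' @return a [ClinicalTable-class] object.
#' @export
ClinicalTable <- function(df) {
  df <- DataFrame(df, check.names = FALSE)
  if ("best_response" %in% colnames(df))
    df$best_response <- as.character(df$best_response)
  for (col in c("clinical_benefit", "os_event", "pfs_event"))
    if (col %in% colnames(df)) df[[col]] <- as.logical(df[[col]])
  new("ClinicalTable", df)
}

setMethod("show", "ClinicalTable", function(object) {
  br <- object$best_response
  cat("ClinicalTable:", nrow(object), "samples",
      sprintf("(CR %d, PR %d, SD %d, PD %d, NA %d)\n",
              sum(br == "CR", na.rm = TRUE), sum(br == "PR", na.rm = TRUE),
              sum(br == "SD", na.rm = TRUE), sum(br == "PD", na.rm = TRUE),
              sum(is.na(br))))
})

#' Responder labels from best response
#'
#' Collapses best response into the responder dichotomy used by the response
#' classifier and the signature group comparisons: CR/PR versus SD/PD.
#' Samples with missing best response get `NA`.
#'
#' @param clin a [ClinicalTable-class].
#' @return logical vector named by sample, `TRUE` for CR/PR.
#' @export
responderFromResponse <- function(clin) {
  stopifnot(is(clin, "ClinicalTable"))
  r <- ifelse(is.na(clin$best_response), NA,
              clin$best_response %in% c("CR", "PR"))
  names(r) <- clin$sample_id
  r
}

#' Read / write the clinical CSV dialect
#'
#' Comma-separated text with columns `sample_id`, `best_response`,
#' `clinical_benefit`, `os_months`, `os_event`, `pfs_months`, `pfs_event`
#' (events written as TRUE/FALSE); extra columns round-trip unchanged.
#'
#' @param path file path.
#' @return `readClinicalCSV` returns a [ClinicalTable-class];
#'   `writeClinicalCSV` returns `path` invisibly.
#' @export
readClinicalCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  df$best_response[df$best_response %in% c("", "NA")] <- NA
  ClinicalTable(df)
}

#' @rdname readClinicalCSV
#' @param clin a [ClinicalTable-class].
#' @export
writeClinicalCSV <- function(clin, path) {
  utils::write.csv(as.data.frame(clin), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
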