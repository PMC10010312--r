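# deterministic toy fixtures shared across test files

toy_counts <- function() {
  m <- matrix(c(
    10, 10, 10, 10, 10, 0,
    0, 0, 0, 0, 0, 0,
    9, 9, 9, 9, 9, 9,
    50, 40, 30, 20, 10, 5,
    10, 10, 10, 10, 9, 9,
    100, 0, 0, 0, 0, 0
  ), nrow = 6, byrow = TRUE,
  dimnames = list(paste0("g", 1:6), paste0("s", 1:6)))
  ExpressionMatrix(m, layer = "counts")
}

toy_norm <- function(values) {
  ExpressionMatrix(values, layer = "log_normalized")
}

# gaussian two-class matrix with planted up/down genes, for classifier tests
separated_classes <- function(n_per_class = 15, n_genes = 300,
                              n_planted = 40, delta = 3, seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_class
  m <- matrix(rnorm(n_genes * n), nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n))))
  labels <- rep(c(TRUE, FALSE), each = n_per_class)
  planted <- sample(rownames(m), n_planted)
  up <- planted[seq_len(n_planted / 2)]
  down <- planted[-seq_len(n_planted / 2)]
  m[up, labels] <- m[up, labels] + delta
  m[down, labels] <- m[down, labels] - delta
  list(norm = toy_norm(m), labels = labels, up = up, down = down,
       planted = planted)
}

small_clinical <- function(best = c("CR", "PR", "SD", "PD"),
                           benefit = c(TRUE, TRUE, FALSE, FALSE)) {
  ClinicalTable(data.frame(
    sample_id = paste0("S", seq_along(best)),
    best_response = best, clinical_benefit = benefit,
    os_months = seq_along(best), os_event = TRUE,
    pfs_months = seq_along(best) / 2, pfs_event = TRUE,
    stringsAsFactors = FALSE))
}
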