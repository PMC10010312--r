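test_that("candidate filtering equals a brute-force double-threshold scan", {
  set.seed(20)
  m <- matrix(rnorm(10 * 8, sd = rep(runif(10, 0.5, 3), 8)), nrow = 10,
              dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:8)))
  norm <- toy_norm(m)
  got <- selectCandidates(norm, 0.25, 0.70)
  med <- apply(m, 1, median); va <- apply(m, 1, var)
  expected <- rownames(m)[med >= quantile(med, 0.25) &
                            va >= quantile(va, 0.70)]
  expect_identical(got, expected)

  expect_identical(selectCandidates(norm, 0, 0), rownames(m))
  expect_error(selectCandidates(toy_norm(m[, 1, drop = FALSE])), "2 samples")
})

test_that("with independent median and variance ranks the selected fraction is near 0.225", {
  set.seed(21)
  mu <- rnorm(4000); sigma <- sqrt(exp(rnorm(4000, sd = 0.5)))
  m <- matrix(rnorm(4000 * 40, mean = mu, sd = sigma), nrow = 4000,
              dimnames = list(sprintf("g%04d", 1:4000), paste0("s", 1:40)))
  frac <- length(selectCandidates(toy_norm(m), 0.25, 0.70)) / 4000
  expect_lt(abs(frac - 0.225), 0.03)
})

test_that("gene t statistics match hand arithmetic and are symmetric under permutation", {
  m <- matrix(c(1, 3, -1, 1,
                0, 2, 1, 3), nrow = 2, byrow = TRUE,
              dimnames = list(c("gA", "gC"), paste0("s", 1:4)))
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  t_stats <- geneTStatistics(toy_norm(m), labels)
  # gA: means 2 vs 0, pooled SD sqrt((2+2)/2) = sqrt(2),
  #     t = 2 / (sqrt(2) * sqrt(1/2+1/2)) = sqrt(2)
  expect_equal(unname(t_stats["gA"]), sqrt(2))

  # a flat gene scores 0 (and triggers the s0 fallback for the others)
  flat <- rbind(m, gB = c(2, 2, 2, 2))
  t_flat <- geneTStatistics(toy_norm(flat), labels)
  expect_equal(unname(t_flat["gB"]), 0)
  expect_true(all(is.finite(t_flat)))

  set.seed(22)
  big <- matrix(rnorm(200 * 20), nrow = 200,
                dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:20)))
  t_mean <- replicate(50, {
    perm <- sample(rep(c(TRUE, FALSE), 10))
    mean(geneTStatistics(big, perm))
  })
  expect_lt(abs(mean(t_mean)), 0.05)

  expect_error(geneTStatistics(big, c(TRUE, rep(FALSE, 19))), "2 samples")
})

test_that("centroid fitting gives class means and swaps with the labels", {
  m <- matrix(c(1, 3, 5, 7,
                0, 2, 10, 12), nrow = 2, byrow = TRUE,
              dimnames = list(c("gA", "gB"), paste0("s", 1:4)))
  f <- factor(c("x", "x", "y", "y"), levels = c("x", "y"))
  model <- fitCentroids(m, f, c("gA", "gB"))
  expect_equal(model@centroids, matrix(c(2, 1, 6, 11), nrow = 2, byrow = TRUE,
                                       dimnames = list(c("x", "y"),
                                                       c("gA", "gB"))))
  # pooled within-class SD: sqrt((2 + 2) / (4 - 2)) for both genes
  expect_equal(unname(model@pooled_sd), c(sqrt(2), sqrt(2)))

  swapped <- fitCentroids(m, factor(c("y", "y", "x", "x"),
                                    levels = c("x", "y")), c("gA", "gB"))
  expect_equal(swapped@centroids["x", ], model@centroids["y", ])

  one_each <- fitCentroids(m[, c(1, 3)], factor(c("x", "y")), c("gA", "gB"))
  expect_equal(unname(one_each@centroids["x", ]), unname(m[, 1]))
  expect_gt(one_each@s0, 0)  # zero pooled SD triggers the s0 fallback
  expect_error(fitCentroids(m, f, c("gA", "gZ")), "gZ")
})

test_that("prediction matches exhaustive distance minimization with deterministic ties", {
  set.seed(23)
  for (rep in 1:25) {
    n_genes <- sample(2:6, 1); K <- sample(2:3, 1); n <- 5
    genes <- paste0("g", seq_len(n_genes))
    classes <- paste0("c", seq_len(K))
    centroids <- matrix(rnorm(K * n_genes), nrow = K,
                        dimnames = list(classes, genes))
    sdv <- setNames(runif(n_genes, 0.5, 2), genes)
    model <- new("CentroidModel", selected_genes = genes,
                 class_labels = classes, centroids = centroids,
                 pooled_sd = sdv, s0 = 0.1,
                 distance_kind = "standardized",
                 cv_trace = data.frame(n_genes = integer(),
                                       cv_accuracy = numeric()),
                 chosen_n_genes = length(genes))
    X <- matrix(rnorm(n_genes * n), nrow = n_genes,
                dimnames = list(genes, paste0("s", 1:n)))
    pred <- predict(model, X)
    for (j in seq_len(n)) {
      d <- sapply(classes, function(k)
        sum(((X[, j] - centroids[k, ]) / (sdv + 0.1))^2))
      expect_identical(pred$class[j], classes[which.min(d)])
      expect_equal(unname(as.numeric(pred[j, paste0("dist_", classes)])),
                   unname(d))
    }
  }
})

test_that("a sample on a centroid and an equidistant sample resolve deterministically", {
  centroids <- matrix(c(0, 0, 2, 2), nrow = 2, byrow = TRUE,
                      dimnames = list(c("first", "second"), c("gA", "gB")))
  model <- new("CentroidModel", selected_genes = c("gA", "gB"),
               class_labels = c("first", "second"), centroids = centroids,
               pooled_sd = c(gA = 1, gB = 1), s0 = 0,
               distance_kind = "standardized",
               cv_trace = data.frame(n_genes = integer(),
                                     cv_accuracy = numeric()),
               chosen_n_genes = 2L)
  X <- matrix(c(2, 2, 1, 1), nrow = 2,
              dimnames = list(c("gA", "gB"), c("on_second", "midpoint")))
  pred <- predict(model, X)
  expect_identical(pred$class, c("second", "first"))
  expect_equal(pred$dist_second[1], 0)
  expect_error(predict(model, X[1, , drop = FALSE]), "gB")
})

test_that("cross-validated training recovers a planted separation", {
  fit <- separated_classes(n_per_class = 15, n_genes = 300, n_planted = 40,
                           delta = 3, seed = 45)
  model <- trainResponseClassifier(fit$norm, fit$labels,
                                   median_percentile = 0,
                                   variance_percentile = 0.3,
                                   gene_grid = seq(4, 60, 4))
  trace <- cvTrace(model)
  expect_identical(trace$n_genes, seq(4L, 60L, 4L))
  expect_true(all(trace$cv_accuracy >= 0 & trace$cv_accuracy <= 1))
  expect_equal(max(trace$cv_accuracy), 1.0)

  model40 <- trainResponseClassifier(fit$norm, fit$labels,
                                     median_percentile = 0,
                                     variance_percentile = 0.3,
                                     gene_grid = 40)
  expect_gte(mean(fit$planted %in% selectedGenes(model40)), 0.8)
  # balanced selection: 20 genes per direction
  t_all <- geneTStatistics(fit$norm, fit$labels)
  expect_identical(sum(t_all[selectedGenes(model40)] > 0), 20L)
})

test_that("a singleton grid is equivalent to a direct fit at that size", {
  fit <- separated_classes(n_per_class = 8, n_genes = 120, n_planted = 10,
                           delta = 2, seed = 46)
  model <- trainResponseClassifier(fit$norm, fit$labels,
                                   median_percentile = 0,
                                   variance_percentile = 0,
                                   gene_grid = 10)
  t_all <- geneTStatistics(fit$norm, fit$labels)
  direct_genes <- immunocentroid:::.select_by_t(t_all, 10L)
  expect_identical(selectedGenes(model), direct_genes)
  direct <- fitCentroids(fit$norm, fit$labels, direct_genes)
  expect_equal(model@centroids, direct@centroids)
  expect_equal(model@pooled_sd, direct@pooled_sd)
})

test_that("gene selection happens inside folds, blind to the held-out sample", {
  fit <- separated_classes(n_per_class = 6, n_genes = 80, n_planted = 8,
                           delta = 1, seed = 47)
  X <- exprValues(fit$norm)
  train_cols <- 2:ncol(X)
  t_orig <- geneTStatistics(X[, train_cols], fit$labels[train_cols])
  perturbed <- fit$labels[train_cols]
  perturbed[c(1, 11)] <- !perturbed[c(1, 11)]
  t_pert <- geneTStatistics(X[, train_cols], perturbed)
  expect_false(identical(immunocentroid:::.select_by_t(t_orig, 8L),
                         immunocentroid:::.select_by_t(t_pert, 8L)))

  # in-fold reselection produces a different CV trace than frozen selection
  with_res <- trainResponseClassifier(fit$norm, fit$labels,
                                      median_percentile = 0,
                                      variance_percentile = 0,
                                      gene_grid = c(4, 8),
                                      reselect_in_fold = TRUE)
  frozen <- trainResponseClassifier(fit$norm, fit$labels,
                                    median_percentile = 0,
                                    variance_percentile = 0,
                                    gene_grid = c(4, 8),
                                    reselect_in_fold = FALSE)
  expect_false(identical(cvTrace(with_res)$cv_accuracy,
                         cvTrace(frozen)$cv_accuracy))
})

test_that("grid handling: truncation warning, rejects odd or empty grids", {
  fit <- separated_classes(n_per_class = 5, n_genes = 30, n_planted = 4,
                           delta = 2, seed = 48)
  expect_warning(
    model <- trainResponseClassifier(fit$norm, fit$labels,
                                     median_percentile = 0,
                                     variance_percentile = 0,
                                     gene_grid = c(10, 200)),
    "truncating")
  expect_identical(cvTrace(model)$n_genes, 10L)
  expect_error(trainResponseClassifier(fit$norm, fit$labels,
                                       gene_grid = integer()), "empty")
  expect_error(trainResponseClassifier(fit$norm, fit$labels,
                                       gene_grid = 5), "even")
})

test_that("subtype classifier is deterministic, accurate on separated data, strict on genes", {
  set.seed(49)
  n <- 60
  genes34 <- sprintf("sub%02d", 1:34)
  other <- sprintf("oth%02d", 1:30)
  subtype <- rep(c("ccA", "ccB"), each = n / 2)
  m <- matrix(rnorm(64 * n), nrow = 64,
              dimnames = list(c(genes34, other), sprintf("s%02d", 1:n)))
  m[genes34[1:17], subtype == "ccB"] <- m[genes34[1:17], subtype == "ccB"] + 3
  m[genes34[18:34], subtype == "ccB"] <- m[genes34[18:34], subtype == "ccB"] - 3
  norm <- toy_norm(m)

  a <- trainSubtypeClassifier(norm, subtype, genes34, seed = 7)
  b <- trainSubtypeClassifier(norm, subtype, genes34, seed = 7)
  expect_identical(a$train_samples, b$train_samples)
  expect_equal(a$test_accuracy, b$test_accuracy)
  expect_gte(a$test_accuracy, 0.95)
  expect_identical(sort(a$model@class_labels), c("ccA", "ccB"))
  # roughly 2/3 - 1/3 stratified split
  expect_identical(length(a$train_samples), 40L)

  expect_error(trainSubtypeClassifier(norm, subtype,
                                      c(genes34[-1], "absent01"), seed = 1),
               "absent01")
})

test_that("zero-variance genes keep distances finite through the s0 fallback", {
  m <- matrix(c(rep(1, 6), 1, 1, 1, 2, 2, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("flat", "informative"), paste0("s", 1:6)))
  labels <- rep(c(TRUE, FALSE), each = 3)
  model <- fitCentroids(m, labels, c("flat", "informative"))
  expect_gt(model@s0, 0)
  pred <- predict(model, m)
  expect_true(all(is.finite(as.matrix(pred[, grep("dist_", names(pred))]))))
})
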