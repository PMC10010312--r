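#' Label-free candidate gene filtering
#'
#' Identifies highly expressed, highly variable candidate genes for
#' supervised selection: genes whose across-sample median is at least the
#' `median_percentile` quantile of all gene medians AND whose across-sample
#' variance is at least the `variance_percentile` quantile of all gene
#' variances (defaults 0.25 and 0.70). No response information is used, so
#' the filter can run once on the full matrix outside cross-validation.
#'
#' @param norm an [ExpressionMatrix-class] on the `log_normalized` layer with
#'   at least two samples.
#' @param median_percentile,variance_percentile quantile cutoffs in `[0, 1)`.
#' @return character vector of candidate gene IDs, in matrix order.
#' @export
selectCandidates <- function(norm, median_percentile = 0.25,
                             variance_percentile = 0.70) {
  .assert_layer(norm, "log_normalized", "selectCandidates")
  if (ncol(norm) < 2L) stop("candidate selection requires at least 2 samples")
  stopifnot(median_percentile >= 0, median_percentile < 1,
            variance_percentile >= 0, variance_percentile < 1)
  v <- exprValues(norm)
  med <- apply(v, 1, stats::median)
  va <- apply(v, 1, stats::var)
  keep <- med >= stats::quantile(med, median_percentile) &
    va >= stats::quantile(va, variance_percentile)
  rownames(v)[keep]
}

# vectorized per-gene pooled-variance t on a genes x samples matrix;
# `g1` is the logical indicator of the first (positive-sign) class
.gene_t_matrix <- function(X, g1, s0 = 0) {
  n1 <- sum(g1); n2 <- sum(!g1)
  X1 <- X[, g1, drop = FALSE]; X2 <- X[, !g1, drop = FALSE]
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  ss1 <- rowSums((X1 - m1)^2); ss2 <- rowSums((X2 - m2)^2)
  sp <- sqrt((ss1 + ss2) / (n1 + n2 - 2))
  if (s0 == 0 && any(sp == 0)) {
    s0 <- stats::median(sp)
    if (s0 == 0) s0 <- 1
  }
  denom <- sp * sqrt(1 / n1 + 1 / n2) + s0
  t <- (m1 - m2) / denom
  t[denom == 0 & m1 == m2] <- 0
  t
}

#' Per-gene two-sample t statistics
#'
#' Pooled-variance t per gene with denominator
#' `s_p * sqrt(1/n1 + 1/n2) + s0`; positive sign means higher in the first
#' class (responders, CR/PR). With the default `s0 = 0`, any gene with zero
#' pooled SD triggers an automatic fallback to `s0 =` the median pooled SD
#' across genes, keeping every statistic finite.
#'
#' @param norm an [ExpressionMatrix-class] (any layer) or numeric matrix.
#' @param labels logical per sample (TRUE = first class) or two-level
#'   factor/character; both classes need at least 2 samples.
#' @param s0 non-negative standard-deviation offset.
#' @return named numeric vector of t statistics, one per gene.
#' @export
geneTStatistics <- function(norm, labels, s0 = 0) {
  X <- if (is(norm, "ExpressionMatrix")) exprValues(norm) else as.matrix(norm)
  g1 <- .as_first_class_indicator(labels, ncol(X))
  if (sum(g1) < 2L || sum(!g1) < 2L)
    stop("both classes need at least 2 samples")
  .gene_t_matrix(X, g1, s0 = s0)
}

.as_first_class_indicator <- function(labels, n) {
  if (is.factor(labels) || is.character(labels)) {
    labels <- if (is.factor(labels)) labels else factor(labels,
                                                        levels = unique(labels))
    if (nlevels(droplevels(labels)) != 2L)
      stop("labels must have exactly two classes")
    labels <- labels == levels(labels)[1]
  }
  labels <- as.logical(labels)
  if (length(labels) != n) stop("one label per sample required")
  if (anyNA(labels)) stop("labels must not be missing")
  labels
}

.class_factor <- function(labels, n) {
  if (is.logical(labels)) {
    if (length(labels) != n) stop("one label per sample required")
    factor(ifelse(labels, "CR/PR", "SD/PD"), levels = c("CR/PR", "SD/PD"))
  } else {
    f <- if (is.factor(labels)) labels else factor(labels,
                                                   levels = unique(labels))
    if (length(f) != n) stop("one label per sample required")
    droplevels(f)
  }
}

.fit_centroids_matrix <- function(X, f) {
  classes <- levels(f)
  K <- length(classes); n <- ncol(X)
  centroids <- matrix(NA_real_, nrow = K, ncol = nrow(X),
                      dimnames = list(classes, rownames(X)))
  ss <- numeric(nrow(X))
  for (k in classes) {
    Xk <- X[, f == k, drop = FALSE]
    ck <- rowMeans(Xk)
    centroids[k, ] <- ck
    ss <- ss + rowSums((Xk - ck)^2)
  }
  pooled_sd <- if (n > K) sqrt(ss / (n - K)) else rep(0, nrow(X))
  names(pooled_sd) <- rownames(X)
  list(centroids = centroids, pooled_sd = pooled_sd)
}

.default_s0 <- function(pooled_sd, s0) {
  if (s0 == 0 && any(pooled_sd == 0)) {
    s0 <- stats::median(pooled_sd)
    if (s0 == 0) s0 <- 1
  }
  s0
}

#' Fit class centroids on a fixed gene list
#'
#' Computes per-class per-gene means and the per-gene pooled within-class
#' standard deviation (no gene selection). When any pooled SD is zero and
#' `s0 = 0`, `s0` falls back to the median pooled SD across the genes (or 1
#' if that is also zero), so standardized distances stay finite.
#'
#' @param norm an [ExpressionMatrix-class] or numeric matrix.
#' @param labels class labels per sample (logical means CR/PR vs SD/PD).
#' @param genes genes to model; must all be present.
#' @param distance_kind `"standardized"` (Dabney-style, default) or
#'   `"euclidean"`.
#' @param s0 standard-deviation offset; see Details.
#' @return a [CentroidModel-class].
#' @export
fitCentroids <- function(norm, labels, genes,
                         distance_kind = c("standardized", "euclidean"),
                         s0 = 0) {
  distance_kind <- match.arg(distance_kind)
  X <- if (is(norm, "ExpressionMatrix")) exprValues(norm) else as.matrix(norm)
  missing_genes <- setdiff(genes, rownames(X))
  if (length(missing_genes))
    stop("gene(s) absent from the matrix: ",
         paste(missing_genes, collapse = ", "))
  f <- .class_factor(labels, ncol(X))
  if (any(table(f) == 0L)) stop("empty class")
  X <- X[genes, , drop = FALSE]
  fit <- .fit_centroids_matrix(X, f)
  new("CentroidModel",
      selected_genes = genes, class_labels = levels(f),
      centroids = fit$centroids, pooled_sd = fit$pooled_sd,
      s0 = .default_s0(fit$pooled_sd, s0),
      distance_kind = distance_kind,
      cv_trace = data.frame(n_genes = integer(), cv_accuracy = numeric()),
      chosen_n_genes = length(genes))
}

#' @rdname CentroidModel-class
#' @aliases selectedGenes cvTrace
#' @export
setMethod("selectedGenes", "CentroidModel", function(x) x@selected_genes)

#' @rdname CentroidModel-class
#' @export
setMethod("cvTrace", "CentroidModel", function(x) x@cv_trace)

setMethod("show", "CentroidModel", function(object) {
  cat("CentroidModel:", length(object@selected_genes), "genes, classes",
      paste(object@class_labels, collapse = " vs "),
      sprintf("[%s distance, s0 = %.3g]\n", object@distance_kind, object@s0))
  if (nrow(object@cv_trace))
    cat("  CV: accuracy", sprintf("%.3f", max(object@cv_trace$cv_accuracy)),
        "at", object@chosen_n_genes, "genes\n")
})

.predict_matrix <- function(centroids, sd_eff, X, distance_kind) {
  denom <- if (distance_kind == "standardized") sd_eff else rep(1, ncol(centroids))
  K <- nrow(centroids)
  d <- matrix(NA_real_, nrow = K, ncol = ncol(X),
              dimnames = list(rownames(centroids), colnames(X)))
  for (k in seq_len(K))
    d[k, ] <- colSums(((X - centroids[k, ]) / denom)^2)
  # ties resolved toward the first listed class (max.col "first" on -d)
  idx <- max.col(-t(d), ties.method = "first")
  list(class = rownames(centroids)[idx], distances = t(d))
}

#' Predict classes from a nearest-centroid model
#'
#' Assigns each sample to the class with minimal distance
#' `d_k = sum_g ((x_g - c_kg) / (pooled_sd_g + s0))^2` (or unscaled squared
#' Euclidean when the model's `distance_kind` is `"euclidean"`). Ties are
#' broken toward the first class in the model's `class_labels`,
#' deterministically.
#'
#' @param object a [CentroidModel-class].
#' @param newdata an [ExpressionMatrix-class] or numeric gene x sample
#'   matrix containing every model gene (missing genes are an error listing
#'   them).
#' @param ... unused.
#' @return data.frame: `sample_id`, `class`, and one squared-distance column
#'   `dist_<class>` per class.
#' @export
setMethod("predict", "CentroidModel", function(object, newdata, ...) {
  X <- if (is(newdata, "ExpressionMatrix")) exprValues(newdata)
       else as.matrix(newdata)
  missing_genes <- setdiff(object@selected_genes, rownames(X))
  if (length(missing_genes))
    stop("model gene(s) absent from the matrix: ",
         paste(missing_genes, collapse = ", "))
  X <- X[object@selected_genes, , drop = FALSE]
  if (!all(is.finite(X))) stop("non-finite expression values")
  pr <- .predict_matrix(object@centroids, object@pooled_sd + object@s0, X,
                        object@distance_kind)
  out <- data.frame(sample_id = colnames(X), class = pr$class,
                    stringsAsFactors = FALSE)
  colnames(pr$distances) <- paste0("dist_", colnames(pr$distances))
  cbind(out, as.data.frame(pr$distances, row.names = seq_len(ncol(X))))
})

# select m genes by t statistic; balanced mode takes m/2 with the largest
# positive t and m/2 with the most negative t (ties: larger |t|, then
# lexicographic gene ID), topping up from the remaining genes by |t| when one
# side runs short
.select_by_t <- function(t_stats, m, balanced = TRUE) {
  ids <- names(t_stats)
  if (balanced) {
    pos_order <- ids[order(-t_stats, ids)]
    neg_order <- ids[order(t_stats, ids)]
    sel <- c(utils::head(pos_order[t_stats[pos_order] > 0], m %/% 2),
             utils::head(neg_order[t_stats[neg_order] < 0], m - m %/% 2))
    if (length(sel) < m) {
      rest <- setdiff(ids, sel)
      rest <- rest[order(-abs(t_stats[rest]), rest)]
      sel <- c(sel, utils::head(rest, m - length(sel)))
    }
    sel
  } else {
    utils::head(ids[order(-abs(t_stats), ids)], m)
  }
}

#' Train the cross-validated nearest-centroid response classifier
#'
#' The de novo response classifier: label-free candidate filtering once on
#' the full matrix ([selectCandidates()]), then leave-one-out
#' cross-validation over a grid of gene counts. Inside each fold the
#' per-gene t statistics (responders vs non-responders) are recomputed on
#' the fold's training samples and the top `m/2` positive-t and `m/2`
#' negative-t candidates are selected, centroids fitted, and the held-out
#' sample predicted, so the held-out sample never informs gene selection.
#' The chosen gene count maximizes CV accuracy (ties: smallest m); the final
#' model refits selection and centroids on all samples at that m and carries
#' the full CV trace.
#'
#' @param norm an [ExpressionMatrix-class] on the `log_normalized` layer.
#' @param labels responder labels (logical TRUE = CR/PR, or two-level
#'   factor with the responder class first); at least 3 samples per class.
#' @param median_percentile,variance_percentile candidate-filter cutoffs,
#'   see [selectCandidates()].
#' @param gene_grid vector of even positive gene counts to scan (default 4
#'   to 100 by 2); entries exceeding the candidate count are dropped with a
#'   warning.
#' @param s0 standard-deviation offset for t statistics and distances.
#' @param distance_kind distance used for prediction.
#' @param balanced select m/2 genes per t sign (default) or the top m by
#'   absolute t.
#' @param reselect_in_fold recompute the supervised selection inside each CV
#'   fold (default TRUE); FALSE freezes the full-data selection and
#'   cross-validates only the centroid fit.
#' @return a [CentroidModel-class] with a populated `cv_trace`.
#' @export
trainResponseClassifier <- function(norm, labels,
                                    median_percentile = 0.25,
                                    variance_percentile = 0.70,
                                    gene_grid = seq(4L, 100L, by = 2L),
                                    s0 = 0,
                                    distance_kind = c("standardized",
                                                      "euclidean"),
                                    balanced = TRUE,
                                    reselect_in_fold = TRUE) {
  distance_kind <- match.arg(distance_kind)
  .assert_layer(norm, "log_normalized", "trainResponseClassifier")
  f <- .class_factor(labels, ncol(norm))
  if (nlevels(f) != 2L) stop("two response classes required")
  if (any(table(f) < 3L)) stop("at least 3 samples per class required")
  g1 <- f == levels(f)[1]

  candidates <- selectCandidates(norm, median_percentile, variance_percentile)
  if (length(gene_grid) == 0L) stop("empty gene grid")
  gene_grid <- sort(unique(as.integer(gene_grid)))
  if (any(gene_grid <= 0L) || any(gene_grid %% 2L != 0L))
    stop("gene_grid must contain positive even integers")
  if (any(gene_grid > length(candidates))) {
    warning("truncating gene grid to the candidate count (",
            length(candidates), ")")
    gene_grid <- gene_grid[gene_grid <= length(candidates)]
    if (length(gene_grid) == 0L) stop("no grid value within candidate count")
  }

  X <- exprValues(norm)[candidates, , drop = FALSE]
  n <- ncol(X)
  full_t <- .gene_t_matrix(X, g1, s0 = s0)
  correct <- matrix(NA, nrow = n, ncol = length(gene_grid))
  for (i in seq_len(n)) {
    Xtr <- X[, -i, drop = FALSE]
    ftr <- droplevels(f[-i])
    if (nlevels(ftr) != 2L) stop("a fold lost one class entirely")
    t_fold <- if (reselect_in_fold) .gene_t_matrix(Xtr, g1[-i], s0 = s0)
              else full_t
    for (j in seq_along(gene_grid)) {
      sel <- .select_by_t(t_fold, gene_grid[j], balanced = balanced)
      fit <- .fit_centroids_matrix(Xtr[sel, , drop = FALSE], ftr)
      sd_eff <- fit$pooled_sd + .default_s0(fit$pooled_sd, s0)
      pr <- .predict_matrix(fit$centroids, sd_eff,
                            X[sel, i, drop = FALSE], distance_kind)
      correct[i, j] <- pr$class == as.character(f[i])
    }
  }
  cv_accuracy <- colMeans(correct)
  chosen <- gene_grid[which.max(cv_accuracy)]

  final_genes <- .select_by_t(full_t, chosen, balanced = balanced)
  model <- fitCentroids(norm, f, final_genes,
                        distance_kind = distance_kind, s0 = s0)
  model@cv_trace <- data.frame(n_genes = gene_grid,
                               cv_accuracy = cv_accuracy)
  validObject(model)
  model
}

#' Train the centroid-based molecular subtype classifier
#'
#' Fits the two-class molecular subtype (e.g. ccA/ccB) nearest-centroid
#' classifier on a fixed gene list using a stratified random 2/3 training /
#' 1/3 test split, and reports held-out accuracy. The split is stratified by
#' subtype so both subtypes are always present in training; per-class
#' training counts are bounded so each class keeps at least one test sample
#' when it has two or more members.
#'
#' @param norm an [ExpressionMatrix-class] on the `log_normalized` layer.
#' @param subtype_labels two-level factor/character of subtype calls per
#'   sample.
#' @param gene_list character vector of classifier genes (e.g. the 34-gene
#'   subtype list); all must be present in the matrix.
#' @param train_fraction fraction of each subtype used for training.
#' @param seed integer seed controlling the split.
#' @param distance_kind,s0 passed to [fitCentroids()].
#' @return list: `model` ([CentroidModel-class]), `test_accuracy`,
#'   `test_samples`, `train_samples`.
#' @export
trainSubtypeClassifier <- function(norm, subtype_labels, gene_list,
                                   train_fraction = 2 / 3, seed = 1L,
                                   distance_kind = c("standardized",
                                                     "euclidean"),
                                   s0 = 0) {
  distance_kind <- match.arg(distance_kind)
  .assert_layer(norm, "log_normalized", "trainSubtypeClassifier")
  f <- .class_factor(subtype_labels, ncol(norm))
  if (nlevels(f) != 2L) stop("exactly two subtypes required")
  missing_genes <- setdiff(gene_list, geneIds(norm))
  if (length(missing_genes))
    stop("gene(s) absent from the matrix: ",
         paste(missing_genes, collapse = ", "))
  if (any(table(f) < 2L)) stop("each subtype needs at least 2 samples")

  train_idx <- .with_seed(seed, {
    unlist(lapply(levels(f), function(k) {
      idx <- which(f == k)
      n_tr <- min(length(idx) - 1L, max(1L, round(train_fraction * length(idx))))
      sample(idx, n_tr)
    }))
  })
  test_idx <- setdiff(seq_len(ncol(norm)), train_idx)
  X <- exprValues(norm)
  model <- fitCentroids(X[, train_idx, drop = FALSE], f[train_idx],
                        gene_list, distance_kind = distance_kind, s0 = s0)
  pred <- predict(model, X[, test_idx, drop = FALSE])
  list(model = model,
       test_accuracy = mean(pred$class == as.character(f[test_idx])),
       test_samples = sampleIds(norm)[test_idx],
       train_samples = sampleIds(norm)[train_idx])
}

#' Serialize / deserialize a CentroidModel as JSON
#'
#' @param model a [CentroidModel-class].
#' @param path file path.
#' @return `writeCentroidModel` returns `path` invisibly;
#'   `readCentroidModel` returns the model.
#' @export
writeCentroidModel <- function(model, path) {
  stopifnot(is(model, "CentroidModel"))
  jsonlite::write_json(list(
    selected_genes = model@selected_genes,
    class_labels = model@class_labels,
    centroids = model@centroids,
    pooled_sd = model@pooled_sd,
    s0 = model@s0,
    distance_kind = model@distance_kind,
    cv_trace = model@cv_trace,
    chosen_n_genes = model@chosen_n_genes
  ), path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeCentroidModel
#' @export
readCentroidModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  centroids <- as.matrix(x$centroids)
  dimnames(centroids) <- list(x$class_labels, x$selected_genes)
  cv <- as.data.frame(x$cv_trace)
  if (!nrow(cv)) cv <- data.frame(n_genes = integer(), cv_accuracy = numeric())
  new("CentroidModel",
      selected_genes = x$selected_genes, class_labels = x$class_labels,
      centroids = centroids,
      pooled_sd = setNames(as.numeric(x$pooled_sd), x$selected_genes),
      s0 = as.numeric(x$s0), distance_kind = x$distance_kind,
      cv_trace = cv, chosen_n_genes = as.integer(x$chosen_n_genes))
}
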