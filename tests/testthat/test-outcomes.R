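test_that("response rates reproduce the printed-table worked example", {
  clin <- ClinicalTable(data.frame(
    sample_id = paste0("S", 1:35),
    best_response = rep(c("CR", "PR", "SD", "PD"), c(1, 12, 6, 16)),
    clinical_benefit = rep(c(TRUE, TRUE, FALSE, FALSE), c(13, 2, 4, 16)),
    os_months = 1, os_event = TRUE, pfs_months = 1, pfs_event = TRUE,
    stringsAsFactors = FALSE))
  rr <- responseRates(clin)
  expect_identical(rr$n_evaluable, 35L)
  expect_equal(rr$orr, 13 / 35)
  expect_identical(unname(rr$percent["orr"]), 37)
  expect_identical(unname(rr$percent["disease_control"]), 54)
  expect_identical(unname(rr$percent["clinical_benefit"]), 43)

  all_pd <- small_clinical(best = rep("PD", 4), benefit = rep(FALSE, 4))
  rr0 <- responseRates(all_pd)
  expect_equal(rr0$orr, 0)
  expect_equal(rr0$disease_control, 0)
  expect_equal(rr0$clinical_benefit_rate, 0)

  na_clin <- ClinicalTable(data.frame(
    sample_id = "S1", best_response = NA_character_,
    clinical_benefit = NA, os_months = 1, os_event = TRUE,
    pfs_months = 1, pfs_event = TRUE))
  expect_error(responseRates(na_clin), "evaluable")
})

test_that("evaluable denominator excludes missing best response", {
  clin <- small_clinical(best = c("CR", "PR", NA, "PD"),
                         benefit = c(TRUE, TRUE, NA, FALSE))
  rr <- responseRates(clin)
  expect_identical(rr$n_evaluable, 3L)
  expect_equal(rr$orr, 2 / 3)
})

test_that("Kaplan-Meier matches hand product-limit computation", {
  km <- kaplanMeier(c(1, 2, 3, 4), c(TRUE, TRUE, TRUE, TRUE))
  expect_equal(survivalAt(km, 2), 0.5)
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$median, 2)

  cens <- kaplanMeier(c(1, 2, 3), c(FALSE, FALSE, FALSE))
  expect_true(all(cens$surv == 1))
  expect_true(is.na(cens$median))

  expect_error(kaplanMeier(c(-1, 2), c(TRUE, TRUE)), "negative")
})

test_that("Kaplan-Meier with interleaved censoring matches a step-by-step oracle", {
  times <- c(1, 2, 3, 4, 5, 6, 7)
  events <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE)
  km <- kaplanMeier(times, events)
  # spreadsheet-style oracle: walk the ordered times, track at-risk counts
  ord <- order(times)
  s <- 1; oracle <- c()
  at_risk <- length(times)
  for (i in ord) {
    if (events[i]) {
      s <- s * (1 - 1 / at_risk)
      oracle <- c(oracle, s)
    }
    at_risk <- at_risk - 1
  }
  expect_equal(km$surv[km$n_event > 0], oracle)
  # right-continuity of the survival query
  expect_equal(survivalAt(km, c(0.5, 1, 1.5)), c(1, oracle[1], oracle[1]))

  # no censoring: KM equals the empirical survival function exactly
  t2 <- c(3, 1, 4, 1, 5)
  km2 <- kaplanMeier(t2, rep(TRUE, 5))
  for (tt in sort(unique(t2)))
    expect_equal(survivalAt(km2, tt), mean(t2 > tt))
})

test_that("Cox regression recovers a hazard ratio of 2 and rejects no-information covariates", {
  set.seed(30)
  n <- 500
  grp <- rep(0:1, each = n / 2)
  times <- rexp(n, rate = 0.05 * 2^grp)
  fit <- coxPH(times, rep(TRUE, n), grp)
  expect_gt(fit$hr, 1.7)
  expect_lt(fit$hr, 2.3)
  expect_true(fit$ci_lower < 2 && fit$ci_upper > 2)

  expect_error(coxPH(times, rep(TRUE, n), rep(1, n)), "constant")
  expect_error(coxPH(times, rep(FALSE, n), grp), "event")

  null_hr <- replicate(10, {
    coxPH(times, rep(TRUE, n), sample(grp))$log_hr
  })
  expect_lt(mean(abs(null_hr)), 0.15)
})

test_that("log-rank test matches the observed-minus-expected table arithmetic", {
  lr0 <- logrankTest(c(1, 2, 3, 1, 2, 3), rep(TRUE, 6),
                     rep(c("a", "b"), each = 3))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)

  times <- c(1, 3, 5, 7, 2, 4, 6, 8)
  events <- rep(TRUE, 8)
  group <- rep(c("a", "b"), each = 4)
  lr <- logrankTest(times, events, group)
  # manual 2xk table arithmetic over distinct event times
  O <- 0; E <- 0; V <- 0
  for (tt in sort(unique(times))) {
    at_risk <- times >= tt
    n1 <- sum(at_risk & group == "a"); n0 <- sum(at_risk)
    d <- sum(times == tt & events)
    d1 <- sum(times == tt & events & group == "a")
    O <- O + d1
    E <- E + d * n1 / n0
    if (n0 > 1) V <- V + d * (n1 / n0) * (1 - n1 / n0) * (n0 - d) / (n0 - 1)
  }
  expect_equal(lr$chisq, (O - E)^2 / V, tolerance = 1e-9)
  expect_error(logrankTest(times, events, rep("a", 8)), "two")
})

test_that("log-rank type-I error is near nominal under the exchangeable null", {
  set.seed(31)
  rejections <- replicate(400, {
    times <- rexp(40, 0.1)
    logrankTest(times, rep(TRUE, 40), rep(c(0, 1), 20))$p < 0.05
  })
  expect_lt(abs(mean(rejections) - 0.05), 0.03)
})

test_that("Fisher exact p matches closed forms and is transpose-invariant", {
  ft <- fisherExact2x2(matrix(c(5, 0, 0, 5), 2))
  expect_equal(ft$p, 2 / choose(10, 5))

  flat <- fisherExact2x2(matrix(c(2, 2, 2, 2), 2))
  expect_equal(flat$p, 1)
  expect_equal(flat$odds_ratio, 1, tolerance = 1e-6)

  set.seed(32)
  for (rep in 1:10) {
    tab <- matrix(rpois(4, 4) + 1, 2)
    expect_equal(fisherExact2x2(tab)$p, fisherExact2x2(t(tab))$p)
  }
  expect_error(fisherExact2x2(matrix(c(0, 0, 1, 2), 2)), "margin")
  expect_error(fisherExact2x2(matrix(c(1.5, 1, 1, 1), 2)), "integers")
})

test_that("Fisher exact p matches exhaustive fixed-margin enumeration", {
  enum_p <- function(tab) {
    r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
    ks <- max(0, r1 + c1 - N):min(r1, c1)
    probs <- dhyper(ks, c1, N - c1, r1)
    p_obs <- dhyper(tab[1, 1], c1, N - c1, r1)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  set.seed(33)
  for (rep in 1:50) {
    tab <- matrix(rpois(4, 5), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisherExact2x2(tab)$p, enum_p(tab), tolerance = 1e-7)
  }
})

test_that("Kruskal-Wallis matches hand-ranked arithmetic and the two-group Wilcoxon", {
  expect_equal(kruskalWallisTest(rep(2, 9), rep(1:3, 3))$H, 0)

  values <- c(2.1, 3.5, 1.2, 4.4, 5.0, 2.8, 3.9, 6.1, 0.7)
  groups <- rep(c("a", "b", "c"), 3)
  kw <- kruskalWallisTest(values, groups)
  r <- rank(values); N <- length(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(x) length(x) * mean(x)^2)) - 3 * (N + 1)
  expect_equal(kw$H, H, tolerance = 1e-12)  # untied data: no correction
  expect_identical(kw$df, 2L)

  set.seed(34)
  x <- rnorm(12); g <- rep(c("a", "b"), 6)
  kw2 <- kruskalWallisTest(x, g)
  w <- wilcox.test(x[g == "a"], x[g == "b"], exact = FALSE,
                   correct = FALSE)$p.value
  expect_equal(kw2$p, w, tolerance = 1e-6)
  expect_error(kruskalWallisTest(x, rep("a", 12)), "two groups")
})

test_that("logistic regression recovers planted log-odds and flags degenerate fits", {
  set.seed(35)
  n <- 500
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 1.5 * x))
  fit <- adjustedLogistic(y, data.frame(x = x))
  expect_lt(abs(fit$estimate[fit$term == "x"] - 1.5), 0.3)
  expect_false(any(fit$separation))

  null_est <- replicate(20, {
    z <- rnorm(n)
    f <- adjustedLogistic(rbinom(n, 1, 0.4), data.frame(z = z))
    f$estimate[f$term == "z"]
  })
  expect_lt(abs(mean(null_est)), 0.1)

  expect_error(adjustedLogistic(rep(1, 10), data.frame(x = rnorm(10))),
               "both response classes")

  sep_x <- c(rep(0, 10), rep(1, 10))
  expect_warning(sep_fit <- adjustedLogistic(sep_x, data.frame(x = sep_x)),
                 "separation")
  expect_true(any(sep_fit$separation))
})
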