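test_that("Brier score is the mean squared forecast error", {
  expect_equal(brier_score(c(0.2, 0.7), c(0.2, 0.7)), 0)
  set.seed(1)
  o <- rbinom(40, 1, 0.5)
  expect_equal(brier_score(rep(0.5, 40), o), 0.25)
  expect_equal(brier_score(c(0.8, 0.2), c(1, 0)), 0.04)
})

test_that("weighted Spearman reduces to rank correlation and honors weights", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(weighted_spearman(x, exp(x)), 1)
  expect_equal(weighted_spearman(x, -x), -1)
  expect_equal(weighted_spearman(c(1, 2, 3), c(2, 1, 3)), 0.5)
  # equal weights recover classical Spearman, ties included
  set.seed(2)
  a <- sample(1:5, 30, replace = TRUE); b <- a + rnorm(30)
  expect_equal(weighted_spearman(a, b),
               cor(a, b, method = "spearman"), tolerance = 1e-12)
  # zero-weighting a discordant point restores perfect correlation
  expect_equal(weighted_spearman(c(1, 2, 3, 4), c(1, 2, 3, -9),
                                 w = c(1, 1, 1, 1e-12)), 1, tolerance = 1e-6)
  expect_error(weighted_spearman(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(weighted_spearman(1:2, 2:1), ">= 3")
})

test_that("ROC AUC equals all-pairs concordance, cross-checked against pROC", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1), n_boot = 0)$auc, 1)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), n_boot = 0)$auc, 0.75)
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(20:200, 1)
    s <- round(runif(n), 2)  # force ties
    l <- rbinom(n, 1, 0.3)
    if (length(unique(l)) < 2) next
    got <- roc_auc(s, l, n_boot = 0)$auc
    expect_equal(got, brute_auc(s, l), tolerance = 1e-12)
    skip_if_not_installed("pROC")
    expect_equal(got,
                 as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-10)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1), n_boot = 0), "both classes")
})

test_that("random scores give chance-level AUC with covering bootstrap CIs", {
  set.seed(5)
  s <- runif(2000); l <- rbinom(2000, 1, 0.3)
  r <- roc_auc(s, l, n_boot = 300, seed = 9)
  expect_lt(abs(r$auc - 0.5), 0.05)
  expect_true(r$ci_low < r$auc & r$auc < r$ci_high)
})

test_that("PR AUC follows the step-wise estimator with prevalence baseline", {
  expect_equal(pr_auc(c(1, 2, 3, 4), c(0, 0, 1, 1), n_boot = 0)$auc, 1)
  expect_equal(pr_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 0, 1), n_boot = 0)$auc,
               1 * 0.5 + (2 / 4) * 0.5)
  # one positive ranked last of four: single step at precision 1/4
  expect_equal(pr_auc(c(0.9, 0.8, 0.7, 0.1), c(0, 0, 0, 1), n_boot = 0)$auc, 0.25)
  set.seed(6)
  s <- runif(4000); l <- rbinom(4000, 1, 0.2)
  expect_lt(abs(pr_auc(s, l, n_boot = 0)$auc - 0.2), 0.04)
  expect_error(pr_auc(1:3, c(0, 0, 0), n_boot = 0), "positive")
})

test_that("metrics are invariant to row order", {
  set.seed(7)
  n <- 120
  s <- runif(n); l <- rbinom(n, 1, 0.4); o <- runif(n); w <- runif(n)
  perm <- sample(n)
  expect_equal(brier_score(s, o), brier_score(s[perm], o[perm]))
  expect_equal(weighted_spearman(s, o, w),
               weighted_spearman(s[perm], o[perm], w[perm]))
  expect_equal(roc_auc(s, l, n_boot = 0)$auc,
               roc_auc(s[perm], l[perm], n_boot = 0)$auc)
  expect_equal(pr_auc(s, l, n_boot = 0)$auc,
               pr_auc(s[perm], l[perm], n_boot = 0)$auc)
})

test_that("exported curve points integrate back to the reported AUCs", {
  set.seed(21)
  for (rep in 1:4) {
    n <- 80
    s <- round(runif(n), 2)
    l <- rbinom(n, 1, 0.3)
    if (length(unique(l)) < 2) next
    roc <- curve_points(s, l, type = "roc")
    expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
    expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
    trap <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
    expect_equal(trap, roc_auc(s, l, n_boot = 0)$auc, tolerance = 1e-12)

    pr <- curve_points(s, l, type = "pr")
    ap <- sum(diff(c(0, pr$recall)) * pr$precision)
    expect_equal(ap, pr_auc(s, l, n_boot = 0)$auc, tolerance = 1e-12)
  }
})

test_that("binary labels flag variants with any affected heterozygote", {
  v <- make_table(c(1L, 2L), c(1L, 0L), c(22L, 44L))
  expect_equal(binary_labels(v), c(1L, 0L))
  expect_equal(binary_labels(v, rule = "posterior", posterior = c(0.6, 0.4)),
               c(1L, 0L))
})

test_that("shrunken posteriors calibrate at least as well as the constant prior mean", {
  set.seed(8)
  for (seed in 1:5) {
    set.seed(seed)
    n <- 400
    p <- rbeta(n, 1.5, 6)
    tot <- 1 + rpois(n, 10)
    aff <- rbinom(n, tot, p)
    v <- make_table(sample.int(10000, n), aff, tot - aff)
    prior <- fit_empirical_prior(v)
    post <- empirical_posterior(v, prior = prior)
    expect_lte(brier_score(post, p), brier_score(rep(prior$mean, n), p))
  }
})

test_that("LOOCV produces one leakage-free refit per variant", {
  set.seed(10)
  v3 <- make_table(c(10L, 20L, 30L), c(2L, 1L, 0L), c(2L, 4L, 5L),
                   revel = c(0.8, 0.5, 0.2))
  res <- loocv_evaluate(v3, covariates = "revel")
  expect_equal(length(res$predictions), 3L)  # exactly one refit per variant
  expect_true(all(is.finite(res$predictions) | is.na(res$predictions)))

  n <- 40
  set.seed(11)
  x <- runif(n)
  tot <- 1 + rpois(n, 8)
  aff <- rbinom(n, tot, plogis(-2 + 2 * x))
  v <- make_table(sample.int(1000, n), aff, tot - aff, revel = x)
  res <- loocv_evaluate(v, covariates = "revel", em_args = list(max_iter = 30L))
  expect_equal(res$n_failed, 0L)
  expect_true(all(is.finite(res$predictions)))

  # changing the held-out variant's counts cannot change its prediction
  v2 <- v
  v2$affected[5L] <- v2$affected[5L] + 50L
  v2$total[5L] <- v2$total[5L] + 50L
  class(v2) <- c("variant_table", "data.frame")
  res2 <- loocv_evaluate(v2, covariates = "revel",
                         em_args = list(max_iter = 30L))
  expect_equal(res2$predictions[5L], res$predictions[5L], tolerance = 1e-10)
})

test_that("k-fold partitions are balanced, seeded, and key-stable", {
  set.seed(12)
  n <- 10
  v <- make_table(seq(5L, 50L, 5L), rbinom(n, 5, 0.3) + 1L, rpois(n, 4))
  v$revel <- runif(n)
  cv1 <- kfold_evaluate(v, k = 5, seed = 7, covariates = "revel",
                        em_args = list(max_iter = 20L))
  expect_equal(as.integer(table(cv1$folds)), rep(2L, 5))
  cv2 <- kfold_evaluate(v, k = 5, seed = 7, covariates = "revel",
                        em_args = list(max_iter = 20L))
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(cv1$pooled_spearman, cv2$pooled_spearman)

  perm <- sample(n)
  vp <- v[perm, , drop = FALSE]
  class(vp) <- c("variant_table", "data.frame")
  cv3 <- kfold_evaluate(vp, k = 5, seed = 7, covariates = "revel",
                        em_args = list(max_iter = 20L))
  expect_identical(cv3$folds, cv1$folds[perm])
  expect_equal(cv3$pooled_spearman, cv1$pooled_spearman, tolerance = 1e-10)
  expect_error(kfold_evaluate(v, k = 11), "exceeds")
})

test_that("predictor evaluation reports both allele-frequency strata", {
  set.seed(13)
  n <- 150
  x <- runif(n)
  tot <- 1 + rpois(n, 6)
  aff <- rbinom(n, tot, plogis(-2.5 + 2.5 * x))
  v <- make_table(sample.int(4000, n), aff, tot - aff, revel = x,
                  af = 10^runif(n, -7, -1))
  prior <- fit_empirical_prior(v)
  post <- empirical_posterior(v, prior = prior)
  rep <- evaluate_predictors(v, list(revel = v$revel), post,
                             n_boot = 50, seed = 3)
  expect_s3_class(rep, "evaluation_report")
  expect_setequal(rep$af_stratum, c("all", "lt_1pct"))
  expect_true(all(is.finite(rep$spearman_weighted)))
  expect_true(all(rep$roc_ci_low <= rep$roc_auc & rep$roc_auc <= rep$roc_ci_high))
})
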