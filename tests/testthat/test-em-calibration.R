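test_that("a constant response yields an intercept-only logit fit", {
  set.seed(1)
  X <- matrix(rnorm(40), 20, dimnames = list(NULL, c("a", "b")))
  co <- regress_step(X, rep(0.3, 20), rep(1, 20))
  expect_equal(unname(co["(Intercept)"]), log(0.3 / 0.7), tolerance = 1e-6)
  expect_equal(unname(co[c("a", "b")]), c(0, 0), tolerance = 1e-8)
})

test_that("a separating binary covariate reproduces the two group means", {
  g <- rep(c(0, 1), each = 10)
  resp <- ifelse(g == 1, 0.6, 0.2)
  co <- regress_step(matrix(g, ncol = 1, dimnames = list(NULL, "g")), resp,
                     rep(1, 20))
  fitted <- plogis(co["(Intercept)"] + co["g"] * c(0, 1))
  expect_equal(unname(fitted), c(0.2, 0.6), tolerance = 1e-6)
})

test_that("collinear columns are dropped with a warning", {
  set.seed(2)
  x <- rnorm(30)
  X <- cbind(a = x, b = 2 * x)
  expect_warning(co <- regress_step(X, plogis(x), rep(1, 30)), "collinear")
  expect_equal(unname(co["b"]), 0)
})

sim_em_data <- function(n, slope, seed, nu_totals = 10) {
  set.seed(seed)
  x <- rnorm(n)
  p <- plogis(-2 + slope * x)
  tot <- 1 + rpois(n, nu_totals)
  aff <- rbinom(n, tot, p)
  v <- make_table(sample.int(50 * n, n), aff, tot - aff, revel = pnorm(x))
  list(v = v, x = x, p = p)
}

test_that("EM leaves prior means at the empirical prior under pure-noise covariates", {
  set.seed(9)
  n <- 1500
  p <- rbeta(n, 1, 9)
  tot <- 1 + rpois(n, 12)
  aff <- rbinom(n, tot, p)
  v <- make_table(sample.int(50000, n), aff, tot - aff,
                  revel = runif(n), alphamissense = runif(n))
  prior <- fit_empirical_prior(v)
  fit <- em_fit(v, prior, covariates = c("revel", "alphamissense"))
  expect_true(all(abs(fit$priors$prior_mean - prior$mean) < 0.02))
})

test_that("EM recovers the sign and ranking of a real covariate effect", {
  dat <- sim_em_data(1200, slope = 3, seed = 21)
  prior <- fit_empirical_prior(dat$v)
  fit <- em_fit(dat$v, prior, covariates = "revel")
  expect_gt(fit$model$coefficients[["revel"]], 0)
  expect_gt(weighted_spearman(fit$priors$prior_mean, dat$p, dat$v$weight), 0.5)
})

test_that("EM respects its stopping rule and conserves concentration", {
  dat <- sim_em_data(200, slope = 2, seed = 4)
  prior <- fit_empirical_prior(dat$v)

  one <- em_fit(dat$v, prior, covariates = "revel", tol = Inf)
  expect_equal(one$model$n_iterations, 1L)
  expect_true(one$model$converged)

  fit <- em_fit(dat$v, prior, covariates = "revel")
  expect_true(fit$model$converged)
  expect_lt(fit$model$trajectory[fit$model$n_iterations], 1e-6)
  expect_equal(fit$priors$alpha_em + fit$priors$beta_em,
               rep(fit$model$nu, nrow(fit$priors)))
  # fixed-point scheme settles: max-change non-increasing over final stretch
  traj <- fit$model$trajectory
  if (length(traj) >= 3L) {
    last3 <- utils::tail(traj, 3L)
    expect_true(all(diff(last3) <= 1e-10))
  }
  # rerun on identical inputs reproduces every prior mean
  again <- em_fit(dat$v, prior, covariates = "revel")
  expect_equal(again$priors$prior_mean, fit$priors$prior_mean)
})

test_that("a singleton variant barely moves its own fitted prior", {
  dat <- sim_em_data(400, slope = 2, seed = 8)
  v <- dat$v
  singleton <- variant_table(99999L, "A", "W", 1L, 0L, revel = 0.95)
  with_s <- finalize_counts(merge_counts(v, singleton))
  prior <- fit_empirical_prior(v)
  fit_wo <- em_fit(v, prior, covariates = "revel")
  fit_w <- em_fit(with_s, fit_empirical_prior(with_s), covariates = "revel")
  own_w <- fit_w$priors$prior_mean[fit_w$priors$variant == "p.A99999W"]
  own_wo <- predict_prior(fit_wo$model,
                          with_s[with_s$variant == "p.A99999W", ])$prior_mean
  expect_lt(abs(own_w - own_wo) / own_wo, 0.01)
})

test_that("prior prediction is deterministic and falls back when covariates are absent", {
  dat <- sim_em_data(300, slope = 2, seed = 5)
  prior <- fit_empirical_prior(dat$v)
  fit <- em_fit(dat$v, prior, covariates = "revel")

  nd <- variant_table(c(7L, 8L), c("A", "A"), c("V", "V"), c(0L, 0L), c(0L, 0L),
                      revel = c(0.5, 0.5))
  pp <- predict_prior(fit$model, nd)
  expect_equal(pp$prior_mean[1L], pp$prior_mean[2L])
  expect_equal(pp$alpha_em + pp$beta_em, rep(fit$model$nu, 2L))

  nd2 <- variant_table(9L, "A", "V", 0L, 0L)  # no covariates at all
  pp2 <- predict_prior(fit$model, nd2)
  expect_true(pp2$empirical_backed)
  expect_equal(pp2$prior_mean, prior$mean)
})

test_that("refitting the concentration inside EM keeps it near the generative value", {
  set.seed(13)
  n <- 800
  p <- rbeta(n, 2, 8)
  tot <- 1 + rpois(n, 20)
  aff <- rbinom(n, tot, p)
  v <- make_table(sample.int(20000, n), aff, tot - aff, revel = runif(n))
  prior <- fit_empirical_prior(v)
  fit <- em_fit(v, prior, covariates = "revel", refit_nu = TRUE)
  expect_true(is.finite(fit$model$nu) && fit$model$nu > 0)
  # with no covariate signal the refit should stay close to the shared fit
  expect_lt(abs(log(fit$model$nu / prior$nu)), log(2))
  expect_equal(fit$priors$alpha_em + fit$priors$beta_em,
               rep(fit$model$nu, nrow(fit$priors)))
})

test_that("zero-variance covariates degrade to an intercept-only prior model", {
  v <- make_table(1:50, rbinom(50, 5, 0.3), 5 - rbinom(50, 5, 0.3),
                  revel = rep(0.5, 50))
  prior <- fit_empirical_prior(v)
  expect_warning(fit <- em_fit(v, prior, covariates = "revel"), "zero variance")
  expect_equal(length(fit$model$stats$kept), 0L)
  expect_equal(length(unique(round(fit$priors$prior_mean, 10))), 1L)
})
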