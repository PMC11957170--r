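#' Beta prior parameters
#'
#' A beta distribution `Beta(alpha, beta)` acting as a penetrance prior,
#' either the shared empirical prior fitted across all variants or a
#' variant-specific calibrated prior.
#'
#' @param alpha,beta positive shape parameters.
#' @return An object of class `beta_params` with fields `alpha`, `beta`,
#'   `mean = alpha/(alpha+beta)` and concentration `nu = alpha+beta`.
#' @export
beta_params <- function(alpha, beta) {
  if (!is.finite(alpha) || !is.finite(beta) || alpha <= 0 || beta <= 0)
    stop("beta parameters must be finite and positive", call. = FALSE)
  structure(list(alpha = alpha, beta = beta,
                 mean = alpha / (alpha + beta), nu = alpha + beta),
            class = "beta_params")
}

#' @export
print.beta_params <- function(x, ...) {
  cat(sprintf("Beta prior: alpha = %.4g, beta = %.4g (mean %.4f, concentration %.4g)\n",
              x$alpha, x$beta, x$mean, x$nu))
  invisible(x)
}

#' Weighted mean observed penetrance
#'
#' The evidence-weighted average of per-variant observed penetrance,
#' `sum(p_i w_i) / sum(w_i)`. This is the mean of the shared empirical
#' prior: with weights normalized, heavily observed variants dominate while
#' singletons contribute almost nothing.
#'
#' @param variants a [variant_table()] with positive totals and weights.
#' @return A single number in `(0, 1)` (or exactly 0/1 in degenerate tables).
#' @export
weighted_prior_mean <- function(variants) {
  stopifnot(inherits(variants, "variant_table"))
  v <- variants[variants$total >= 1L, , drop = FALSE]
  if (nrow(v) == 0L) stop("no variants with observed heterozygotes", call. = FALSE)
  if (sum(v$weight) <= 0) stop("all evidence weights are zero", call. = FALSE)
  p <- v$affected / v$total
  sum(p * v$weight) / sum(v$weight)
}

# Weighted leave-one-heterozygote-out squared prediction error as a
# function of the concentration nu. Each heterozygote of variant i is
# predicted by the beta-binomial posterior built from the variant's
# remaining counts and the shared prior; with the true prior this predictor
# is Bayes-optimal for a held-out observation, so the criterion has an
# interior minimum at the generative concentration. (Scoring the full
# Eq.-3 posterior against observed penetrance instead is monotone in nu —
# the posterior reproduces the observed fraction exactly as nu -> 0 — and
# cannot identify the concentration.)
# `loo` additionally removes variant i from the prior-mean estimate.
prior_mse <- function(nu, p, a, n, w, loo = TRUE) {
  S <- sum(p * w); W <- sum(w)
  mu <- if (loo) {
    den <- W - w
    ifelse(den > 0, (S - p * w) / den, S / W)
  } else rep(S / W, length(p))
  # prediction for a held-out affected (f1) / unaffected (f0) heterozygote
  f1 <- (a - 1 + mu * nu) / (n - 1 + nu)
  f0 <- (a + mu * nu) / (n - 1 + nu)
  per_het <- (a * (1 - f1)^2 + (n - a) * f0^2) / n
  sum(w * per_het) / W
}

#' Fit the shared empirical beta prior
#'
#' The prior mean is fixed to the evidence-weighted average of observed
#' penetrance ([weighted_prior_mean()]); the concentration `nu` is then
#' chosen to minimize the weighted mean squared error of cross-validated
#' posterior predictions: each heterozygote is predicted by the
#' beta-binomial posterior formed from the variant's remaining counts and
#' the shared prior. This is a proper squared-error criterion whose
#' population minimizer is the generative concentration; scoring the full
#' conjugate posterior against observed penetrance instead is monotone in
#' `nu` and cannot identify it. By default the prior mean entering variant
#' `i`'s predictions also excludes variant `i` (leave-one-out), removing
#' self-fit optimism; `loo = FALSE` keeps the in-sample mean.
#'
#' @param variants a [variant_table()] with at least two variants with
#'   observed heterozygotes.
#' @param loo logical; hold each variant out of the prior mean (default)
#'   or use the in-sample mean throughout.
#' @param nu_range search interval for the concentration (log-scale bounded
#'   minimization; a log-spaced grid fallback covers optimizer failure).
#' @param joint logical; if `TRUE`, jointly minimize over (mean, nu) instead
#'   of fixing the mean to the weighted average.
#' @return A [beta_params()] with attributes `mse` (criterion at optimum)
#'   and `method`.
#' @export
fit_empirical_prior <- function(variants, loo = TRUE, nu_range = c(0.1, 1e4),
                                joint = FALSE) {
  stopifnot(inherits(variants, "variant_table"))
  v <- variants[variants$total >= 1L, , drop = FALSE]
  if (nrow(v) < 2L) stop("need >= 2 variants with observed heterozygotes", call. = FALSE)
  p <- v$affected / v$total
  a <- v$affected; n <- v$total; w <- v$weight
  if (sum(w) <= 0) stop("all evidence weights are zero", call. = FALSE)
  mu <- sum(p * w) / sum(w)

  if (joint) {
    # Free (mean, nu) under the same leave-one-heterozygote-out criterion.
    obj <- function(par) {
      m <- inv_logit(par[1L]); nu <- exp(par[2L])
      f1 <- (a - 1 + m * nu) / (n - 1 + nu)
      f0 <- (a + m * nu) / (n - 1 + nu)
      sum(w * (a * (1 - f1)^2 + (n - a) * f0^2) / n) / sum(w)
    }
    fit <- stats::optim(c(logit(clip01(mu)), log(10)), obj, method = "Nelder-Mead")
    m <- inv_logit(fit$par[1L]); nu <- exp(fit$par[2L])
    out <- beta_params(m * nu, (1 - m) * nu)
    attr(out, "mse") <- fit$value; attr(out, "method") <- "joint-nelder-mead"
    return(out)
  }

  f <- function(lnu) prior_mse(exp(lnu), p, a, n, w, loo = loo)
  opt <- tryCatch(
    stats::optimize(f, interval = log(nu_range), tol = 1e-6),
    error = function(e) NULL
  )
  if (is.null(opt) || !is.finite(opt$objective)) {
    grid <- exp(seq(log(nu_range[1L]), log(nu_range[2L]), length.out = 400L))
    mse <- vapply(grid, prior_mse, 0, p = p, a = a, n = n, w = w, loo = loo)
    nu <- grid[which.min(mse)]
    warning("bounded minimization failed; falling back to log-spaced grid search over nu")
    out <- beta_params(mu * nu, (1 - mu) * nu)
    attr(out, "mse") <- min(mse); attr(out, "method") <- "grid"
    return(out)
  }
  nu <- exp(opt$minimum)
  out <- beta_params(mu * nu, (1 - mu) * nu)
  attr(out, "mse") <- opt$objective
  attr(out, "method") <- if (loo) "loo-mse" else "in-sample-mse"
  out
}

#' Empirical posterior penetrance
#'
#' Conjugate beta-binomial update of the shared empirical prior with a
#' variant's observed counts:
#' `(affected + alpha_prior) / (total + alpha_prior + beta_prior)`.
#' With no observations this returns the prior mean; as counts grow it
#' converges to the observed penetrance.
#'
#' @param affected,unaffected non-negative counts (vectorized), or a
#'   [variant_table()] as `affected`.
#' @param prior a [beta_params()].
#' @return Posterior mean penetrance in `(0, 1)`.
#' @export
empirical_posterior <- function(affected, unaffected = NULL, prior) {
  if (inherits(affected, "variant_table")) {
    unaffected <- affected$unaffected
    affected <- affected$affected
  }
  stopifnot(inherits(prior, "beta_params"))
  (affected + prior$alpha) / (affected + unaffected + prior$alpha + prior$beta)
}

#' Equal-tailed beta credible interval
#'
#' @param alpha,beta posterior beta shape parameters (vectorized).
#' @param level interval mass in `(0, 1)`; default 0.95.
#' @return A two-column matrix `low`, `high` of beta quantiles.
#' @export
credible_interval <- function(alpha, beta, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  tail <- (1 - level) / 2
  cbind(low = stats::qbeta(tail, alpha, beta),
        high = stats::qbeta(1 - tail, alpha, beta))
}
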