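#' Covariate-calibrated variant-specific priors (EM)
#'
#' Starting from the shared empirical prior, variant-specific priors are
#' produced by iterating: (a) weighted regression of current penetrance
#' point estimates (on the logit scale) on variant covariates; (b) mapping
#' fitted means back to beta priors `(p*nu, (1-p)*nu)` with the concentration
#' `nu` carried from the empirical prior; (c) conjugate update of those
#' priors with observed counts to refresh the point estimates. Iteration
#' stops when no fitted prior mean moves by more than `tol`.
#'
#' @name em_calibration
NULL

default_covariates <- c("density", "revel", "alphamissense", "clinvar")

# Raw (unstandardized) covariate matrix, NAs preserved.
covariate_matrix <- function(variants, covariates) {
  if (length(covariates) == 0L)
    return(matrix(numeric(0), nrow(variants), 0L))
  cols <- lapply(covariates, function(nm) {
    switch(nm,
           clinvar = encode_clinvar(variants$clinvar),
           {
             if (!nm %in% names(variants))
               stop(sprintf("unknown covariate '%s'", nm), call. = FALSE)
             as.numeric(variants[[nm]])
           })
  })
  m <- do.call(cbind, cols)
  colnames(m) <- covariates
  m
}

# Weighted standardization + mean imputation with missingness indicators.
# `stats` from a training call reapplies the same transform to new data.
prepare_design <- function(raw, w, stats = NULL) {
  if (is.null(stats)) {
    stats <- list(impute = numeric(0), center = numeric(0), scale = numeric(0),
                  kept = character(0), indicator = character(0))
    for (j in colnames(raw)) {
      x <- raw[, j]; ok <- !is.na(x)
      if (!any(ok)) next  # covariate absent everywhere: drop
      imp <- sum(x[ok] * w[ok]) / sum(w[ok])
      xf <- ifelse(ok, x, imp)
      mu <- sum(xf * w) / sum(w)
      sd <- sqrt(weighted_var(xf, w))
      if (sd < 1e-10) {
        warning(sprintf("covariate '%s' has zero variance; dropped", j))
        next
      }
      stats$impute[j] <- imp; stats$center[j] <- mu; stats$scale[j] <- sd
      stats$kept <- c(stats$kept, j)
      if (any(!ok)) stats$indicator <- c(stats$indicator, j)
    }
  }
  if (length(stats$kept) == 0L)
    return(list(X = matrix(0, nrow(raw), 0L), stats = stats))
  X <- sapply(stats$kept, function(j) {
    x <- raw[, j]
    x[is.na(x)] <- stats$impute[[j]]
    (x - stats$center[[j]]) / stats$scale[[j]]
  })
  X <- matrix(X, nrow = nrow(raw), dimnames = list(NULL, stats$kept))
  for (j in stats$indicator)
    X <- cbind(X, structure(as.numeric(is.na(raw[, j])), class = NULL))
  if (length(stats$indicator))
    colnames(X)[(length(stats$kept) + 1L):ncol(X)] <-
      paste0("missing_", stats$indicator)
  list(X = X, stats = stats)
}

#' Single weighted regression step on the logit scale
#'
#' Weighted least squares of `logit(response)` (responses clipped to
#' `[eps, 1-eps]`) on a design matrix with intercept. Collinear columns are
#' dropped (coefficient set to zero) with a warning.
#'
#' @param X numeric design matrix without intercept (standardized covariates).
#' @param response per-variant values in `(0, 1)`.
#' @param weights per-variant non-negative regression weights.
#' @param eps clipping bound for the logit transform.
#' @return Named coefficient vector (`(Intercept)` first).
#' @export
regress_step <- function(X, response, weights, eps = 1e-4) {
  y <- logit(clip01(response, eps))
  D <- cbind(`(Intercept)` = 1, X)
  fit <- stats::lm.wfit(D, y, w = weights)
  coefs <- fit$coefficients
  if (anyNA(coefs)) {
    warning(sprintf("collinear design: dropping %s",
                    paste(names(coefs)[is.na(coefs)], collapse = ", ")))
    coefs[is.na(coefs)] <- 0
  }
  coefs
}

#' Fit variant-specific priors by EM
#'
#' @param variants a finalized [variant_table()] (totals >= 1, weights set).
#' @param empirical_prior a [beta_params()] from [fit_empirical_prior()].
#' @param covariates character vector of covariate names among
#'   `"density"`, `"revel"`, `"alphamissense"`, `"clinvar"` (or any numeric
#'   column of the table). Missing values are mean-imputed with a
#'   missingness indicator.
#' @param tol convergence tolerance on the largest change in any fitted
#'   prior mean between iterations.
#' @param max_iter iteration cap.
#' @param eps clipping bound keeping responses strictly inside (0, 1).
#' @param nu concentration for the variant priors; defaults to the
#'   empirical prior's concentration (uncertainty calibrated once, means
#'   recalibrated per variant).
#' @param refit_nu if `TRUE`, the concentration is re-optimized each
#'   iteration under the current variant-specific prior means (same
#'   held-out per-heterozygote squared-error criterion as
#'   [fit_empirical_prior()]).
#' @return A list with `model` (class `em_model`: coefficients,
#'   standardization stats, `nu`, iteration trace, convergence flag) and
#'   `priors` (data.frame: variant key, `alpha_em`, `beta_em`, `prior_mean`).
#' @export
em_fit <- function(variants, empirical_prior,
                   covariates = default_covariates,
                   tol = 1e-6, max_iter = 100L, eps = 1e-4, nu = NULL,
                   refit_nu = FALSE) {
  stopifnot(inherits(variants, "variant_table"),
            inherits(empirical_prior, "beta_params"))
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  v <- variants[variants$total >= 1L, , drop = FALSE]
  if (nrow(v) < 2L) stop("need >= 2 variants with observations", call. = FALSE)
  nu <- nu %||% empirical_prior$nu
  w <- v$weight
  raw <- covariate_matrix(v, covariates)
  des <- prepare_design(raw, w)
  X <- des$X

  r <- empirical_posterior(v$affected, v$unaffected, empirical_prior)
  p_hat_prev <- r
  trajectory <- numeric(0)
  converged <- FALSE
  coefs <- NULL
  for (it in seq_len(max_iter)) {
    coefs <- regress_step(X, r, w, eps = eps)
    eta <- drop(cbind(1, X) %*% coefs)
    # least squares on the logit scale is mean-biased (Jensen): recenter the
    # intercept so the weighted mean of fitted priors matches the responses,
    # anchoring the ensemble penetrance rate at the empirical prior
    target <- sum(w * r) / sum(w)
    delta <- stats::uniroot(function(d)
      sum(w * inv_logit(eta + d)) / sum(w) - target,
      interval = c(-15, 15), tol = 1e-10)$root
    coefs[1L] <- coefs[1L] + delta
    p_hat <- clip01(inv_logit(eta + delta), eps)
    if (any(!is.finite(p_hat))) {
      bad <- which(!is.finite(p_hat))
      stop(sprintf("EM produced non-finite fitted values for variant(s) %s",
                   paste(utils::head(v$variant[bad], 5L), collapse = ", ")),
           call. = FALSE)
    }
    if (refit_nu) {
      crit <- function(lnu) {
        nv <- exp(lnu)
        f1 <- (v$affected - 1 + p_hat * nv) / (v$total - 1 + nv)
        f0 <- (v$affected + p_hat * nv) / (v$total - 1 + nv)
        sum(w * (v$affected * (1 - f1)^2 + (v$total - v$affected) * f0^2) /
              v$total) / sum(w)
      }
      nu <- exp(stats::optimize(crit, interval = log(c(0.1, 1e4)),
                                tol = 1e-6)$minimum)
    }
    delta <- max(abs(p_hat - p_hat_prev))
    trajectory <- c(trajectory, delta)
    p_hat_prev <- p_hat
    r <- (v$affected + nu * p_hat) / (v$total + nu)
    if (delta < tol) { converged <- TRUE; break }
  }
  model <- structure(list(
    coefficients = coefs, stats = des$stats, nu = nu,
    covariates = covariates, eps = eps,
    empirical_prior = empirical_prior,
    n_iterations = length(trajectory), converged = converged,
    trajectory = trajectory
  ), class = "em_model")
  priors <- data.frame(variant = v$variant, position = v$position,
                       ref = v$ref, alt = v$alt,
                       alpha_em = p_hat_prev * nu, beta_em = (1 - p_hat_prev) * nu,
                       prior_mean = p_hat_prev,
                       stringsAsFactors = FALSE)
  list(model = model, priors = priors)
}

#' @export
print.em_model <- function(x, ...) {
  cat(sprintf("<em_model> %d iterations (%s), nu = %.4g\ncoefficients:\n",
              x$n_iterations, if (x$converged) "converged" else "not converged",
              x$nu))
  print(x$coefficients)
  invisible(x)
}

#' Predict variant-specific priors from a fitted EM model
#'
#' Applies the fitted regression to new covariates (standardized and
#' imputed with the training statistics), inverse-logit, clips, and scales
#' by the model concentration. Rows with every covariate missing fall back
#' to the empirical prior mean and are flagged.
#'
#' @param model an `em_model` from [em_fit()].
#' @param newdata a [variant_table()] or data.frame carrying the model's
#'   covariate columns.
#' @return data.frame with `alpha_em`, `beta_em`, `prior_mean` and logical
#'   `empirical_backed` per row.
#' @export
predict_prior <- function(model, newdata) {
  stopifnot(inherits(model, "em_model"))
  raw <- covariate_matrix(newdata, model$covariates)
  all_missing <- if (ncol(raw) > 0L) apply(raw, 1L, function(z) all(is.na(z)))
                 else rep(FALSE, nrow(raw))
  X <- prepare_design(raw, w = rep(1, nrow(raw)), stats = model$stats)$X
  p <- clip01(inv_logit(drop(cbind(1, X) %*% model$coefficients)), model$eps)
  p[all_missing] <- model$empirical_prior$mean
  data.frame(alpha_em = p * model$nu, beta_em = (1 - p) * model$nu,
             prior_mean = p, empirical_backed = all_missing,
             stringsAsFactors = FALSE)
}
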