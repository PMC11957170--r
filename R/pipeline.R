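#' Run the full penetrance pipeline
#'
#' Convenience wrapper: finalize counts, (optionally) compute the
#' leave-self-out structural density covariate, fit the shared empirical
#' prior, calibrate variant-specific priors by EM, form Bayesian posteriors,
#' average per residue, and scan for hot-spots.
#'
#' @param variants a [variant_table()].
#' @param residues optional `residue_coords` for the density covariate.
#' @param covariates covariate names for [em_fit()]; `"density"` is used
#'   only when `residues` is supplied (or the table already carries a
#'   density column).
#' @param radius density neighborhood radius (angstroms).
#' @param hotspot_window,hotspot_min_mean,hotspot_min_variants thresholds
#'   for [scan_hotspots()].
#' @param em_args extra arguments to [em_fit()].
#' @return List of class `penbayes_fit`: `variants`, `empirical_prior`,
#'   `em` (model + priors), `estimates`, `residue_map`, `hotspots`.
#' @export
run_pipeline <- function(variants, residues = NULL,
                         covariates = default_covariates, radius = 15,
                         hotspot_window = 100L, hotspot_min_mean = 0.4,
                         hotspot_min_variants = 4L, em_args = list()) {
  v <- finalize_counts(variants)
  if (!is.null(residues)) {
    dens <- density_covariate(residues, v, radius = radius, leave_out = TRUE)
    v$density <- as.numeric(dens)
  } else if (all(is.na(v$density))) {
    covariates <- setdiff(covariates, "density")
  }
  drop_all_na <- vapply(setdiff(covariates, "clinvar"), function(nm)
    nm %in% names(v) && all(is.na(v[[nm]])), TRUE)
  covariates <- setdiff(covariates, setdiff(covariates, "clinvar")[drop_all_na])
  prior <- fit_empirical_prior(v)
  fit <- do.call(em_fit, c(list(variants = v, empirical_prior = prior,
                                covariates = covariates), em_args))
  estimates <- bayesian_posterior(v, fit$priors)
  residue_map <- residue_mean_penetrance(estimates)
  hotspots <- scan_hotspots(residue_map, v$position, window = hotspot_window,
                            min_mean = hotspot_min_mean,
                            min_variants = hotspot_min_variants)
  structure(list(variants = v, empirical_prior = prior, em = fit,
                 estimates = estimates, residue_map = residue_map,
                 hotspots = hotspots),
            class = "penbayes_fit")
}

#' @export
print.penbayes_fit <- function(x, ...) {
  cat(sprintf("<penbayes_fit> %d variants\n", nrow(x$variants)))
  print(x$empirical_prior)
  cat(sprintf("EM: %d iterations, %d hot-spot segment(s)\n",
              x$em$model$n_iterations, nrow(x$hotspots)))
  invisible(x)
}

#' Write a run manifest
#'
#' Records configuration, seed, prior parameters, EM coefficients and
#' convergence trace, and the package version, as JSON alongside outputs so
#' every result file is reproducible from config + seed.
#'
#' @param fit a `penbayes_fit`.
#' @param path output JSON path.
#' @param seed seed used for the run.
#' @param config optional configuration list to embed.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(fit, path, seed = NA_integer_, config = NULL) {
  m <- list(
    package = "penbayes",
    version = as.character(utils::packageVersion("penbayes")),
    seed = seed,
    empirical_prior = list(alpha = fit$empirical_prior$alpha,
                           beta = fit$empirical_prior$beta,
                           mean = fit$empirical_prior$mean,
                           nu = fit$empirical_prior$nu),
    em = list(coefficients = as.list(fit$em$model$coefficients),
              nu = fit$em$model$nu,
              n_iterations = fit$em$model$n_iterations,
              converged = fit$em$model$converged,
              trajectory = fit$em$model$trajectory),
    n_variants = nrow(fit$variants),
    config = config
  )
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
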