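#' Simulation configuration
#'
#' Defines the generative model for synthetic variant tables: per-variant
#' true penetrance drawn from a beta baseline on the logit scale, shifted by
#' covariate effects and positional cluster boosts; heterozygote totals are
#' heavily right-skewed (a large singleton fraction, the rest shifted
#' Poisson), and affected counts are binomial in the true penetrance —
#' exactly the structure the beta-binomial model assumes, so recovery tests
#' have a known truth.
#'
#' @param n_variants number of variants (default 2000).
#' @param protein_length residues in the toy protein (default 500).
#' @param prior_alpha,prior_beta generative beta for baseline penetrance
#'   (default `Beta(1, 60)`, a rare-disease scale with heavy mass near 0).
#' @param covariate_effects named numeric vector of logit-scale slopes for
#'   latent standard-normal covariates (default `c(revel = 1,
#'   alphamissense = 1)`); the stored scores are noisy probit transforms of
#'   the latents, so stored covariates correlate with, but do not determine,
#'   the truth.
#' @param covariate_noise_sd sd of the noise added before the probit
#'   transform (default 0.5).
#' @param singleton_fraction fraction of variants observed in exactly one
#'   heterozygote (default 0.6).
#' @param mean_total_nonsingleton mean heterozygote total among
#'   non-singletons; totals are `1 + Poisson(mean - 1)` (default 21).
#' @param cluster_spec list of `c(center, spread, boost)` triples adding a
#'   Gaussian bump `boost * exp(-(pos-center)^2 / (2 spread^2))` to the
#'   logit of penetrance — three loci by default, to exercise the hot-spot
#'   and density modules.
#' @param clinvar_fraction fraction of variants carrying a ClinVar class
#'   (assigned from true penetrance with 15% label noise; default 0.5).
#' @param structure logical; also grow a toy self-avoiding 3D chain.
#' @param seed RNG seed; generation is a pure function of (config, seed).
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_variants = 2000L, protein_length = 500L,
                              prior_alpha = 1, prior_beta = 60,
                              covariate_effects = c(revel = 1, alphamissense = 1),
                              covariate_noise_sd = 0.5,
                              singleton_fraction = 0.6,
                              mean_total_nonsingleton = 21,
                              cluster_spec = list(c(100, 10, 2),
                                                  c(250, 15, 1.5),
                                                  c(400, 10, 2)),
                              clinvar_fraction = 0.5,
                              structure = TRUE, seed = 1L) {
  if (singleton_fraction < 0 || singleton_fraction > 1)
    stop("singleton_fraction must lie in [0, 1]", call. = FALSE)
  if (prior_alpha <= 0 || prior_beta <= 0)
    stop("generative beta parameters must be positive", call. = FALSE)
  if (mean_total_nonsingleton < 1)
    stop("mean_total_nonsingleton must be >= 1", call. = FALSE)
  for (cl in cluster_spec)
    if (length(cl) != 3L || cl[2L] <= 0)
      stop("each cluster spec is c(center, spread > 0, boost)", call. = FALSE)
  structure(list(
    n_variants = as.integer(n_variants), protein_length = as.integer(protein_length),
    prior_alpha = prior_alpha, prior_beta = prior_beta,
    covariate_effects = covariate_effects, covariate_noise_sd = covariate_noise_sd,
    singleton_fraction = singleton_fraction,
    mean_total_nonsingleton = mean_total_nonsingleton,
    cluster_spec = cluster_spec, clinvar_fraction = clinvar_fraction,
    structure = structure, seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Generate a synthetic variant dataset
#'
#' @param config a [simulation_config()].
#' @return List of class `synthetic_dataset`: `variants` (a finalized
#'   [variant_table()]), `true_penetrance`, `latents` (the noise-free
#'   covariate latents), `structure` (toy `residue_coords` or `NULL`),
#'   `config`.
#' @export
generate <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_variants
  L <- config$protein_length
  if (n > 19L * L)
    stop("n_variants exceeds the number of distinct missense variants", call. = FALSE)

  protein <- sample(amino_acids, L, replace = TRUE)
  space <- enumerate_missense(L, reference = protein)
  pick <- sample(nrow(space), n)
  pos <- space$position[pick]; ref <- space$ref[pick]; alt <- space$alt[pick]

  base <- stats::rbeta(n, config$prior_alpha, config$prior_beta)
  eta <- logit(clip01(base, 1e-6))
  latents <- NULL
  effects <- config$covariate_effects
  if (length(effects) > 0L) {
    latents <- matrix(stats::rnorm(n * length(effects)), n,
                      dimnames = list(NULL, names(effects)))
    eta <- eta + drop(latents %*% effects)
  }
  for (cl in config$cluster_spec)
    eta <- eta + cl[3L] * exp(-(pos - cl[1L])^2 / (2 * cl[2L]^2))
  true_pen <- inv_logit(eta)

  singleton <- stats::runif(n) < config$singleton_fraction
  total <- ifelse(singleton, 1L,
                  1L + stats::rpois(n, config$mean_total_nonsingleton - 1))
  affected <- stats::rbinom(n, total, true_pen)

  scores <- list(revel = NA_real_, alphamissense = NA_real_)
  for (nm in intersect(names(effects), names(scores)))
    scores[[nm]] <- stats::pnorm(latents[, nm] +
                                   stats::rnorm(n, 0, config$covariate_noise_sd))

  has_cv <- stats::runif(n) < config$clinvar_fraction
  flip <- stats::runif(n) < 0.15
  likely_path <- xor(true_pen > 0.2, flip)
  clinvar <- ifelse(!has_cv, "absent",
                    ifelse(likely_path, "P/LP",
                           ifelse(stats::runif(n) < 0.5, "VUS", "B/LB")))

  af <- pmin(total / 6e5, 0.05)

  variants <- variant_table(pos, ref, alt, affected, total - affected,
                            af = af, revel = scores$revel,
                            alphamissense = scores$alphamissense,
                            clinvar = clinvar)
  variants <- finalize_counts(variants)

  struct <- if (isTRUE(config$structure))
    generate_toy_structure(L, seed = config$seed + 1L) else NULL

  structure(list(variants = variants, true_penetrance = true_pen,
                 latents = latents, structure = struct, config = config),
            class = "synthetic_dataset")
}

#' Grow a toy self-avoiding 3D residue chain
#'
#' Consecutive C-alpha spacing 3.8 angstroms; any non-consecutive pair is
#' kept at least 4 angstroms apart by per-step rejection with restarts.
#' The chain is writable as a PDB file ([write_toy_pdb()]) so the structure
#' reader and the density module can be exercised without real data.
#'
#' @param length number of residues (>= 2).
#' @param seed RNG seed.
#' @param max_restarts chain-level restarts before giving up.
#' @return `residue_coords` data.frame (positions `1..length`, chain "A").
#' @export
generate_toy_structure <- function(length, seed = 1L, max_restarts = 200L) {
  stopifnot(length >= 2L)
  set.seed(seed)
  step <- 3.8; min_sep <- 4.0
  rand_dir <- function() {
    z <- stats::runif(1, -1, 1); phi <- stats::runif(1, 0, 2 * pi)
    r <- sqrt(1 - z^2)
    c(r * cos(phi), r * sin(phi), z)
  }
  for (attempt in seq_len(max_restarts)) {
    xyz <- matrix(0, length, 3L)
    xyz[2L, ] <- step * rand_dir()
    ok <- TRUE
    i <- 3L
    while (i <= length) {
      placed <- FALSE
      for (try in 1:60) {
        cand <- xyz[i - 1L, ] + step * rand_dir()
        d2 <- rowSums((xyz[1:(i - 2L), , drop = FALSE] -
                         matrix(cand, i - 2L, 3L, byrow = TRUE))^2)
        if (all(d2 >= min_sep^2)) { xyz[i, ] <- cand; placed <- TRUE; break }
      }
      if (!placed) { ok <- FALSE; break }
      i <- i + 1L
    }
    if (ok) {
      out <- data.frame(position = seq_len(length), chain = "A",
                        x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                        stringsAsFactors = FALSE)
      class(out) <- c("residue_coords", "data.frame")
      return(out)
    }
  }
  stop("failed to grow a self-avoiding chain; increase max_restarts", call. = FALSE)
}

#' Write residue coordinates as a one-atom-per-residue PDB file
#'
#' @param coords a `residue_coords` data.frame.
#' @param path output PDB path.
#' @param b optional per-residue B-factor values.
#' @return `path`, invisibly.
#' @export
write_toy_pdb <- function(coords, path, b = NULL) {
  n <- nrow(coords)
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(coords[, c("x", "y", "z")]))),
    resno = coords$position, chain = coords$chain,
    resid = rep("ALA", n), elety = rep("CA", n),
    o = rep(1, n), b = b %||% rep(0, n)
  )
  invisible(path)
}

#' Parameter-recovery harness
#'
#' Runs the full pipeline (generate, fit empirical prior, EM calibration)
#' across seeds and summarizes how well the generative truth is recovered:
#' bias and RMSE of the fitted prior mean against the mean true penetrance,
#' the sign-recovery rate of each covariate effect, and the rank correlation
#' between fitted prior means and true penetrance.
#'
#' @param config a [simulation_config()] (its seed is replaced per run).
#' @param n_seeds number of independent runs.
#' @param seeds optional explicit seed vector.
#' @return data.frame with one row per seed: `seed`, `prior_mean_hat`,
#'   `prior_mean_true`, `bias`, `rmse_posterior`, `rank_corr`,
#'   `sign_<effect>` columns.
#' @export
recovery_harness <- function(config = simulation_config(), n_seeds = 5L,
                             seeds = NULL) {
  seeds <- seeds %||% seq_len(n_seeds)
  covs <- names(config$covariate_effects)
  rows <- lapply(seeds, function(s) {
    cfg <- config; cfg$seed <- s; cfg$structure <- FALSE
    dat <- generate(cfg)
    v <- dat$variants
    truth <- dat$true_penetrance  # totals >= 1 by construction: no rows dropped
    prior <- fit_empirical_prior(v)
    fit <- em_fit(v, prior, covariates = covs)
    est <- bayesian_posterior(v, fit$priors)
    w <- v$weight
    truth_mean <- sum(truth * w) / sum(w)
    row <- data.frame(
      seed = s,
      prior_mean_hat = prior$mean,
      prior_mean_true = truth_mean,
      bias = prior$mean - truth_mean,
      rmse_posterior = sqrt(mean((est$posterior_mean - truth)^2)),
      rank_corr = weighted_spearman(fit$priors$prior_mean, truth, w)
    )
    for (nm in covs)
      row[[paste0("sign_", nm)]] <-
        sign(fit$model$coefficients[[nm]]) == sign(config$covariate_effects[[nm]])
    row
  })
  do.call(rbind, rows)
}
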