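#' Brier score
#'
#' Mean squared difference between probabilistic forecasts and outcomes,
#' `mean((f - o)^2)`. Lower is better; a perfect forecast scores 0 and a
#' constant 0.5 forecast against binary outcomes scores 0.25.
#'
#' @param forecasts,outcomes numeric vectors in `[0, 1]` of equal length.
#' @return A single non-negative number.
#' @export
brier_score <- function(forecasts, outcomes) {
  stopifnot(length(forecasts) == length(outcomes), length(forecasts) >= 1L)
  mean((forecasts - outcomes)^2)
}

#' Weighted Spearman rank correlation
#'
#' Weighted Pearson correlation of mid-ranks (average ranks for ties).
#' With equal weights this is the classical Spearman coefficient.
#'
#' @param x,y numeric vectors; pairs with a missing value are dropped.
#' @param w non-negative weights (default equal).
#' @return Correlation in `[-1, 1]`.
#' @export
weighted_spearman <- function(x, y, w = rep(1, length(x))) {
  keep <- is.finite(x) & is.finite(y) & is.finite(w)
  x <- x[keep]; y <- y[keep]; w <- w[keep]
  if (length(x) < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  wn <- w / sum(w)
  mx <- sum(wn * rx); my <- sum(wn * ry)
  vx <- sum(wn * (rx - mx)^2); vy <- sum(wn * (ry - my)^2)
  if (vx <= 0 || vy <= 0)
    stop("undefined correlation: zero variance in ranks", call. = FALSE)
  sum(wn * (rx - mx) * (ry - my)) / sqrt(vx * vy)
}

mann_whitney_auc <- function(scores, labels) {
  pos <- labels == 1
  r <- rank(scores, ties.method = "average")
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

average_precision <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # group tied scores so a tie block enters the curve as one threshold step
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(1 - l)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]
  P <- sum(l)
  prec <- tp / (tp + fp)
  dtp <- diff(c(0, tp))
  sum(dtp / P * prec)
}

boot_ci <- function(stat, scores, labels, n_boot, seed, level = 0.95) {
  set.seed(seed)
  ip <- which(labels == 1); in0 <- which(labels == 0)
  vals <- vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(ip, length(ip), replace = TRUE),
             sample(in0, length(in0), replace = TRUE))
    stat(scores[idx], labels[idx])
  }, 0)
  tail <- (1 - level) / 2
  stats::quantile(vals, c(tail, 1 - tail), names = FALSE, na.rm = TRUE)
}

#' ROC AUC with bootstrap confidence interval
#'
#' AUC by the concordance (Mann-Whitney) formulation: the probability a
#' random positive outranks a random negative, ties counted one half.
#' The confidence interval is a stratified percentile bootstrap
#' (resampling positives and negatives separately).
#'
#' @param scores numeric predictor values.
#' @param labels binary 0/1 outcomes; both classes must be present.
#' @param n_boot bootstrap resamples (default 2000; set 0 to skip the CI).
#' @param seed RNG seed for the bootstrap.
#' @param level CI level.
#' @return List `auc`, `ci_low`, `ci_high`.
#' @export
roc_auc <- function(scores, labels, n_boot = 2000L, seed = 1L, level = 0.95) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("ROC AUC requires both classes present", call. = FALSE)
  auc <- mann_whitney_auc(scores, labels)
  ci <- if (n_boot > 0) boot_ci(mann_whitney_auc, scores, labels, n_boot, seed, level)
        else c(NA_real_, NA_real_)
  list(auc = auc, ci_low = ci[1L], ci_high = ci[2L])
}

#' Precision-recall AUC with bootstrap confidence interval
#'
#' Area under the precision-recall curve by the step-wise
#' (interpolation-free) average-precision estimator, with tied scores
#' entering as a single threshold step. For an uninformative score the
#' expected value equals the positive prevalence.
#'
#' @inheritParams roc_auc
#' @return List `auc`, `ci_low`, `ci_high`.
#' @export
pr_auc <- function(scores, labels, n_boot = 2000L, seed = 1L, level = 0.95) {
  labels <- as.integer(labels)
  if (sum(labels == 1) == 0L)
    stop("PR AUC requires at least one positive", call. = FALSE)
  auc <- average_precision(scores, labels)
  ci <- if (n_boot > 0) boot_ci(average_precision, scores, labels, n_boot, seed, level)
        else c(NA_real_, NA_real_)
  list(auc = auc, ci_low = ci[1L], ci_high = ci[2L])
}

#' ROC or precision-recall curve points
#'
#' Threshold-by-threshold curve coordinates (tied scores form one step),
#' suitable for CSV export and plotting.
#'
#' @inheritParams roc_auc
#' @param type `"roc"` (false/true positive rates) or `"pr"`
#'   (recall/precision).
#' @return data.frame with `threshold` and the two coordinate columns,
#'   ordered from the strictest threshold down.
#' @export
curve_points <- function(scores, labels, type = c("roc", "pr")) {
  type <- match.arg(type)
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  last <- !duplicated(cumsum(!duplicated(s)), fromLast = TRUE)
  tp <- cumsum(l)[last]; fp <- cumsum(1 - l)[last]
  P <- sum(l); N <- sum(1 - l)
  thr <- s[last]
  if (type == "roc") {
    data.frame(threshold = c(Inf, thr),
               fpr = c(0, fp / N), tpr = c(0, tp / P))
  } else {
    data.frame(threshold = thr, recall = tp / P, precision = tp / (tp + fp))
  }
}

#' Binary affected/unaffected labels per variant
#'
#' Default rule: label 1 iff the variant has at least one affected
#' heterozygote. The alternative `"posterior"` mode thresholds a posterior
#' penetrance vector instead.
#'
#' @param variants a [variant_table()].
#' @param rule `"any_affected"` (default) or `"posterior"`.
#' @param posterior numeric vector of posterior means (for
#'   `rule = "posterior"`).
#' @param threshold cut point for the posterior rule (default 0.5).
#' @return Integer 0/1 vector.
#' @export
binary_labels <- function(variants, rule = c("any_affected", "posterior"),
                          posterior = NULL, threshold = 0.5) {
  rule <- match.arg(rule)
  if (rule == "any_affected") return(as.integer(variants$affected >= 1L))
  stopifnot(!is.null(posterior), length(posterior) == nrow(variants))
  as.integer(posterior > threshold)
}

#' Score a set of covariates against penetrance outcomes
#'
#' For each named predictor column: weighted Spearman correlation and Brier
#' score against the empirical-posterior outcome, and ROC / PR AUC against
#' the binary affected label. Reported for the full table and for the rare
#' stratum (allele frequency below `af_cut` or missing).
#'
#' @param variants a finalized [variant_table()].
#' @param predictors named list of numeric vectors aligned with `variants`
#'   rows (e.g. prior means, REVEL, encoded ClinVar).
#' @param outcome numeric outcome vector (typically the empirical posterior).
#' @param af_cut allele-frequency cut for the rare stratum (default 0.01).
#' @param n_boot,seed bootstrap settings for the AUC CIs.
#' @return data.frame of class `evaluation_report`: one row per predictor
#'   and stratum with `spearman_weighted`, `brier`, `roc_auc`, `pr_auc` and
#'   their CI bounds.
#' @export
evaluate_predictors <- function(variants, predictors, outcome,
                                af_cut = 0.01, n_boot = 2000L, seed = 1L) {
  stopifnot(inherits(variants, "variant_table"), is.list(predictors))
  labels <- binary_labels(variants)
  strata <- list(all = rep(TRUE, nrow(variants)),
                 lt_1pct = is.na(variants$af) | variants$af < af_cut)
  rows <- list()
  for (sname in names(strata)) {
    sel <- strata[[sname]]
    for (pname in names(predictors)) {
      f <- predictors[[pname]][sel]
      o <- outcome[sel]; w <- variants$weight[sel]; l <- labels[sel]
      ok <- is.finite(f)
      sp <- tryCatch(weighted_spearman(f[ok], o[ok], w[ok]),
                     error = function(e) NA_real_)
      br <- if (any(ok)) brier_score(f[ok], o[ok]) else NA_real_
      roc <- tryCatch(roc_auc(f[ok], l[ok], n_boot, seed),
                      error = function(e) list(auc = NA_real_, ci_low = NA_real_,
                                               ci_high = NA_real_))
      pr <- tryCatch(pr_auc(f[ok], l[ok], n_boot, seed),
                     error = function(e) list(auc = NA_real_, ci_low = NA_real_,
                                              ci_high = NA_real_))
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = pname, af_stratum = sname, n = sum(ok),
        spearman_weighted = sp, brier = br,
        roc_auc = roc$auc, roc_ci_low = roc$ci_low, roc_ci_high = roc$ci_high,
        pr_auc = pr$auc, pr_ci_low = pr$ci_low, pr_ci_high = pr$ci_high,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("evaluation_report", "data.frame")
  out
}

# Refit prior + EM on a training subset and predict held-out prior means.
fit_and_predict <- function(train, test, covariates, em_args) {
  prior <- fit_empirical_prior(train)
  fit <- do.call(em_fit, c(list(variants = train, empirical_prior = prior,
                                covariates = covariates), em_args))
  predict_prior(fit$model, test)$prior_mean
}

#' Leave-one-out cross-validated prior predictions
#'
#' For each variant, the empirical prior and EM model are refitted with that
#' variant excluded and its prior mean predicted from covariates alone;
#' predictions never see the held-out variant's counts. When the density
#' covariate is used it should be supplied in leave-self-out form
#' ([density_covariate()]), which removes the remaining self-leakage path.
#'
#' @param variants finalized [variant_table()].
#' @param covariates covariate names for [em_fit()].
#' @param em_args extra arguments passed to [em_fit()] (e.g. `max_iter`).
#' @return List: `predictions` (numeric vector of held-out prior means
#'   aligned with `variants`), `n_failed` (folds whose refit failed, their
#'   predictions `NA`).
#' @export
loocv_evaluate <- function(variants, covariates = default_covariates,
                           em_args = list()) {
  stopifnot(inherits(variants, "variant_table"))
  n <- nrow(variants)
  preds <- rep(NA_real_, n)
  failed <- 0L
  for (i in seq_len(n)) {
    res <- tryCatch(
      fit_and_predict(variants[-i, , drop = FALSE],
                      variants[i, , drop = FALSE], covariates, em_args),
      error = function(e) NA_real_
    )
    if (is.na(res)) failed <- failed + 1L
    preds[i] <- res
  }
  list(predictions = preds, n_failed = failed)
}

# Deterministic, key-ordered fold assignment: identical under row shuffles.
make_folds <- function(keys, k, seed) {
  ord <- order(keys)
  set.seed(seed)
  fold_sorted <- sample(rep_len(seq_len(k), length(keys)))
  folds <- integer(length(keys))
  folds[ord] <- fold_sorted
  folds
}

#' k-fold cross-validated evaluation
#'
#' Random equal-sized partition (keyed on variant identifiers, so fold
#' membership is invariant to input row order), each fold held out once.
#' Held-out Bayesian posteriors are scored against the empirical posterior
#' by weighted Spearman correlation, per fold and pooled.
#'
#' @param variants finalized [variant_table()].
#' @param k number of folds (default 5).
#' @param seed partition seed.
#' @param covariates,em_args as in [loocv_evaluate()].
#' @return List: `folds` (assignment), `predictions` (held-out prior
#'   means), `posterior` (held-out Bayesian posterior means),
#'   `per_fold` (data.frame fold/spearman), `pooled_spearman`.
#' @export
kfold_evaluate <- function(variants, k = 5L, seed = 1L,
                           covariates = default_covariates, em_args = list()) {
  stopifnot(inherits(variants, "variant_table"))
  n <- nrow(variants)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop("k exceeds the number of variants", call. = FALSE)
  folds <- make_folds(variants$variant, k, seed)
  prior_all <- fit_empirical_prior(variants)
  emp_post <- empirical_posterior(variants, prior = prior_all)
  preds <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    hold <- folds == f
    preds[hold] <- fit_and_predict(variants[!hold, , drop = FALSE],
                                   variants[hold, , drop = FALSE],
                                   covariates, em_args)
  }
  nu <- prior_all$nu
  posterior <- (variants$affected + preds * nu) / (variants$total + nu)
  per_fold <- do.call(rbind, lapply(seq_len(k), function(f) {
    sel <- folds == f
    sp <- tryCatch(weighted_spearman(posterior[sel], emp_post[sel],
                                     variants$weight[sel]),
                   error = function(e) NA_real_)
    data.frame(fold = f, n = sum(sel), spearman = sp)
  }))
  pooled <- weighted_spearman(posterior, emp_post, variants$weight)
  list(folds = folds, predictions = preds, posterior = posterior,
       per_fold = per_fold, pooled_spearman = pooled)
}
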