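# Internal numeric helpers shared across modules.

logit <- function(p) log(p) - log1p(-p)

inv_logit <- function(x) stats::plogis(x)

clip01 <- function(p, eps = 1e-4) pmin(pmax(p, eps), 1 - eps)

#' @noRd
weighted_mean_safe <- function(x, w) {
  keep <- is.finite(x) & is.finite(w)
  sw <- sum(w[keep])
  if (sw <= 0) stop("all weights are zero or non-finite", call. = FALSE)
  sum(x[keep] * w[keep]) / sw
}

# Weighted variance with normalized weights (population form).
weighted_var <- function(x, w) {
  w <- w / sum(w)
  mu <- sum(w * x)
  sum(w * (x - mu)^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single number in [0, 1]", name), call. = FALSE)
  invisible(x)
}
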