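#' Bayesian posterior penetrance estimates
#'
#' Conjugate update of variant-specific priors with observed heterozygote
#' counts: `alpha_post = affected + alpha_em`,
#' `beta_post = unaffected + beta_em`. Posterior means and equal-tailed 95%
#' credible intervals follow from the beta shape. Variants with no
#' observations (prospective predictions) carry posterior = prior exactly.
#'
#' @param variants a [variant_table()] (counts may be zero for prospective
#'   variants), or a data.frame with `affected`/`unaffected` columns.
#' @param priors data.frame with `alpha_em`, `beta_em` aligned rowwise with
#'   `variants` (as returned by [em_fit()] or [predict_prior()]).
#' @param level credible-interval mass.
#' @return data.frame of class `penetrance_estimates`: variant key columns,
#'   `prior_mean`, `posterior_mean`, `alpha_post`, `beta_post`, `ci_low`,
#'   `ci_high`, and `provenance` (`"observed"` or `"prospective"`).
#' @export
bayesian_posterior <- function(variants, priors, level = 0.95) {
  stopifnot(nrow(variants) == nrow(priors),
            all(c("alpha_em", "beta_em") %in% names(priors)))
  a <- variants$affected %||% rep(0L, nrow(priors))
  b <- variants$unaffected %||% rep(0L, nrow(priors))
  alpha_post <- a + priors$alpha_em
  beta_post <- b + priors$beta_em
  ci <- credible_interval(alpha_post, beta_post, level)
  out <- data.frame(
    variant = variants$variant %||% sprintf("v%d", seq_len(nrow(priors))),
    position = variants$position %||% NA_integer_,
    ref = variants$ref %||% NA_character_,
    alt = variants$alt %||% NA_character_,
    prior_mean = priors$alpha_em / (priors$alpha_em + priors$beta_em),
    posterior_mean = alpha_post / (alpha_post + beta_post),
    alpha_post = alpha_post, beta_post = beta_post,
    ci_low = ci[, "low"], ci_high = ci[, "high"],
    provenance = ifelse(a + b > 0, "observed", "prospective"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("penetrance_estimates", "data.frame")
  out
}

amino_acids <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Enumerate possible missense variants
#'
#' Without a coding sequence, every position can mutate to each of the 19
#' other amino acids. With a coding sequence, only substitutions reachable
#' by a single nucleotide change in some codon are enumerated (stop and
#' synonymous changes excluded, deduplicated at the amino-acid level) —
#' the set for which population SNV data can exist.
#'
#' @param protein_length number of residues (ignored if `coding_sequence`
#'   given, where it must match the translation length).
#' @param coding_sequence optional in-frame nucleotide string (no stop
#'   codons before the final position; a trailing stop codon is allowed).
#' @param reference optional character vector of reference amino acids per
#'   position (used when no coding sequence is given). Without one, each
#'   residue gets a placeholder reference of `"A"`, giving the 19 possible
#'   substitutions per position.
#' @return data.frame with `position`, `ref`, `alt`.
#' @export
enumerate_missense <- function(protein_length = NULL, coding_sequence = NULL,
                               reference = NULL) {
  if (is.null(coding_sequence)) {
    if (is.null(protein_length) || protein_length < 0)
      stop("protein_length required when no coding sequence is given", call. = FALSE)
    if (protein_length == 0) return(data.frame(position = integer(0),
                                               ref = character(0), alt = character(0)))
    ref <- reference %||% rep("A", protein_length)
    out <- do.call(rbind, lapply(seq_len(protein_length), function(i) {
      alts <- setdiff(amino_acids, ref[i])
      data.frame(position = i, ref = ref[i], alt = alts, stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    return(out)
  }
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("codon-aware enumeration requires the Biostrings package", call. = FALSE)
  code <- Biostrings::GENETIC_CODE
  cds <- toupper(gsub("\\s", "", coding_sequence))
  if (nchar(cds) %% 3L != 0L) stop("coding sequence length must be a multiple of 3", call. = FALSE)
  codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  aa <- unname(code[codons])
  if (anyNA(aa)) stop("coding sequence contains non-ACGT codons", call. = FALSE)
  if (length(aa) && aa[length(aa)] == "*") { codons <- codons[-length(codons)]; aa <- aa[-length(aa)] }
  if (any(aa == "*")) stop("coding sequence contains an internal stop codon", call. = FALSE)
  if (!is.null(protein_length) && length(codons) != protein_length)
    stop("translation length does not match protein_length", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  out <- lapply(seq_along(codons), function(i) {
    cod <- strsplit(codons[i], "")[[1L]]
    alts <- character(0)
    for (pos in 1:3) for (b in setdiff(bases, cod[pos])) {
      mut <- cod; mut[pos] <- b
      maa <- unname(code[paste(mut, collapse = "")])
      if (maa != "*" && maa != aa[i]) alts <- c(alts, maa)
    }
    alts <- sort(unique(alts))
    if (length(alts) == 0L) return(NULL)
    data.frame(position = i, ref = aa[i], alt = alts, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(position = integer(0), ref = character(0),
                                      alt = character(0))
  rownames(out) <- NULL
  out
}

#' Write penetrance estimates as a deterministic CSV
#'
#' Rows sorted by `(position, ref, alt)`, fixed column order, numeric fields
#' formatted to 6 decimals: reruns on the same inputs are byte-identical and
#' a round-trip read recovers values to 1e-6.
#'
#' @param estimates a `penetrance_estimates` data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(estimates, path) {
  e <- as.data.frame(estimates)
  e <- e[order(e$position, e$ref, e$alt), , drop = FALSE]
  numcols <- c("prior_mean", "posterior_mean", "alpha_post", "beta_post",
               "ci_low", "ci_high")
  for (j in intersect(numcols, names(e))) e[[j]] <- sprintf("%.6f", e[[j]])
  cols <- intersect(c("variant", "position", "ref", "alt", numcols, "provenance"),
                    names(e))
  ok <- tryCatch({
    utils::write.csv(e[, cols, drop = FALSE], path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(err) err)
  if (!isTRUE(ok))
    stop(sprintf("failed to write estimates to '%s': %s", path,
                 conditionMessage(ok)), call. = FALSE)
  invisible(path)
}

#' Read back a penetrance estimate CSV
#' @param path CSV written by [write_estimates()].
#' @return data.frame with numeric estimate columns.
#' @export
read_estimates <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
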