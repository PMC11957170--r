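# Fixture builders and independent brute-force oracles used across tests.

# formal names chosen so that covariate arguments in `...` (af, revel, ...)
# can never partially match a count argument
make_table <- function(.positions, .n_affected, .n_unaffected,
                       ref = NULL, alt = NULL, ...) {
  aa <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I")
  ref <- ref %||% aa[((.positions - 1L) %% 10L) + 1L]
  alt <- alt %||% ifelse(ref == "W", "Y", "W")
  finalize_counts(variant_table(.positions, ref, alt,
                                .n_affected, .n_unaffected, ...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_table <- function(n, L = 200L, seed = 1L) {
  set.seed(seed)
  pos <- sample(seq_len(L), n, replace = FALSE)
  tot <- 1L + stats::rpois(n, 5)
  aff <- stats::rbinom(n, tot, stats::rbeta(n, 1, 4))
  # covariates are a deterministic function of the variant key, as a real
  # score is: tables drawn for the same key agree on them
  make_table(pos, aff, tot - aff,
             revel = ((pos * 37L) %% 100L) / 100,
             alphamissense = ((pos * 61L) %% 100L) / 100)
}

write_csv_lines <- function(lines) {
  tf <- tempfile(fileext = ".csv")
  writeLines(lines, tf)
  tf
}

# All-pairs brute-force structural density (the production code vectorizes).
brute_density <- function(residues, variants, radius, leave_out = NULL) {
  v <- variants[variants$total >= 1L, , drop = FALSE]
  if (!is.null(leave_out)) v <- v[v$variant != leave_out, , drop = FALSE]
  out <- rep(NA_real_, nrow(residues))
  names(out) <- residues$position
  for (i in seq_len(nrow(residues))) {
    num <- 0; den <- 0
    for (j in seq_len(nrow(v))) {
      k <- match(v$position[j], residues$position)
      if (is.na(k)) next
      d <- sqrt(sum((unlist(residues[i, c("x", "y", "z")]) -
                       unlist(residues[k, c("x", "y", "z")]))^2))
      if (d <= radius) {
        num <- num + v$weight[j] * v$affected[j]
        den <- den + v$weight[j] * v$total[j]
      }
    }
    if (den > 0) out[i] <- num / den
  }
  out
}

# Exhaustive window enumeration mirroring the scan definition.
brute_hotspots <- function(residue_map, positions, window = 100L,
                           min_mean = 0.4, min_variants = 4L, L = NULL) {
  pos_res <- as.integer(names(residue_map))
  L <- L %||% max(c(positions, pos_res))
  qual <- integer(0)
  for (s in seq_len(max(L - window + 1L, 1L))) {
    e <- s + window - 1L
    nv <- sum(positions >= s & positions <= e)
    inw <- pos_res >= s & pos_res <= e
    if (nv >= min_variants && any(inw) && mean(residue_map[inw]) > min_mean)
      qual <- c(qual, s)
  }
  if (length(qual) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      n_variants = integer(0), mean_penetrance = numeric(0)))
  grp <- cumsum(c(TRUE, diff(qual) > window))
  segs <- lapply(split(qual, grp), function(ss) {
    lo <- min(ss); hi <- max(ss) + window - 1L
    vb <- pos_res[pos_res >= lo & pos_res <= hi]
    start <- min(vb); end <- max(vb)
    data.frame(start = start, end = end,
               n_variants = sum(positions >= start & positions <= end),
               mean_penetrance = mean(residue_map[pos_res >= start & pos_res <= end]))
  })
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

# All-pairs concordance count (ties one half) for ROC AUC.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}
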