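#' Variant heterozygote count tables
#'
#' A `variant_table` is a data.frame with one row per missense variant,
#' keyed by `(position, ref, alt)` in 1-based protein coordinates of a single
#' transcript. It carries affected/unaffected heterozygote counts, the
#' evidence weight derived from the total heterozygote count, an optional
#' allele frequency, and the covariates used for prior calibration
#' (REVEL, AlphaMissense, ClinVar class, structural disease density).
#'
#' @param position 1-based integer residue positions.
#' @param ref,alt single-letter amino acids; `ref != alt` rowwise.
#' @param affected,unaffected non-negative integer heterozygote counts.
#' @param af allele frequency in `[0, 1]` or `NA`.
#' @param revel,alphamissense in-silico scores in `[0, 1]` or `NA`.
#' @param clinvar classification, one of `"P/LP"`, `"VUS"`, `"B/LB"`,
#'   `"absent"` (free-text ClinVar strings are normalized; see
#'   [encode_clinvar()]).
#' @param density structural disease-density covariate, `>= 0` or `NA`.
#' @return A data.frame of class `variant_table` with columns
#'   `variant, position, ref, alt, affected, unaffected, total, weight, af,
#'   revel, alphamissense, clinvar, density`.
#' @seealso [read_count_table()], [merge_counts()], [observed_penetrance()]
#' @export
variant_table <- function(position, ref, alt, affected, unaffected,
                          af = NA_real_, revel = NA_real_,
                          alphamissense = NA_real_, clinvar = "absent",
                          density = NA_real_) {
  n <- length(position)
  position <- as.integer(position)
  affected <- as.integer(affected)
  unaffected <- as.integer(unaffected)
  if (any(is.na(position)) || any(position < 1L))
    stop("residue positions must be integers >= 1", call. = FALSE)
  if (any(ref == alt))
    stop("ref and alt amino acids must differ", call. = FALSE)
  if (any(affected < 0L) || any(unaffected < 0L))
    stop("heterozygote counts must be non-negative", call. = FALSE)
  af <- rep_len(as.numeric(af), n)
  if (any(af < 0 | af > 1, na.rm = TRUE))
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  for (nm in c("revel", "alphamissense")) {
    v <- get(nm)
    if (any(v < 0 | v > 1, na.rm = TRUE))
      stop(sprintf("%s scores must lie in [0, 1]", nm), call. = FALSE)
  }
  clinvar <- normalize_clinvar(rep_len(clinvar, n))
  density <- rep_len(as.numeric(density), n)
  if (any(density < 0, na.rm = TRUE))
    stop("density covariate must be >= 0", call. = FALSE)
  total <- affected + unaffected
  out <- data.frame(
    variant = sprintf("p.%s%d%s", ref, position, alt),
    position = position, ref = ref, alt = alt,
    affected = affected, unaffected = unaffected, total = total,
    weight = ifelse(total >= 1L, evidence_weight(pmax(total, 1L)), 0),
    af = af,
    revel = rep_len(as.numeric(revel), n),
    alphamissense = rep_len(as.numeric(alphamissense), n),
    clinvar = clinvar,
    density = density,
    stringsAsFactors = FALSE
  )
  class(out) <- c("variant_table", "data.frame")
  out
}

empty_variant_table <- function() {
  variant_table(integer(0), character(0), character(0), integer(0), integer(0))
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("<variant_table> %d variants, %d affected / %d total heterozygotes\n",
              nrow(x), sum(x$affected), sum(x$total)))
  NextMethod()
}

# "p.R420W" -> list(position = 420, ref = "R", alt = "W")
parse_protein_hgvs <- function(id) {
  m <- regexec("^(?:p\\.)?([A-Za-z])([0-9]+)([A-Za-z])$", trimws(id))
  parts <- regmatches(id, m)
  bad <- lengths(parts) != 4L
  if (any(bad))
    stop(sprintf("unparseable variant identifier(s): %s",
                 paste(utils::head(id[bad], 5L), collapse = ", ")), call. = FALSE)
  mat <- do.call(rbind, parts)
  list(ref = toupper(mat[, 2L]),
       position = as.integer(mat[, 3L]),
       alt = toupper(mat[, 4L]))
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", comment.char = "")
}

pick_column <- function(df, candidates, what, required = TRUE, path = "") {
  hit <- candidates[candidates %in% tolower(names(df))]
  if (length(hit) == 0L) {
    if (required)
      stop(sprintf("%s: missing required column for %s (accepted names: %s)",
                   path, what, paste(candidates, collapse = ", ")), call. = FALSE)
    return(NULL)
  }
  names(df)[match(hit[1L], tolower(names(df)))]
}

as_count <- function(x, colname, path) {
  y <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(y) | y < 0 | y != floor(y))
  if (length(bad) > 0L)
    stop(sprintf("%s: non-integer %s count in data row(s) %s (value '%s')",
                 path, colname, paste(utils::head(bad, 5L), collapse = ", "),
                 x[bad[1L]]), call. = FALSE)
  as.integer(y)
}

#' Read a curated heterozygote count table
#'
#' Parses a CSV/TSV table with one row per variant report: a protein-level
#' variant identifier (either an HGVS-style column such as `p.R420W`, or
#' explicit `position`/`ref`/`alt` columns) plus affected and unaffected
#' heterozygote counts. Optional covariate columns (`af`, `revel`,
#' `alphamissense`, `clinvar`) are carried through when present.
#'
#' @param path file path to a delimited text file with a header row.
#' @param source_label free-text label recorded in the `source` attribute.
#' @param column_map optional named character vector remapping file column
#'   names onto the canonical names (e.g. `c(affected = "n_cases")`).
#' @return A [variant_table()]. Rows with the same variant key are kept as
#'   independent reports; use [merge_counts()] to sum them.
#' @export
read_count_table <- function(path, source_label = basename(path),
                             column_map = NULL) {
  df <- read_delim_auto(path)
  if (!is.null(column_map))
    for (canon in names(column_map))
      names(df)[names(df) == column_map[[canon]]] <- canon
  if (nrow(df) == 0L) {
    out <- empty_variant_table()
    attr(out, "source") <- source_label
    return(out)
  }
  vcol <- pick_column(df, c("variant", "hgvs_p", "protein_change"), "variant id",
                      required = FALSE, path = path)
  if (!is.null(vcol)) {
    key <- parse_protein_hgvs(df[[vcol]])
  } else {
    pcol <- pick_column(df, c("position", "pos", "residue"), "variant id", path = path)
    rcol <- pick_column(df, c("ref", "ref_aa"), "reference amino acid", path = path)
    acol <- pick_column(df, c("alt", "alt_aa"), "alternate amino acid", path = path)
    key <- list(position = as.integer(df[[pcol]]),
                ref = toupper(df[[rcol]]), alt = toupper(df[[acol]]))
  }
  affc <- pick_column(df, c("affected", "n_affected", "cases"), "affected count", path = path)
  unac <- pick_column(df, c("unaffected", "n_unaffected", "controls"), "unaffected count", path = path)
  opt <- function(cands) {
    col <- pick_column(df, cands, "", required = FALSE, path = path)
    if (is.null(col)) NULL else df[[col]]
  }
  num_or_na <- function(x) if (is.null(x)) NA_real_ else suppressWarnings(as.numeric(x))
  out <- variant_table(
    position = key$position, ref = key$ref, alt = key$alt,
    affected = as_count(df[[affc]], "affected", path),
    unaffected = as_count(df[[unac]], "unaffected", path),
    af = num_or_na(opt(c("af", "allele_frequency", "allele_freq"))),
    revel = num_or_na(opt(c("revel"))),
    alphamissense = num_or_na(opt(c("alphamissense", "am"))),
    clinvar = opt(c("clinvar", "clinvar_code", "classification")) %||% "absent",
    density = num_or_na(opt(c("density", "cpvt_density")))
  )
  attr(out, "source") <- source_label
  out
}

#' Read a population (gnomAD-style) variant table
#'
#' Population heterozygotes are treated as unaffected: the allele count maps
#' to the unaffected count and the affected count is zero. Rows at or above
#' `af_threshold` are dropped; the default reproduces the `< 0.01%` rarity
#' filter used when pooling population controls with curated cases.
#'
#' @param path delimited file with variant id columns (as in
#'   [read_count_table()]), an allele frequency column (`af`), and an allele
#'   count column (`ac`/`allele_count`).
#' @param af_threshold keep variants with allele frequency strictly below
#'   this value (default `1e-4`, i.e. 0.01%).
#' @inheritParams read_count_table
#' @return A [variant_table()] with `affected = 0` throughout.
#' @export
read_population_table <- function(path, af_threshold = 1e-4,
                                  source_label = basename(path),
                                  column_map = NULL) {
  df <- read_delim_auto(path)
  if (!is.null(column_map))
    for (canon in names(column_map))
      names(df)[names(df) == column_map[[canon]]] <- canon
  if (nrow(df) == 0L) {
    out <- empty_variant_table()
    attr(out, "source") <- source_label
    return(out)
  }
  vcol <- pick_column(df, c("variant", "hgvs_p", "protein_change"), "variant id",
                      required = FALSE, path = path)
  if (!is.null(vcol)) {
    key <- parse_protein_hgvs(df[[vcol]])
  } else {
    pcol <- pick_column(df, c("position", "pos"), "variant id", path = path)
    rcol <- pick_column(df, c("ref", "ref_aa"), "reference amino acid", path = path)
    acol <- pick_column(df, c("alt", "alt_aa"), "alternate amino acid", path = path)
    key <- list(position = as.integer(df[[pcol]]),
                ref = toupper(df[[rcol]]), alt = toupper(df[[acol]]))
  }
  afc <- pick_column(df, c("af", "allele_frequency", "allele_freq"), "allele frequency", path = path)
  acc <- pick_column(df, c("ac", "allele_count"), "allele count", path = path)
  af <- suppressWarnings(as.numeric(df[[afc]]))
  if (any(af < 0, na.rm = TRUE))
    stop(sprintf("%s: negative allele frequency in row(s) %s", path,
                 paste(which(af < 0), collapse = ", ")), call. = FALSE)
  keep <- !is.na(af) & af < af_threshold
  out <- variant_table(
    position = key$position[keep], ref = key$ref[keep], alt = key$alt[keep],
    affected = rep(0L, sum(keep)),
    unaffected = as_count(df[[acc]][keep], "allele", path),
    af = af[keep]
  )
  attr(out, "source") <- source_label
  out
}

#' Merge variant tables by summing heterozygote counts
#'
#' Rows sharing a `(position, ref, alt)` key have their affected and
#' unaffected counts summed across sources (each input row is treated as an
#' independent report); covariates are joined by taking the first non-missing
#' value per key. Weights are recomputed from the merged totals.
#'
#' @param ... two or more [variant_table()] objects (or a single one, in
#'   which case its duplicate keys are collapsed).
#' @return A merged [variant_table()] with unique keys, ordered by
#'   `(position, ref, alt)`.
#' @export
merge_counts <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1L]]) && !is.data.frame(tabs[[1L]]))
    tabs <- tabs[[1L]]
  stopifnot(all(vapply(tabs, inherits, TRUE, "variant_table")))
  all <- do.call(rbind, lapply(tabs, as.data.frame))
  if (nrow(all) == 0L) return(empty_variant_table())
  refmap <- tapply(all$ref, all$position, function(r) unique(r))
  multi <- names(refmap)[lengths(refmap) > 1L]
  if (length(multi) > 0L)
    stop(sprintf("conflicting reference amino acids at position(s) %s",
                 paste(utils::head(multi, 5L), collapse = ", ")), call. = FALSE)
  key <- paste(all$position, all$ref, all$alt, sep = "|")
  first <- function(x) { v <- x[!is.na(x)]; if (length(v)) v[1L] else x[1L] }
  agg <- lapply(split(seq_len(nrow(all)), key), function(idx) {
    rows <- all[idx, , drop = FALSE]
    cv <- rows$clinvar[rows$clinvar != "absent"]
    data.frame(position = rows$position[1L], ref = rows$ref[1L], alt = rows$alt[1L],
               affected = sum(rows$affected), unaffected = sum(rows$unaffected),
               af = first(rows$af), revel = first(rows$revel),
               alphamissense = first(rows$alphamissense),
               clinvar = if (length(cv)) cv[1L] else "absent",
               density = first(rows$density), stringsAsFactors = FALSE)
  })
  agg <- do.call(rbind, agg)
  agg <- agg[order(agg$position, agg$ref, agg$alt), , drop = FALSE]
  variant_table(agg$position, agg$ref, agg$alt, agg$affected, agg$unaffected,
                af = agg$af, revel = agg$revel, alphamissense = agg$alphamissense,
                clinvar = agg$clinvar, density = agg$density)
}

#' Observed penetrance
#'
#' The fraction of affected heterozygotes among all heterozygotes observed
#' for a variant: `affected / (affected + unaffected)`.
#'
#' @param affected,unaffected non-negative integer counts (vectorized), or
#'   pass a [variant_table()] as `affected` to use its count columns.
#' @return Numeric vector in `[0, 1]`. Variants with zero total heterozygotes
#'   have no defined observed penetrance and raise an error.
#' @examples
#' observed_penetrance(14, 10)  # 14 of 24 heterozygotes affected
#' @export
observed_penetrance <- function(affected, unaffected = NULL) {
  if (inherits(affected, "variant_table")) {
    unaffected <- affected$unaffected
    affected <- affected$affected
  }
  total <- affected + unaffected
  if (any(total == 0L))
    stop("observed penetrance is undefined for variants with zero heterozygotes",
         call. = FALSE)
  affected / total
}

#' Evidence weight from total heterozygote count
#'
#' Confidence mass assigned to each variant's observation,
#' `w = 1 - 1/(0.01 + n)` for `n` total heterozygotes, clamped to `[0, 1]`.
#' Singletons (`n = 1`) receive weight ~0.0099, so variants seen in a single
#' individual barely influence ensemble fits; the weight approaches 1 as
#' counts grow. The `"gentle"` form `1 - 1/(1 + 0.01 n)` ramps up far more
#' slowly and is provided as an alternative parameterization.
#'
#' @param total_heterozygotes positive integer count(s).
#' @param form `"printed"` (default) or `"gentle"`.
#' @return Weights in `[0, 1)`, strictly increasing in the count.
#' @export
evidence_weight <- function(total_heterozygotes, form = c("printed", "gentle")) {
  form <- match.arg(form)
  n <- total_heterozygotes
  if (any(n < 1))
    stop("evidence_weight requires total_heterozygotes >= 1; zero-count variants are excluded upstream",
         call. = FALSE)
  w <- switch(form,
              printed = 1 - 1 / (0.01 + n),
              gentle  = 1 - 1 / (1 + 0.01 * n))
  pmin(pmax(w, 0), 1)
}

clinvar_levels <- c("P/LP", "VUS", "B/LB", "absent")

normalize_clinvar <- function(x) {
  x[is.na(x) | x == ""] <- "absent"
  key <- tolower(trimws(x))
  map <- c(
    "p/lp" = "P/LP", "pathogenic" = "P/LP", "likely pathogenic" = "P/LP",
    "pathogenic/likely pathogenic" = "P/LP", "likely_pathogenic" = "P/LP",
    "vus" = "VUS", "uncertain significance" = "VUS",
    "uncertain_significance" = "VUS", "conflicting" = "VUS",
    "b/lb" = "B/LB", "benign" = "B/LB", "likely benign" = "B/LB",
    "benign/likely benign" = "B/LB", "likely_benign" = "B/LB",
    "absent" = "absent", "not provided" = "absent", "na" = "absent"
  )
  out <- unname(map[key])
  bad <- is.na(out)
  if (any(bad))
    stop(sprintf("unrecognized ClinVar classification '%s'; accepted labels map onto {%s}",
                 x[bad][1L], paste(clinvar_levels, collapse = ", ")), call. = FALSE)
  out
}

#' Encode ClinVar classifications as a binary covariate
#'
#' Following clinical convention for model evaluation, pathogenic/likely
#' pathogenic variants are coded 1 (affected) while VUS and benign/likely
#' benign variants are coded 0 (unaffected); variants absent from ClinVar
#' are missing.
#'
#' @param code character vector of classifications; common ClinVar strings
#'   ("Pathogenic", "Uncertain significance", "Likely benign", ...) are
#'   normalized onto `P/LP`, `VUS`, `B/LB`, `absent`.
#' @return Numeric vector of 0/1 with `NA` for `absent`.
#' @export
encode_clinvar <- function(code) {
  norm <- normalize_clinvar(code)
  out <- ifelse(norm == "P/LP", 1, 0)
  out[norm == "absent"] <- NA_real_
  out
}

#' Finalize a variant table for model fitting
#'
#' Drops variants with zero observed heterozygotes (their evidence weight is
#' undefined; they receive prospective priors only) and recomputes weights.
#'
#' @param x a [variant_table()].
#' @param weight_form passed to [evidence_weight()].
#' @return The filtered table.
#' @export
finalize_counts <- function(x, weight_form = "printed") {
  stopifnot(inherits(x, "variant_table"))
  x <- x[x$total >= 1L, , drop = FALSE]
  x$weight <- evidence_weight(x$total, form = weight_form)
  class(x) <- c("variant_table", "data.frame")
  x
}

#' Write a variant table as canonical CSV
#'
#' Fixed column order and plain integer counts so that
#' `read_count_table(write_variant_table(x))` round-trips counts exactly.
#'
#' @param x a [variant_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(x, path) {
  stopifnot(inherits(x, "variant_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
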