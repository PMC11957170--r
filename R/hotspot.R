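#' Residue-averaged penetrance
#'
#' Unweighted mean of the Bayesian penetrance of all variants at each
#' residue; residues carrying no variants are absent from the map.
#'
#' @param estimates a `penetrance_estimates` data.frame (or any data.frame
#'   with `position` and a value column).
#' @param value column to average (default `"posterior_mean"`).
#' @return Named numeric vector, names = residue positions (sorted).
#' @export
residue_mean_penetrance <- function(estimates, value = "posterior_mean") {
  if (nrow(estimates) == 0L) return(stats::setNames(numeric(0), character(0)))
  agg <- tapply(estimates[[value]], estimates$position, mean)
  out <- as.numeric(agg)
  names(out) <- names(agg)
  out[order(as.integer(names(out)))]
}

#' Sliding-window hot-spot scan
#'
#' Slides a fixed-length window across the protein. A window qualifies when
#' it contains at least `min_variants` variants and the mean value over its
#' variant-bearing residues exceeds `min_mean` (strict). Overlapping
#' qualifying windows are merged into maximal segments, each trimmed to its
#' outermost variant-bearing residues and reported with the variant count
#' and mean over the trimmed span.
#'
#' @param residue_map named numeric vector from [residue_mean_penetrance()].
#' @param variant_positions integer vector of variant residue positions
#'   (with multiplicity: two variants at one residue count twice).
#' @param window window width in residues (default 100).
#' @param min_mean strict lower threshold on the window mean (default 0.4).
#' @param min_variants minimum variant count per window (default 4, i.e.
#'   "more than 3 variants").
#' @param protein_length scan range upper bound; defaults to the largest
#'   position seen.
#' @param dilute if `TRUE`, the window mean is taken over all residues in
#'   the window (empty residues count 0) instead of variant-bearing
#'   residues only.
#' @return data.frame of class `hotspot_segments` with `start`, `end`,
#'   `n_variants`, `mean_penetrance`, sorted and disjoint.
#' @export
scan_hotspots <- function(residue_map, variant_positions, window = 100L,
                          min_mean = 0.4, min_variants = 4L,
                          protein_length = NULL, dilute = FALSE) {
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  empty <- data.frame(start = integer(0), end = integer(0),
                      n_variants = integer(0), mean_penetrance = numeric(0))
  class(empty) <- c("hotspot_segments", "data.frame")
  if (length(variant_positions) == 0L) return(empty)
  pos_res <- as.integer(names(residue_map))
  L <- protein_length %||% max(c(variant_positions, pos_res))
  starts <- seq_len(max(L - window + 1L, 1L))
  qual <- logical(length(starts))
  for (k in seq_along(starts)) {
    s <- starts[k]; e <- s + window - 1L
    nv <- sum(variant_positions >= s & variant_positions <= e)
    if (nv < min_variants) next
    inw <- pos_res >= s & pos_res <= e
    if (!any(inw)) next
    m <- if (dilute) sum(residue_map[inw]) / window else mean(residue_map[inw])
    qual[k] <- m > min_mean
  }
  if (!any(qual)) return(empty)
  qs <- starts[qual]
  # starts differing by < window overlap; == window are adjacent; both merge
  brk <- c(TRUE, diff(qs) > window)
  grp <- cumsum(brk)
  segs <- lapply(split(qs, grp), function(ss) {
    lo <- min(ss); hi <- max(ss) + window - 1L
    vb <- pos_res[pos_res >= lo & pos_res <= hi]
    if (length(vb) == 0L) return(NULL)
    start <- min(vb); end <- max(vb)
    nv <- sum(variant_positions >= start & variant_positions <= end)
    inseg <- pos_res >= start & pos_res <= end
    m <- if (dilute) sum(residue_map[inseg]) / (end - start + 1L)
         else mean(residue_map[inseg])
    data.frame(start = start, end = end, n_variants = nv, mean_penetrance = m)
  })
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  class(out) <- c("hotspot_segments", "data.frame")
  out
}

#' Ship the published five-range domain map
#'
#' The schematic domain ranges for the ryanodine receptor protomer in
#' transcript residue coordinates. The published legend names six regions
#' but prints five ranges; the five ranges are shipped verbatim with
#' positional labels and users can relabel freely.
#'
#' @return data.frame `name`, `start`, `end`.
#' @export
ryr2_domains <- function() {
  data.frame(
    name = c("NTD", "BSolB", "BSolC", "CSol", "TMD"),
    start = c(1L, 2109L, 3634L, 4490L, 4887L),
    end = c(639L, 3554L, 4130L, 4886L, 4914L),
    stringsAsFactors = FALSE
  )
}

validate_domains <- function(domains) {
  stopifnot(all(c("name", "start", "end") %in% names(domains)))
  if (any(domains$start > domains$end))
    stop("domain start must be <= end", call. = FALSE)
  d <- domains[order(domains$start), , drop = FALSE]
  if (nrow(d) > 1L && any(d$start[-1L] <= d$end[-nrow(d)]))
    stop("domain intervals overlap", call. = FALSE)
  d
}

#' Label residues or segments with their containing domain
#'
#' @param x integer residue positions, or a `hotspot_segments` data.frame
#'   (labelled by midpoint containment; a segment straddling domains gets
#'   the domain of its start).
#' @param domains data.frame `name`, `start`, `end` (non-overlapping);
#'   default [ryr2_domains()].
#' @return character vector of domain names, `"inter-domain"` where no
#'   interval contains the position; for segments, the input data.frame
#'   with a `domain` column added.
#' @export
annotate_domains <- function(x, domains = ryr2_domains()) {
  d <- validate_domains(domains)
  label_one <- function(pos) {
    hit <- which(d$start <= pos & pos <= d$end)
    if (length(hit)) d$name[hit[1L]] else "inter-domain"
  }
  if (is.data.frame(x)) {
    x$domain <- vapply(x$start, label_one, "")
    return(x)
  }
  vapply(as.integer(x), label_one, "")
}
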