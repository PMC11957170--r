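#' Read alpha-carbon coordinates from a structure file
#'
#' One C-alpha per resolved residue of the selected chain; where alternate
#' locations exist the highest-occupancy conformer is kept (ties broken by
#' altloc identifier order).
#'
#' @param path PDB or mmCIF file (format chosen by extension:
#'   `.cif`/`.mmcif` read as mmCIF, anything else as PDB).
#' @param chain chain identifier (default `"A"`).
#' @return data.frame of class `residue_coords` with columns `position`
#'   (author residue number), `chain`, `x`, `y`, `z` (angstroms), one row
#'   per resolved residue, ordered by position.
#' @export
read_structure <- function(path, chain = "A") {
  if (!file.exists(path)) stop(sprintf("structure file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  pdb <- suppressWarnings(
    if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path, rm.alt = FALSE)
    else bio3d::read.pdb(path, rm.alt = FALSE)
  )
  at <- pdb$atom
  chains <- sort(unique(at$chain))
  if (!chain %in% chains)
    stop(sprintf("chain '%s' not present; available chains: %s", chain,
                 paste(chains, collapse = ", ")), call. = FALSE)
  ca <- at[at$chain == chain & at$elety == "CA" & !is.na(at$resno), , drop = FALSE]
  if (nrow(ca) == 0L)
    stop(sprintf("no C-alpha atoms found in chain '%s' of %s", chain, path), call. = FALSE)
  if (is.null(ca$o)) ca$o <- 1
  ca$o[is.na(ca$o)] <- 1
  ca <- ca[order(ca$resno, -ca$o, ca$alt), , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  if (any(!is.finite(ca$x) | !is.finite(ca$y) | !is.finite(ca$z)))
    stop("non-finite coordinates in structure", call. = FALSE)
  out <- data.frame(position = as.integer(ca$resno), chain = chain,
                    x = ca$x, y = ca$y, z = ca$z, stringsAsFactors = FALSE)
  class(out) <- c("residue_coords", "data.frame")
  out
}

# Pairwise Euclidean distances between two coordinate matrices (rows).
pairwise_dist <- function(A, B) {
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

#' Structural disease-density profile
#'
#' For each resolved residue `r`, the evidence-weighted affected fraction
#' among heterozygotes of variants whose residues lie within `radius`
#' angstroms (C-alpha to C-alpha) of `r`, the residue's own variants
#' included:
#' `density(r) = sum_v k(d) w_v affected_v / sum_v k(d) w_v total_v`
#' over in-neighborhood variants `v`, with `k` the uniform cutoff kernel
#' (1 within `radius`) or an exponential decay `exp(-d / length_scale)`.
#' Residues whose neighborhood carries no heterozygotes get `NA`.
#'
#' @param residues a `residue_coords` data.frame ([read_structure()] or
#'   [generate_toy_structure()]).
#' @param variants a finalized [variant_table()]. Variants at positions
#'   without resolved coordinates contribute nothing; they are listed in the
#'   `coverage` attribute of the result.
#' @param radius neighborhood radius in angstroms (default 15).
#' @param kernel `"cutoff"` (default) or `"exponential"`.
#' @param length_scale decay length for the exponential kernel (angstroms).
#' @param leave_out optional variant key (`"p.R420W"` style) excluded from
#'   both sums, for leakage-free use of the density as that variant's own
#'   covariate.
#' @param multi_chain if `TRUE` and `residues` spans several chains (e.g. a
#'   homotetramer), the distance between two residue positions is the
#'   minimum over all chain copies, capturing inter-protomer neighborhoods;
#'   the default treats each row independently (single-protomer use).
#' @return Named numeric vector (names = residue positions) of densities in
#'   `[0, 1]` or `NA`; attribute `coverage` is a data.frame flagging which
#'   variants fell on resolved residues.
#' @export
compute_density <- function(residues, variants, radius = 15,
                            kernel = c("cutoff", "exponential"),
                            length_scale = 5, leave_out = NULL,
                            multi_chain = FALSE) {
  kernel <- match.arg(kernel)
  stopifnot(radius > 0, inherits(variants, "variant_table"))
  v <- variants[variants$total >= 1L, , drop = FALSE]
  if (!is.null(leave_out)) v <- v[v$variant != leave_out, , drop = FALSE]
  coverage <- data.frame(variant = v$variant,
                         resolved = v$position %in% residues$position,
                         stringsAsFactors = FALSE)
  v <- v[coverage$resolved[match(v$variant, coverage$variant)], , drop = FALSE]
  R <- as.matrix(residues[, c("x", "y", "z")])
  if (multi_chain) {
    # collapse chain copies: min distance over copies of either position
    upos <- sort(unique(residues$position))
    out_res <- data.frame(position = upos)
    D_all <- pairwise_dist(R, R)
    D <- matrix(Inf, length(upos), length(upos))
    by_chain <- split(seq_len(nrow(residues)), residues$chain)
    for (ra in by_chain) for (rb in by_chain) {
      ia <- match(residues$position[ra], upos)
      ib <- match(residues$position[rb], upos)
      D[ia, ib] <- pmin(D[ia, ib], D_all[ra, rb, drop = FALSE])
    }
    Dv <- D[, match(v$position, upos), drop = FALSE]
  } else {
    out_res <- residues
    Dv <- if (nrow(v) > 0L)
      pairwise_dist(R, R[match(v$position, residues$position), , drop = FALSE])
    else matrix(0, nrow(residues), 0L)
  }
  num <- den <- rep(0, nrow(out_res))
  if (nrow(v) > 0L) {
    K <- if (kernel == "cutoff") (Dv <= radius) * 1 else exp(-Dv / length_scale)
    num <- drop(K %*% (v$weight * v$affected))
    den <- drop(K %*% (v$weight * v$total))
  }
  prof <- ifelse(den > 0, num / den, NA_real_)
  names(prof) <- out_res$position
  attr(prof, "num") <- num
  attr(prof, "den") <- den
  attr(prof, "coverage") <- coverage
  attr(prof, "radius") <- radius
  attr(prof, "kernel") <- kernel
  prof
}

#' Leave-self-out density covariate for each variant
#'
#' Evaluates [compute_density()] at each variant's own residue with that
#' variant excluded from the sums, so the covariate carries no information
#' from the variant's own heterozygotes. With `leave_out = FALSE` the
#' all-data (prospective) density at the variant's residue is returned.
#' Variants on unresolved residues (or with an empty neighborhood) get the
#' weighted mean density, flagged in the `imputed` attribute.
#'
#' @inheritParams compute_density
#' @param leave_out logical; exclude each variant from its own neighborhood
#'   (default `TRUE`).
#' @param impute fill unresolved/empty-neighborhood variants with the
#'   weighted mean density (default `TRUE`); otherwise `NA`.
#' @return Numeric vector aligned with `variants` rows; attribute `imputed`
#'   is a logical vector marking filled values.
#' @export
density_covariate <- function(residues, variants, radius = 15,
                              kernel = "cutoff", length_scale = 5,
                              leave_out = TRUE, impute = TRUE) {
  stopifnot(inherits(variants, "variant_table"))
  n <- nrow(variants)
  out <- rep(NA_real_, n)
  full <- compute_density(residues, variants, radius, kernel, length_scale)
  num <- attr(full, "num"); den <- attr(full, "den")
  idx <- match(as.character(variants$position), names(full))
  for (i in seq_len(n)) {
    k <- idx[i]
    if (is.na(k)) next
    if (leave_out && variants$total[i] >= 1L) {
      # a variant's kernel weight at its own residue is 1 (distance 0), so
      # holding it out subtracts its terms from the precomputed sums
      nm <- num[k] - variants$weight[i] * variants$affected[i]
      dn <- den[k] - variants$weight[i] * variants$total[i]
      out[i] <- if (dn > 1e-12) nm / dn else NA_real_
    } else {
      out[i] <- full[[k]]
    }
  }
  imputed <- !is.finite(out)
  if (impute && any(imputed)) {
    w <- variants$weight
    ok <- is.finite(out)
    if (any(ok)) out[imputed] <- sum(out[ok] * w[ok]) / sum(w[ok])
    else out[imputed] <- 0
  }
  attr(out, "imputed") <- imputed
  out
}

#' Export per-residue values into the B-factor column of a PDB file
#'
#' Writes a copy of the structure with each atom's B-factor set to the value
#' mapped to its residue (e.g. a density profile or residue-averaged
#' penetrance), for rendering in external viewers. Residues absent from the
#' map, or mapped to a missing value, get the sentinel -1.0.
#'
#' @param values named numeric vector (names = residue positions), values in
#'   `[0, 1]` for penetrance maps.
#' @param structure_path input PDB/mmCIF file.
#' @param out_path output PDB path.
#' @param chain restrict annotation to this chain (other chains keep the
#'   sentinel); `NULL` annotates every chain by residue number.
#' @return `out_path`, invisibly.
#' @export
export_structure_colors <- function(values, structure_path, out_path,
                                    chain = NULL) {
  ext <- tolower(tools::file_ext(structure_path))
  pdb <- if (ext %in% c("cif", "mmcif")) bio3d::read.cif(structure_path)
         else bio3d::read.pdb(structure_path)
  vals <- values[!is.na(values)]
  b <- rep(-1.0, nrow(pdb$atom))
  idx <- match(as.character(pdb$atom$resno), names(vals))
  hit <- !is.na(idx)
  if (!is.null(chain)) hit <- hit & pdb$atom$chain == chain
  b[hit] <- unname(vals[idx[hit]])
  pdb$atom$b <- b
  bio3d::write.pdb(pdb, file = out_path, b = b)
  invisible(out_path)
}
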