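pdb_line <- function(serial, alt, resno, x, y, z, occ, chain = "A") {
  sprintf("ATOM  %5d  CA %1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, alt, "ALA", chain, resno, x, y, z, occ, 0)
}

test_that("structure reading returns one C-alpha per resolved residue", {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(1, " ", 1, 0, 0, 0, 1),
               pdb_line(2, " ", 2, 3.8, 0, 0, 1),
               pdb_line(3, " ", 3, 7.6, 0, 0, 1), "END"), tf)
  res <- read_structure(tf, chain = "A")
  expect_equal(res$position, 1:3)
  expect_equal(res$x, c(0, 3.8, 7.6))
  expect_error(read_structure(tf, chain = "Z"), "available chains: A")
})

test_that("alternate locations resolve to the highest occupancy", {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(1, "A", 1, 0, 0, 0, 0.7),
               pdb_line(2, "B", 1, 9, 9, 9, 0.3),
               pdb_line(3, " ", 2, 3.8, 0, 0, 1), "END"), tf)
  res <- read_structure(tf, chain = "A")
  expect_equal(nrow(res), 2L)
  expect_equal(res$x[res$position == 1], 0)
})

test_that("density matches hand-computed neighborhoods on a collinear chain", {
  res <- data.frame(position = 1:3, chain = "A",
                    x = c(0, 3.8, 7.6), y = 0, z = 0)
  class(res) <- c("residue_coords", "data.frame")

  v <- make_table(c(1L, 3L), c(2L, 0L), c(2L, 2L))
  v$weight <- c(1, 1)
  prof <- compute_density(res, v, radius = 5)
  # residue 2 sees both variants (3.8 A each); residues 1 and 3 see only
  # themselves (7.6 A apart)
  expect_equal(unname(prof[["2"]]), 2 / 6)
  expect_equal(unname(prof[["1"]]), 2 / 4)
  expect_equal(unname(prof[["3"]]), 0)

  # a lone fully penetrant variant: density 1 at its own residue
  v1 <- make_table(1L, 5L, 0L)
  p1 <- compute_density(res, v1, radius = 2)
  expect_equal(unname(p1[["1"]]), 1)
  expect_true(is.na(p1[["3"]]))

  # no affected heterozygotes anywhere: zero wherever the denominator is live
  v0 <- make_table(c(1L, 2L), c(0L, 0L), c(3L, 4L))
  p0 <- compute_density(res, v0, radius = 5)
  expect_equal(unname(p0[!is.na(p0)]), rep(0, sum(!is.na(p0))))
})

test_that("density equals the all-pairs brute force on random toy structures", {
  for (seed in 1:8) {
    set.seed(seed)
    res <- generate_toy_structure(40, seed = seed)
    n <- 12
    v <- make_table(sample(1:40, n), rbinom(n, 6, 0.4), rbinom(n, 6, 0.6))
    radius <- runif(1, 4, 20)
    fast <- compute_density(res, v, radius = radius)
    slow <- brute_density(res, v, radius = radius)
    expect_equal(as.numeric(fast), as.numeric(slow), tolerance = 1e-10)
    ok <- !is.na(fast)
    expect_true(all(fast[ok] >= 0 & fast[ok] <= 1))

    # the vectorized leave-self-out covariate agrees with an explicit
    # hold-one-out profile evaluated at the variant's own residue
    cov <- density_covariate(res, v, radius = radius, impute = FALSE)
    i <- sample(nrow(v), 1)
    loo <- brute_density(res, v, radius = radius, leave_out = v$variant[i])
    expect_equal(unname(cov[i]), unname(loo[[as.character(v$position[i])]]),
                 tolerance = 1e-10)
  }
})

test_that("adding an affected heterozygote never lowers in-radius density", {
  set.seed(30)
  res <- generate_toy_structure(30, seed = 30)
  v <- make_table(c(5L, 9L, 20L), c(1L, 0L, 2L), c(3L, 4L, 2L))
  before <- compute_density(res, v, radius = 12)
  v2 <- v; v2$affected[2L] <- v2$affected[2L] + 1L
  v2$total <- v2$affected + v2$unaffected
  v2 <- finalize_counts(v2)
  after <- compute_density(res, v2, radius = 12)
  # weight of the bumped variant also changes; check at its own residue
  expect_gte(after[["9"]], before[["9"]])
})

test_that("leave-one-out density excludes the variant's own heterozygotes", {
  res <- data.frame(position = 1:20, chain = "A",
                    x = 3.8 * (0:19), y = 0, z = 0)
  class(res) <- c("residue_coords", "data.frame")
  v <- make_table(c(3L, 15L), c(2L, 1L), c(1L, 1L))
  prof <- compute_density(res, v, radius = 5, leave_out = "p.N3W")
  # with the only in-radius variant removed, its residue has no neighborhood
  expect_true(is.na(prof[["3"]]))

  cov <- density_covariate(res, v, radius = 5, leave_out = TRUE, impute = FALSE)
  expect_true(all(is.na(cov)))
  cov_imp <- density_covariate(res, v, radius = 5, leave_out = TRUE)
  expect_true(all(is.finite(cov_imp)))
  expect_true(all(attr(cov_imp, "imputed")))

  full <- density_covariate(res, v, radius = 5, leave_out = FALSE)
  expect_equal(full[1L], 2 / 3)
})

test_that("variants off the resolved structure are flagged, not counted", {
  res <- generate_toy_structure(10, seed = 3)
  v <- make_table(c(2L, 500L), c(1L, 5L), c(1L, 0L))
  prof <- compute_density(res, v, radius = 8)
  cov <- attr(prof, "coverage")
  expect_false(cov$resolved[cov$variant == v$variant[2L]])
  expect_equal(unname(prof[["2"]]), 0.5)
})

test_that("multi-chain mode uses the minimum distance across chain copies", {
  # chain A spaced 10 A apart; chain B mostly far away, except its copy of
  # residue 5 sits 2 A from chain A's residue 1
  a <- data.frame(position = 1:5, chain = "A", x = c(0, 10, 20, 30, 40),
                  y = 0, z = 0)
  b <- data.frame(position = 1:5, chain = "B", x = c(0, 10, 20, 30, 2),
                  y = c(1000, 1000, 1000, 1000, 0), z = 0)
  res <- rbind(a, b)
  class(res) <- c("residue_coords", "data.frame")
  v <- make_table(c(1L, 5L), c(2L, 0L), c(0L, 4L))

  a_only <- a; class(a_only) <- c("residue_coords", "data.frame")
  single <- compute_density(a_only, v, radius = 6)
  expect_equal(unname(single[["1"]]), 1)  # residue 5 is 40 A away

  multi <- compute_density(res, v, radius = 6, multi_chain = TRUE)
  w <- v$weight
  expect_equal(unname(multi[["1"]]),
               (w[1] * 2) / (w[1] * 2 + w[2] * 4), tolerance = 1e-12)
  # and residue 5 now also sees variant 1 through its chain-B copy
  expect_equal(unname(multi[["5"]]), unname(multi[["1"]]), tolerance = 1e-12)
})

test_that("B-factor export writes values with the -1 sentinel and round-trips", {
  res <- generate_toy_structure(6, seed = 4)
  tf <- tempfile(fileext = ".pdb")
  write_toy_pdb(res, tf)

  vals <- c("1" = 0.5, "2" = 0.5, "3" = 0.5, "4" = 0.5, "5" = 0.5, "6" = 0.5)
  out <- tempfile(fileext = ".pdb")
  export_structure_colors(vals, tf, out)
  back <- suppressWarnings(bio3d::read.pdb(out))
  expect_equal(back$atom$b, rep(0.5, 6))

  partial <- c("2" = 0.31, "5" = 0.87)
  export_structure_colors(partial, tf, out)
  back2 <- suppressWarnings(bio3d::read.pdb(out))
  expect_equal(back2$atom$b[back2$atom$resno == 2], 0.31, tolerance = 5e-3)
  expect_equal(back2$atom$b[back2$atom$resno == 5], 0.87, tolerance = 5e-3)
  expect_equal(back2$atom$b[back2$atom$resno == 1], -1)
})
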