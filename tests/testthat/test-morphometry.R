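# Footprint operators and index computation, checked against brute-force
# per-pixel reference implementations and against phantom ground truth.

test_that("project_axial equals a triple-loop projection on a random volume", {
  set.seed(21)
  vox <- array(sample(0:3, 30^3, replace = TRUE, prob = c(0.9, 0.03, 0.04, 0.03)),
               c(30, 30, 30))
  vol <- label_volume(vox, diag(c(0.35, 0.35, 0.7, 1)))
  for (lab in 1:3) {
    fp <- project_axial(vol, lab)
    want <- matrix(FALSE, 30, 30)
    for (i in 1:30) for (j in 1:30) for (k in 1:30) {
      if (vox[i, j, k] == lab) want[i, j] <- TRUE
    }
    expect_identical(fp$occupancy, want)
  }
  expect_error(project_axial(vol, 7L), "label_absent")
  expect_error(project_axial(vol, "femur"), "label_absent")
})

test_that("extent operators: single cell, voxelized bar, rotated bar", {
  one <- footprint2d(matrix(TRUE, 1, 1), 0, 0)
  one$dx <- one$dy <- 0.35
  expect_equal(ap_extent(one), 0.35)
  expect_equal(ml_max_width(one), 0.35)

  # 30 mm bar along y at 0.35 mm spacing
  y <- seq(0, 40, by = 0.35)
  occ <- matrix(y >= 5 & y <= 35, nrow = 1)[, , drop = FALSE]
  occ <- matrix(y >= 5 & y <= 5 + 30, nrow = 1)
  fp <- footprint2d(rbind(occ), c(0), y)
  fp$dx <- 0.35
  expect_lt(abs(ap_extent(fp) - 30), 0.35 + 1e-9)
  fp_t <- footprint2d(t(rbind(occ)), y, c(0))
  fp_t$dy <- 0.35
  expect_lt(abs(ml_max_width(fp_t) - 30), 0.35 + 1e-9)

  expect_error(ap_extent(footprint2d(matrix(FALSE, 2, 2), 1:2, 1:2)),
               "footprint_empty")
})

test_that("body width on a disc and degenerate central third", {
  # full disc of diameter D: minimum over the central third is the chord at
  # one-third offset, 0.9428 D; allow voxel granularity
  D <- 30; sp <- 0.35
  xs <- seq(-16, 16, by = sp); ys <- seq(-16, 16, by = sp)
  occ <- outer(xs, ys, function(x, y) x^2 + y^2 <= (D / 2)^2)
  fp <- footprint2d(occ, xs, ys)
  a <- body_min_width(fp, side_sign = 1)
  expect_gt(a, 0.94 * D)
  expect_lt(a, D + 2 * sp)

  # two blobs far anterior/posterior: central third is empty
  occ2 <- matrix(FALSE, 41, 41)
  occ2[18:24, 1:3] <- TRUE
  occ2[18:24, 39:41] <- TRUE
  fp2 <- footprint2d(occ2, seq_len(41) * sp, seq_len(41) * sp)
  expect_error(body_min_width(fp2), "footprint_empty")
})

test_that("max-diameter column: symmetry, tie break, constructed horns", {
  D <- 30; sp <- 0.35
  xs <- seq(-16, 16, by = sp); ys <- seq(-16, 16, by = sp)
  occ <- outer(xs, ys, function(x, y) x^2 + y^2 <= (D / 2)^2)
  fp <- footprint2d(occ, xs, ys)
  md <- max_diameter_column(fp)
  expect_lt(abs(md$x), sp)               # central column
  expect_lt(abs(md$e - D), sp + 1e-9)

  # two equal-span columns: center rule picks the one nearest the plateau
  # centroid (first on an exact tie); the peripheral rule is still available
  occ2 <- matrix(FALSE, 5, 9)
  occ2[2, 2:8] <- TRUE
  occ2[4, 1:7] <- TRUE
  fp2 <- footprint2d(occ2, seq_len(5), seq_len(9))
  expect_equal(max_diameter_column(fp2)$col, 2L)
  expect_equal(max_diameter_column(fp2, side_sign = 1, tie = "peripheral")$col, 4L)
  expect_equal(max_diameter_column(fp2, side_sign = -1, tie = "peripheral")$col, 2L)
  occ2b <- matrix(FALSE, 7, 9)
  occ2b[c(2, 4, 6), 1:7] <- TRUE
  fp2b <- footprint2d(occ2b, seq_len(7), seq_len(9))
  expect_equal(max_diameter_column(fp2b)$col, 4L)

  # constructed column: two runs of 8 cells, gap 10, spacing 0.35
  col <- c(rep(TRUE, 8), rep(FALSE, 10), rep(TRUE, 8))
  occ3 <- matrix(col, nrow = 1)
  fp3 <- footprint2d(occ3, 0, seq_along(col) * 0.35)
  fp3$dx <- 0.35
  hc <- horn_coverage(fp3, 0)
  expect_equal(hc$c, 2.8)
  expect_equal(hc$d, 2.8)
  expect_equal(hc$covered, 5.6)
  # single full-span run: c + d = covered = e, PCM = 1
  occ4 <- matrix(rep(TRUE, 26), nrow = 1)
  fp4 <- footprint2d(occ4, 0, seq_len(26) * 0.35)
  fp4$dx <- 0.35
  hc4 <- horn_coverage(fp4, 0)
  expect_equal(hc4$c + hc4$d, hc4$covered)
  expect_equal(hc4$covered, 26 * 0.35)
})

test_that("all operators match brute-force oracles on random footprints", {
  set.seed(77)
  for (rep in 1:20) {
    fp <- random_footprint(40)
    occ <- fp$occupancy
    expect_equal(ap_extent(fp), brute$ap_extent(occ, fp$dy))
    expect_equal(ml_max_width(fp), brute$ml_max_width(occ, fp$dx))
    md <- max_diameter_column(fp)
    bd <- brute$max_diameter(occ, fp$dy)
    expect_equal(md$col, bd$col)
    expect_equal(md$e, bd$e)
    runs <- brute$runs_in_col(occ[md$col, ])
    hc <- horn_coverage(fp, md$x)
    expect_equal(hc$covered, sum(runs) * fp$dy)
    if (length(runs) >= 2) {
      expect_equal(hc$d, runs[1] * fp$dy)
      expect_equal(hc$c, runs[length(runs)] * fp$dy)
    }
    for (ss in c(1, -1)) {
      a_pkg <- tryCatch(body_min_width(fp, side_sign = ss),
                        error = function(e) NA_real_)
      a_ref <- brute$body_min_width(occ, fp$x_mm, fp$y_mm, fp$dx, fp$dy, ss)
      if (!is.na(a_pkg)) expect_equal(a_pkg, a_ref)
    }
  }
})

test_that("compute_indices: worked L/M examples and exact symmetry", {
  # cadaveric sizing data: the two published AP diameter pairs
  expect_equal(lm_ratio_from_lengths(35.8, 47.2), 0.758, tolerance = 0.003)
  expect_equal(lm_ratio_from_lengths(34.0, 43.0), 0.790, tolerance = 0.003)
  expect_error(lm_ratio_from_lengths(30, 0), "morphometry_degenerate")

  # identical lateral and mirrored medial shapes give L/M = 1 exactly
  s <- tiny_spec()
  s$medial <- meniscus_shape(c(-8, 0), r_out_ml = 7, r_out_ap = 8,
                             side = "medial")
  res <- compute_indices(generate_knee(s)$volume)
  expect_identical(res$lm_ratio, 1)
  expect_equal(res$rmt, res$a_body_min_width_mm / res$b_tibia_max_width_mm)
})

test_that("parameter recovery against phantom ground truth (spot checks)", {
  for (seed in c(1, 2)) {
    s <- small_spec(seed = seed)
    g <- generate_knee(s)
    res <- compute_indices(g$volume)
    gt <- g$truth
    tol_xy <- 2 * s$spacing[1]
    expect_lt(abs(res$a_body_min_width_mm - gt$a), tol_xy)
    expect_lt(abs(res$b_tibia_max_width_mm - gt$b), tol_xy)
    expect_lt(abs(res$e_max_ap_diameter_mm - gt$e), tol_xy)
    expect_lt(abs(res$L_lateral_ap_mm - gt$L), tol_xy)
    expect_lt(abs(res$M_medial_ap_mm - gt$M), tol_xy)
    expect_lt(abs(res$rmt - gt$rmt), 0.03)
    expect_lt(abs(res$pcm - gt$pcm), 0.03)
    expect_lt(abs(res$lm_ratio - gt$lm_ratio), 0.03)
  }
})

test_that("fragmented lateral footprints are flagged", {
  s <- tiny_spec()
  g <- generate_knee(s)
  vox <- g$volume$voxels
  # carve the lateral meniscus in two with a radial cut
  xs <- seq_len(dim(vox)[1])
  cut <- which(abs((xs - (dim(vox)[1] + 1) / 2) * 0.5 - 8) < 0.5)
  vox[cut, , ][vox[cut, , ] == 2L] <- 0L
  res <- compute_indices(label_volume(vox, g$volume$affine))
  expect_true(res$fragmented)
  expect_gt(res$lateral_components, 1L)
})
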