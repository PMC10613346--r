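# Shared fixtures: compact phantom specs that keep unit tests fast.
# `small_spec()` keeps the study's anisotropic voxel size but crops the field
# of view to what the structures need; `tiny_spec()` additionally coarsens the
# voxels for tests where speed matters more than resolution.

small_spec <- function(..., seed = 1L) {
  knee_phantom_spec(field_mm = c(100, 70, 20), seed = seed, ...)
}

tiny_spec <- function(seed = 1L, jitter_mm = 0) {
  knee_phantom_spec(
    lateral = meniscus_shape(c(8, 0), r_out_ml = 7, r_out_ap = 8,
                             side = "lateral"),
    medial = meniscus_shape(c(-8, 0), r_out_ml = 7, r_out_ap = 9,
                            side = "medial"),
    tibia_ml_semi = 17, tibia_ap_semi = 12,
    spacing = c(0.5, 0.5, 1), field_mm = c(40, 40, 10),
    jitter_mm = jitter_mm, seed = seed)
}

complete_discoid_spec <- function(seed = 1L) {
  lat <- dlm_lateral_shape(coverage = 1)
  lat$opening_angle <- 0
  knee_phantom_spec(lateral = lat, field_mm = c(100, 70, 20), seed = seed)
}

# independent per-pixel reference implementations of the footprint operators
# (straight loops, no shared code with the package internals)
brute <- list(
  ap_extent = function(occ, dy) {
    rows <- integer()
    for (j in seq_len(ncol(occ))) if (any(occ[, j])) rows <- c(rows, j)
    (max(rows) - min(rows) + 1) * dy
  },
  ml_max_width = function(occ, dx) {
    best <- 0L
    for (j in seq_len(ncol(occ))) {
      i <- which(occ[, j])
      if (length(i)) best <- max(best, max(i) - min(i) + 1L)
    }
    best * dx
  },
  max_diameter = function(occ, dy) {
    spans <- integer(nrow(occ))
    for (i in seq_len(nrow(occ))) {
      j <- which(occ[i, ])
      spans[i] <- if (length(j)) max(j) - min(j) + 1L else 0L
    }
    cands <- which(spans == max(spans))
    # center tie rule: tied column nearest the plateau centroid, first wins
    i_star <- cands[which.min(abs(cands - mean(cands)))]
    list(col = i_star, e = max(spans) * dy)
  },
  runs_in_col = function(v) {
    runs <- list(); len <- 0L
    for (j in seq_along(v)) {
      if (v[j]) len <- len + 1L
      if ((!v[j] || j == length(v)) && len > 0L) {
        runs[[length(runs) + 1L]] <- len
        len <- 0L
      }
    }
    unlist(runs)
  },
  body_min_width = function(occ, x_mm, y_mm, dx, dy, side_sign,
                            frac = 1 / 3) {
    rows <- which(vapply(seq_along(y_mm), function(j) any(occ[, j]),
                         logical(1)))
    y_lo <- y_mm[min(rows)] - dy / 2
    y_hi <- y_mm[max(rows)] + dy / 2
    mid <- (y_lo + y_hi) / 2
    hb <- (y_hi - y_lo) * frac / 2
    best <- Inf
    for (j in seq_along(y_mm)) {
      if (y_mm[j] < mid - hb || y_mm[j] > mid + hb) next
      col <- occ[, j]
      if (!any(col)) next
      # peripheral-adjacent run
      runs <- rle(col)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      occ_runs <- which(runs$values)
      k <- if (side_sign >= 0) occ_runs[length(occ_runs)] else occ_runs[1]
      best <- min(best, runs$lengths[k] * dx)
    }
    best
  }
)

random_footprint <- function(n = 40, p = 0.3) {
  occ <- matrix(stats::runif(n * n) < p, n, n)
  if (!any(occ)) occ[n %/% 2, n %/% 2] <- TRUE
  footprint2d(occ, seq_len(n) * 0.35, seq_len(n) * 0.35)
}
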