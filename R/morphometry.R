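# Axial-footprint morphometry. All operators work on a Footprint2D: the
# top-down (axial) projection of one structure's 3D mask, in anatomical mm
# coordinates. Lengths follow the voxel-box model -- a run of n cells at
# spacing s measures n*s mm (outer face to outer face) -- so a voxelized bar
# of physical length l measures l to within one spacing.
#
# Index definitions (measured on the view from the top):
#   RMT  = a / b   minimum meniscal body width over maximum tibial width
#   PCM  = (c + d) / e  anterior + posterior horn widths over the AP diameter
#                        at the maximum-diameter sagittal line
#   L/M  = L / M   lateral over medial AP diameter

#' Construct a 2D footprint
#'
#' @param occupancy logical matrix, first index ML (x), second PA (y).
#' @param x_mm,y_mm strictly increasing, uniformly spaced cell-center
#'   coordinates in mm.
#' @param source_label label id the footprint was projected from.
#' @return object of class `footprint2d`.
#' @export
footprint2d <- function(occupancy, x_mm, y_mm, source_label = NA_integer_) {
  stopifnot(is.matrix(occupancy), is.logical(occupancy),
            nrow(occupancy) == length(x_mm), ncol(occupancy) == length(y_mm))
  check_uniform <- function(v, nm) {
    if (length(v) > 1) {
      d <- diff(v)
      if (any(d <= 0) || diff(range(d)) > 1e-6 * mean(d)) {
        stop("footprint_invalid: ", nm,
             " coordinates must be strictly increasing and uniform",
             call. = FALSE)
      }
    }
  }
  check_uniform(x_mm, "x"); check_uniform(y_mm, "y")
  structure(list(occupancy = occupancy, x_mm = as.numeric(x_mm),
                 y_mm = as.numeric(y_mm),
                 dx = if (length(x_mm) > 1) x_mm[2] - x_mm[1] else NA_real_,
                 dy = if (length(y_mm) > 1) y_mm[2] - y_mm[1] else NA_real_,
                 source_label = source_label),
            class = "footprint2d")
}

stop_if_empty <- function(fp, op) {
  if (!any(fp$occupancy)) {
    stop("footprint_empty: ", op, " needs a non-empty footprint",
         call. = FALSE)
  }
}

#' Project a label to its axial footprint
#'
#' Collapses z: a cell is occupied iff at least one voxel with the requested
#' label shares its (x, y) center.
#'
#' @param vol a [label_volume()].
#' @param label structure name (e.g. `"lateral_meniscus"`) or integer label id.
#' @return a [footprint2d()].
#' @export
project_axial <- function(vol, label) {
  id <- if (is.character(label)) {
    if (!label %in% names(vol$label_map)) {
      stop("label_absent: unknown structure name '", label, "'", call. = FALSE)
    }
    vol$label_map[[label]]
  } else as.integer(label)
  m <- vol$voxels == id
  dims <- dim(vol$voxels)
  occ <- matrix(rowSums(matrix(m, nrow = dims[1] * dims[2])) > 0,
                nrow = dims[1], ncol = dims[2])
  if (!any(occ)) {
    stop("label_absent: label ", id, " has no voxels", call. = FALSE)
  }
  footprint2d(occ, axis_coords(vol, 1), axis_coords(vol, 2), source_label = id)
}

#' Anteroposterior extent of a footprint
#'
#' Outer-face span along y: (last occupied row - first occupied row + 1) * dy.
#' This is the meniscal AP diameter (symbols L and M).
#'
#' @param fp a [footprint2d()].
#' @return length in mm.
#' @export
ap_extent <- function(fp) {
  stop_if_empty(fp, "ap_extent")
  j <- which(colSums(fp$occupancy) > 0)
  (j[length(j)] - j[1] + 1) * fp$dy
}

#' Maximum mediolateral width of a footprint
#'
#' Maximum over rows y of the first-to-last occupied span along x (symbol b
#' when applied to the tibial plateau).
#'
#' @param fp a [footprint2d()].
#' @return width in mm.
#' @export
ml_max_width <- function(fp) {
  stop_if_empty(fp, "ml_max_width")
  spans <- apply(fp$occupancy, 2, function(col) {
    i <- which(col)
    if (!length(i)) 0L else i[length(i)] - i[1] + 1L
  })
  max(spans) * fp$dx
}

#' Minimum meniscal body width (symbol a)
#'
#' Over the rows whose centers lie in the central `body_fraction` of the
#' footprint's AP extent, takes the occupied run adjacent to the peripheral
#' edge (largest x for a lateral meniscus, `side_sign = +1`) and returns the
#' minimum run length. Using the peripheral-adjacent run excludes the inner
#' hollow of a crescent while spanning toward the midline for a filled
#' discoid.
#'
#' @param fp a [footprint2d()].
#' @param side_sign +1 if the periphery is at larger x (lateral meniscus in
#'   right-knee convention), -1 otherwise.
#' @param body_fraction central fraction of the AP extent treated as the body.
#' @return width in mm.
#' @export
body_min_width <- function(fp, side_sign = 1, body_fraction = 1 / 3) {
  stop_if_empty(fp, "body_min_width")
  occ_rows <- which(colSums(fp$occupancy) > 0)
  y_lo <- fp$y_mm[occ_rows[1]] - fp$dy / 2
  y_hi <- fp$y_mm[occ_rows[length(occ_rows)]] + fp$dy / 2
  mid <- (y_lo + y_hi) / 2
  half_band <- (y_hi - y_lo) * body_fraction / 2
  rows <- which(fp$y_mm >= mid - half_band & fp$y_mm <= mid + half_band)
  widths <- vapply(rows, function(j) {
    col <- fp$occupancy[, j]
    if (!any(col)) return(NA_real_)
    r <- rle(col)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    occ <- which(r$values)
    run <- if (side_sign >= 0) occ[length(occ)] else occ[1]
    r$lengths[run] * fp$dx
  }, numeric(1))
  widths <- widths[!is.na(widths)]
  if (!length(widths)) {
    stop("footprint_empty: no occupied rows in the central body band",
         call. = FALSE)
  }
  min(widths)
}

#' Column of maximum AP diameter (symbol e)
#'
#' Finds the ML position x* whose column has the largest first-to-last
#' occupied span along y; e is that span. At voxel resolution the maximal
#' span is attained on a plateau of columns; by default ties break to the
#' column nearest the plateau's center, which is stable across grid
#' resolutions (a peripheral tie-break lets x* slide to where a near-discoid
#' footprint's inner hole closes, biasing c, d and PCM by far more than one
#' voxel against a fine-grid reference).
#'
#' @param fp a [footprint2d()].
#' @param side_sign +1 if the periphery is at larger x (used by
#'   `tie = "peripheral"`).
#' @param tie `"center"` (default) or `"peripheral"`.
#' @return list with `x` (mm), `col` (index) and `e` (mm).
#' @export
max_diameter_column <- function(fp, side_sign = 1,
                                tie = c("center", "peripheral")) {
  tie <- match.arg(tie)
  stop_if_empty(fp, "max_diameter_column")
  spans <- apply(fp$occupancy, 1, function(row) {
    j <- which(row)
    if (!length(j)) 0L else j[length(j)] - j[1] + 1L
  })
  best <- which(spans == max(spans))
  i_star <- if (tie == "center") {
    best[which.min(abs(best - mean(best)))]
  } else if (side_sign >= 0) best[length(best)] else best[1]
  list(x = fp$x_mm[i_star], col = i_star, e = max(spans) * fp$dy)
}

#' Anterior and posterior horn widths at a sagittal line (symbols c, d)
#'
#' Measures the occupied runs along y in the column at x*. `c` is the
#' anterior-most run's length, `d` the posterior-most; `covered` is the total
#' occupied length including any middle runs. For a single full-span run
#' (complete discoid) c + d equals the run length and PCM = covered / e = 1.
#'
#' @param fp a [footprint2d()].
#' @param x_star ML position in mm (snapped to the nearest column).
#' @return list with `c`, `d`, `covered` (mm) and `n_runs`.
#' @export
horn_coverage <- function(fp, x_star) {
  stop_if_empty(fp, "horn_coverage")
  i <- which.min(abs(fp$x_mm - x_star))
  col <- fp$occupancy[i, ]
  if (!any(col)) {
    stop("footprint_empty: column at x = ", signif(x_star, 4),
         " mm has no occupied cells", call. = FALSE)
  }
  r <- rle(col)
  lens <- r$lengths[r$values] * fp$dy
  n_runs <- length(lens)
  if (n_runs == 1L) {
    # single run: the horns meet; split the full width evenly so c + d equals
    # the covered length
    list(c = lens / 2, d = lens / 2, covered = lens, n_runs = 1L)
  } else {
    # y increases toward anterior: last run is the anterior horn
    list(c = lens[n_runs], d = lens[1], covered = sum(lens), n_runs = n_runs)
  }
}

# count 4-connected components of a footprint (fragmentation flag)
count_components <- function(fp) {
  occ <- fp$occupancy
  lab <- matrix(0L, nrow(occ), ncol(occ))
  nxt <- 0L
  idx <- which(occ)
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    nr <- nrow(occ)
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (cur - 1L) %% nr + 1L
      j <- (cur - 1L) %/% nr + 1L
      for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
        if (nb[1] >= 1L && nb[1] <= nr && nb[2] >= 1L && nb[2] <= ncol(occ)) {
          flat <- nb[1] + (nb[2] - 1L) * nr
          if (occ[flat] && lab[flat] == 0L) {
            lab[flat] <- nxt
            queue <- c(queue, flat)
          }
        }
      }
    }
  }
  nxt
}

#' Compute the three DLM indices from a label volume
#'
#' Reproduces the manual measurement protocol on the axial footprints:
#' `a` = minimum body width of the lateral meniscus, `b` = maximum tibial
#' width, `(c, d, e)` at the lateral footprint's maximum-AP-diameter column,
#' `L`/`M` = lateral/medial AP extents; then RMT = a/b, PCM = covered/e
#' (equal to (c+d)/e unless the footprint has more than two runs at x*),
#' L/M = L/M.
#'
#' @param vol a [label_volume()] containing all three structures.
#' @param body_fraction central AP fraction used for the body (default 1/3).
#' @return object of class `morphometry_result`.
#' @export
compute_indices <- function(vol, body_fraction = 1 / 3) {
  fp_lat <- project_axial(vol, "lateral_meniscus")
  fp_med <- project_axial(vol, "medial_meniscus")
  fp_tib <- project_axial(vol, "tibial_plateau")

  a <- body_min_width(fp_lat, side_sign = 1, body_fraction = body_fraction)
  b <- ml_max_width(fp_tib)
  md <- max_diameter_column(fp_lat, side_sign = 1)
  hc <- horn_coverage(fp_lat, md$x)
  L <- ap_extent(fp_lat)
  M <- ap_extent(fp_med)
  if (b <= 0 || md$e <= 0 || M <= 0) {
    stop("morphometry_degenerate: zero denominator (b, e or M)",
         call. = FALSE)
  }
  n_comp <- count_components(fp_lat)
  structure(list(
    a_body_min_width_mm = a, b_tibia_max_width_mm = b,
    c_anterior_horn_mm = hc$c, d_posterior_horn_mm = hc$d,
    e_max_ap_diameter_mm = md$e, L_lateral_ap_mm = L, M_medial_ap_mm = M,
    rmt = a / b, pcm = min(hc$covered / md$e, 1), lm_ratio = L / M,
    lateral_components = n_comp, fragmented = n_comp > 1L),
    class = "morphometry_result")
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat("<morphometry_result>\n")
  cat(sprintf("  a = %.2f mm  b = %.2f mm  c = %.2f mm  d = %.2f mm  e = %.2f mm\n",
              x$a_body_min_width_mm, x$b_tibia_max_width_mm,
              x$c_anterior_horn_mm, x$d_posterior_horn_mm,
              x$e_max_ap_diameter_mm))
  cat(sprintf("  L = %.2f mm  M = %.2f mm\n",
              x$L_lateral_ap_mm, x$M_medial_ap_mm))
  cat(sprintf("  RMT = %.3f  PCM = %.3f  L/M = %.3f\n",
              x$rmt, x$pcm, x$lm_ratio))
  if (isTRUE(x$fragmented)) {
    cat("  WARNING: lateral footprint has ", x$lateral_components,
        " components; measurements on torn/fragmented menisci are unreliable\n",
        sep = "")
  }
  invisible(x)
}

#' L/M ratio from two AP diameters
#'
#' Convenience for computing the lateral-to-medial AP diameter ratio directly
#' from measured lengths, e.g. published meniscal sizing data.
#'
#' @param L,M lateral and medial AP diameters in mm.
#' @return L / M.
#' @export
lm_ratio_from_lengths <- function(L, M) {
  if (any(M <= 0) || any(L < 0)) {
    stop("morphometry_degenerate: need L >= 0 and M > 0", call. = FALSE)
  }
  L / M
}
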