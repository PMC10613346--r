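# Parametric knee phantom: C-shaped elliptical-annulus menisci spanning the
# crescent -> discoid continuum, plus an elliptical tibial-plateau cartilage
# slab, voxelized at MRI-like anisotropic spacing with analytically known
# ground-truth morphometry.
#
# Continuous shape model. A meniscus footprint lives on the outer ellipse
# with semi-axes r_out_ml (x) and r_out_ap (y) about `center`. In elliptical
# coordinates (rho = scaled radius, theta = scaled angle) a point belongs to
# the footprint iff it is outside the opening gap (which faces the
# intercondylar midline) and rho lies in [inner(theta), 1], where
# inner(theta) = 1 - max(coverage, w(theta)) and w(theta) interpolates the
# anterior-horn / body / posterior-horn radial width fractions
# piecewise-smoothly over angle. coverage = 1 fills the spanned sector
# completely (complete discoid).

#' Construct a meniscus shape
#'
#' @param center (x, y) footprint center in mm; x = ML, y = PA (+y anterior).
#' @param r_out_ml,r_out_ap outer semi-axes in mm; the AP diameter of the
#'   meniscus equals `2 * r_out_ap`.
#' @param opening_angle angular width (radians) of the C-shape gap facing the
#'   intercondylar midline; 0 closes the ring.
#' @param w_ant,w_body,w_post radial width fractions in (0, 1] at the anterior
#'   horn, mid-body and posterior horn.
#' @param coverage scalar in (0, 1]; the footprint fills the outer ellipse
#'   down to `1 - max(coverage, w(theta))`, so 1 gives a complete discoid.
#' @param thickness_mm superoinferior thickness of the voxelized meniscus.
#' @param side `"medial"` or `"lateral"`; decides which way the gap and the
#'   body apex face (the body apex is peripheral, away from the midline).
#' @return object of class `meniscus_shape`.
#' @export
meniscus_shape <- function(center, r_out_ml, r_out_ap,
                           opening_angle = 0.9,
                           w_ant = 0.5, w_body = 0.45, w_post = 0.5,
                           coverage = 0.2, thickness_mm = 4,
                           side = c("lateral", "medial")) {
  side <- match.arg(side)
  if (r_out_ml <= 0 || r_out_ap <= 0) {
    stop("shape_invalid: outer semi-axes must be > 0", call. = FALSE)
  }
  ws <- c(w_ant, w_body, w_post)
  if (any(ws <= 0) || any(ws > 1)) {
    stop("shape_invalid: width fractions must lie in (0, 1]", call. = FALSE)
  }
  if (coverage <= 0 || coverage > 1) {
    stop("shape_invalid: coverage must lie in (0, 1]", call. = FALSE)
  }
  if (opening_angle < 0 || opening_angle >= pi) {
    stop("shape_invalid: opening_angle must lie in [0, pi)", call. = FALSE)
  }
  if (thickness_mm <= 0) {
    stop("shape_invalid: thickness_mm must be > 0", call. = FALSE)
  }
  structure(list(center = as.numeric(center), r_out_ml = r_out_ml,
                 r_out_ap = r_out_ap, opening_angle = opening_angle,
                 w_ant = w_ant, w_body = w_body, w_post = w_post,
                 coverage = coverage, thickness_mm = thickness_mm,
                 side = side),
            class = "meniscus_shape")
}

# interpolated radial width fraction at elliptical angle theta.
# phi is measured from the body apex (the peripheral point: theta = 0 for a
# lateral meniscus at +x, theta = pi for a medial one). Within a quarter turn
# of the apex the width blends body -> horn with a cos^2 ramp (C1 smooth);
# beyond that it holds the horn value out to the gap.
width_fraction <- function(shape, theta) {
  theta_body <- if (shape$side == "lateral") 0 else pi
  phi <- wrap_angle(theta - theta_body)
  # anterior (+y) corresponds to phi > 0 for lateral, phi < 0 for medial
  s_ant <- if (shape$side == "lateral") phi else -phi
  w_horn <- ifelse(s_ant > 0, shape$w_ant, shape$w_post)
  blend <- abs(phi) <= pi / 2
  w <- w_horn
  w[blend] <- shape$w_body * cos(phi[blend])^2 + w_horn[blend] * sin(phi[blend])^2
  w
}

wrap_angle <- function(a) {
  ((a + pi) %% (2 * pi)) - pi
}

#' Point membership in a continuous meniscus footprint
#'
#' Deterministic membership test for the continuous (unvoxelized) axial
#' footprint. Vectorized over points; boundaries are closed.
#'
#' @param shape a [meniscus_shape()].
#' @param x,y point coordinates in mm (equal-length vectors).
#' @param jitter optional list of two functions `outer(theta)` and
#'   `inner(theta)` returning a radial displacement in mm, used by the
#'   voxelizer to emulate segmentation boundary error; omit for the exact
#'   shape.
#' @return logical vector.
#' @export
footprint_membership <- function(shape, x, y, jitter = NULL) {
  u <- (x - shape$center[1]) / shape$r_out_ml
  v <- (y - shape$center[2]) / shape$r_out_ap
  rho <- sqrt(u^2 + v^2)
  theta <- atan2(v, u)

  theta_gap <- if (shape$side == "lateral") pi else 0
  in_gap <- shape$opening_angle > 0 &
    abs(wrap_angle(theta - theta_gap)) < shape$opening_angle / 2

  inner <- 1 - pmax(shape$coverage, width_fraction(shape, theta))
  if (!is.null(jitter)) {
    # convert a mm displacement into elliptical-radius units at this angle
    r_local <- 1 / sqrt((cos(theta) / shape$r_out_ml)^2 +
                        (sin(theta) / shape$r_out_ap)^2)
    outer_lim <- 1 + jitter$outer(theta) / r_local
    inner <- pmax(inner - jitter$inner(theta) / r_local, 0)
  } else {
    outer_lim <- 1
  }
  !in_gap & rho <= outer_lim & rho >= inner
}

#' Construct a knee phantom specification
#'
#' The defaults describe a normal (non-discoid) adult knee at the acquisition
#' geometry of an axial 3D proton-density sequence: 0.35 mm in-plane
#' resolution and 0.7 mm slices.
#'
#' @param lateral,medial [meniscus_shape()] objects; defaults give a normal
#'   crescent lateral meniscus (AP diameter 35 mm) and medial meniscus (AP
#'   diameter 47.2 mm).
#' @param tibia_ml_semi,tibia_ap_semi semi-axes in mm of the elliptical tibial
#'   plateau footprint (centered on the midline).
#' @param tibia_thickness_mm thickness of the plateau cartilage slab; the
#'   default is an exact multiple of the 0.7 mm slice thickness so the slab
#'   voxelizes without a partial slice.
#' @param spacing voxel size (dx, dy, dz) in mm.
#' @param field_mm physical extent of the simulated volume in mm.
#' @param jitter_mm amplitude (sd) of smooth seeded radial boundary noise;
#'   0 disables it.
#' @param seed RNG seed used for the jitter draw (volume is a pure function
#'   of the spec).
#' @return object of class `knee_phantom_spec`.
#' @export
knee_phantom_spec <- function(lateral = default_lateral_shape(),
                              medial = default_medial_shape(),
                              tibia_ml_semi = 37.5, tibia_ap_semi = 25,
                              tibia_thickness_mm = 2.8,
                              spacing = c(0.35, 0.35, 0.7),
                              field_mm = c(160, 160, 60),
                              jitter_mm = 0, seed = 1L) {
  stopifnot(inherits(lateral, "meniscus_shape"),
            inherits(medial, "meniscus_shape"))
  if (lateral$side != "lateral" || medial$side != "medial") {
    stop("spec_invalid: shapes passed to the wrong slot", call. = FALSE)
  }
  if (tibia_ml_semi <= 0 || tibia_ap_semi <= 0 || tibia_thickness_mm <= 0) {
    stop("spec_invalid: tibia dimensions must be > 0", call. = FALSE)
  }
  if (any(spacing <= 0) || any(field_mm <= 0)) {
    stop("spec_invalid: spacing and field must be > 0", call. = FALSE)
  }
  if (jitter_mm < 0) stop("spec_invalid: jitter_mm must be >= 0", call. = FALSE)
  spec <- structure(
    list(lateral = lateral, medial = medial,
         tibia_ml_semi = tibia_ml_semi, tibia_ap_semi = tibia_ap_semi,
         tibia_thickness_mm = tibia_thickness_mm,
         spacing = as.numeric(spacing), field_mm = as.numeric(field_mm),
         jitter_mm = jitter_mm, seed = as.integer(seed)),
    class = "knee_phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' Default lateral meniscus (normal crescent)
#' @export
default_lateral_shape <- function() {
  meniscus_shape(center = c(19, 0), r_out_ml = 16, r_out_ap = 17.5,
                 opening_angle = 0.9, w_ant = 0.5, w_body = 0.45,
                 w_post = 0.5, coverage = 0.2, thickness_mm = 4,
                 side = "lateral")
}

#' Default medial meniscus
#' @export
default_medial_shape <- function() {
  meniscus_shape(center = c(-19, 0), r_out_ml = 16, r_out_ap = 23.6,
                 opening_angle = 1.6, w_ant = 0.45, w_body = 0.4,
                 w_post = 0.55, coverage = 0.2, thickness_mm = 4,
                 side = "medial")
}

#' Discoid lateral meniscus shape (DLM stated world)
#'
#' A broad, high-coverage lateral meniscus whose defaults land the cohort
#' means near the reported DLM group: RMT around 0.25, PCM around 0.85 and a
#' reduced AP diameter giving L/M near 0.66 against the default medial shape.
#' @param coverage coverage fraction; 1 gives a complete discoid.
#' @export
dlm_lateral_shape <- function(coverage = 0.85) {
  meniscus_shape(center = c(14, 0), r_out_ml = 22, r_out_ap = 15.6,
                 opening_angle = 0.7, w_ant = 0.6, w_body = 0.55,
                 w_post = 0.6, coverage = coverage, thickness_mm = 5,
                 side = "lateral")
}

validate_phantom_spec <- function(spec) {
  half <- spec$field_mm / 2
  for (nm in c("lateral", "medial")) {
    sh <- spec[[nm]]
    if (abs(sh$center[1]) + sh$r_out_ml > half[1] ||
        abs(sh$center[2]) + sh$r_out_ap > half[2]) {
      stop("spec_invalid: ", nm, " meniscus footprint exceeds the volume field",
           call. = FALSE)
    }
    ml_lo <- sh$center[1] - sh$r_out_ml
    ml_hi <- sh$center[1] + sh$r_out_ml
    if (ml_lo < -spec$tibia_ml_semi - 1e-9 ||
        ml_hi > spec$tibia_ml_semi + 1e-9) {
      stop("spec_invalid: ", nm, " meniscus ML extent exceeds the tibial ",
           "plateau", call. = FALSE)
    }
  }
  if (spec$tibia_ml_semi > half[1] || spec$tibia_ap_semi > half[2]) {
    stop("spec_invalid: tibial footprint exceeds the volume field",
         call. = FALSE)
  }
  z_need <- spec$tibia_thickness_mm +
    max(spec$lateral$thickness_mm, spec$medial$thickness_mm)
  if (z_need > spec$field_mm[3]) {
    stop("spec_invalid: structures exceed the volume field in z", call. = FALSE)
  }
  invisible(spec)
}

# smooth periodic radial noise: order-4 Fourier series with N(0,1)
# coefficients, normalized so sd over theta equals `amp` mm
fourier_jitter <- function(amp, k_max = 4L) {
  if (amp == 0) return(function(theta) rep(0, length(theta)))
  a <- stats::rnorm(k_max)
  b <- stats::rnorm(k_max)
  scale <- amp / sqrt(k_max)
  function(theta) {
    out <- numeric(length(theta))
    for (k in seq_len(k_max)) {
      out <- out + a[k] * cos(k * theta) + b[k] * sin(k * theta)
    }
    scale * out
  }
}

#' Voxelize a knee phantom
#'
#' Labels a voxel with a structure id iff its center lies inside the (possibly
#' jittered) continuous footprint and inside the structure's z slab. The tibial
#' cartilage slab sits at the bottom of the volume with both menisci resting on
#' it. Ground truth is always computed on the exact, unjittered shapes; the
#' difference between measured and true indices is the voxelization +
#' segmentation error budget.
#'
#' @param spec a [knee_phantom_spec()].
#' @return list with `volume` (a [label_volume()]) and `truth`
#'   (a `ground_truth`, see [ground_truth_indices()]).
#' @export
generate_knee <- function(spec) {
  validate_phantom_spec(spec)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)

  jit <- function() {
    if (spec$jitter_mm == 0) NULL
    else list(outer = fourier_jitter(spec$jitter_mm),
              inner = fourier_jitter(spec$jitter_mm))
  }
  # fixed draw order keeps volumes reproducible structure-by-structure
  jit_lat <- jit(); jit_med <- jit(); jit_tib <- jit()

  dims <- pmax(2L, as.integer(round(spec$field_mm / spec$spacing)))
  xc <- (seq_len(dims[1]) - (dims[1] + 1) / 2) * spec$spacing[1]
  yc <- (seq_len(dims[2]) - (dims[2] + 1) / 2) * spec$spacing[2]
  zc <- (seq_len(dims[3]) - 0.5) * spec$spacing[3]
  gx <- rep(xc, times = dims[2])
  gy <- rep(yc, each = dims[1])

  fp_lat <- footprint_membership(spec$lateral, gx, gy, jit_lat)
  fp_med <- footprint_membership(spec$medial, gx, gy, jit_med)
  if (any(fp_lat & fp_med)) {
    stop("shape_collision: lateral and medial footprints overlap",
         call. = FALSE)
  }
  tib_theta <- atan2(gy / spec$tibia_ap_semi, gx / spec$tibia_ml_semi)
  tib_rho <- sqrt((gx / spec$tibia_ml_semi)^2 + (gy / spec$tibia_ap_semi)^2)
  tib_lim <- 1
  if (!is.null(jit_tib)) {
    r_local <- 1 / sqrt((cos(tib_theta) / spec$tibia_ml_semi)^2 +
                        (sin(tib_theta) / spec$tibia_ap_semi)^2)
    tib_lim <- 1 + jit_tib$outer(tib_theta) / r_local
  }
  fp_tib <- tib_rho <= tib_lim

  vox <- integer(prod(dims))
  n_plane <- dims[1] * dims[2]
  lab <- default_label_map()
  fill <- function(fp, z0, z1, label) {
    ks <- which(zc >= z0 & zc < z1)
    idx2d <- which(fp)
    for (k in ks) vox[idx2d + (k - 1L) * n_plane] <<- label
  }
  z_men0 <- spec$tibia_thickness_mm
  fill(fp_tib, 0, spec$tibia_thickness_mm, lab[["tibial_plateau"]])
  fill(fp_med, z_men0, z_men0 + spec$medial$thickness_mm,
       lab[["medial_meniscus"]])
  fill(fp_lat, z_men0, z_men0 + spec$lateral$thickness_mm,
       lab[["lateral_meniscus"]])
  dim(vox) <- dims

  affine <- diag(c(spec$spacing, 1))
  affine[1:3, 4] <- c(xc[1], yc[1], zc[1])
  vol <- label_volume(vox, affine, lab, side = "right")
  list(volume = vol, truth = ground_truth_indices(spec))
}

#' Analytic ground-truth morphometry of a phantom
#'
#' Evaluates the study's raw lengths and indices on the continuous, unjittered
#' shapes: L and M (AP diameters) and b (maximum tibial width) in closed form;
#' a, c, d and e by applying the same operational definitions as the
#' measurement module to the continuous footprint sampled on a fine grid
#' (0.05 mm by default). For a closed complete discoid (coverage 1, no
#' opening) e, c and d use the exact disc values.
#'
#' @param spec a [knee_phantom_spec()].
#' @param resolution fine-grid step in mm.
#' @param body_fraction central AP fraction defining the meniscal body
#'   (matches the measurement default of one third).
#' @return object of class `ground_truth` with fields `a`, `b`, `c`, `d`,
#'   `e`, `L`, `M`, `rmt`, `pcm`, `lm_ratio`.
#' @export
ground_truth_indices <- function(spec, resolution = 0.05,
                                 body_fraction = 1 / 3) {
  lat <- spec$lateral
  fp <- continuous_footprint(lat, resolution)
  a <- body_min_width(fp, side_sign = 1, body_fraction = body_fraction)
  if (lat$coverage == 1 && lat$opening_angle == 0) {
    e <- 2 * lat$r_out_ap
    cc <- lat$r_out_ap
    d <- lat$r_out_ap
    pcm <- 1
  } else {
    md <- max_diameter_column(fp, side_sign = 1)
    hc <- horn_coverage(fp, md$x)
    e <- md$e
    cc <- hc$c
    d <- hc$d
    pcm <- min(hc$covered / e, 1)
  }
  L <- 2 * lat$r_out_ap
  M <- 2 * spec$medial$r_out_ap
  b <- 2 * spec$tibia_ml_semi
  structure(list(a = a, b = b, c = cc, d = d, e = e, L = L, M = M,
                 rmt = a / b, pcm = pcm, lm_ratio = L / M),
            class = "ground_truth")
}

# sample a continuous shape's membership on a fine grid and wrap it as a
# Footprint2D so measurement operators apply unchanged
continuous_footprint <- function(shape, resolution) {
  x <- seq(shape$center[1] - shape$r_out_ml - resolution,
           shape$center[1] + shape$r_out_ml + resolution, by = resolution)
  y <- seq(shape$center[2] - shape$r_out_ap - resolution,
           shape$center[2] + shape$r_out_ap + resolution, by = resolution)
  occ <- footprint_membership(shape, rep(x, times = length(y)),
                              rep(y, each = length(x)))
  dim(occ) <- c(length(x), length(y))
  footprint2d(occ, x, y, source_label = NA_integer_)
}

#' Isotropically scale a phantom specification
#'
#' Multiplies every mm shape parameter (not the voxel spacing) by `factor`.
#' All three ground-truth indices are dimensionless and invariant under this.
#'
#' @param spec a [knee_phantom_spec()].
#' @param factor positive scale factor.
#' @export
scale_knee_spec <- function(spec, factor) {
  stopifnot(factor > 0)
  sc_shape <- function(sh) {
    meniscus_shape(center = sh$center * factor,
                   r_out_ml = sh$r_out_ml * factor,
                   r_out_ap = sh$r_out_ap * factor,
                   opening_angle = sh$opening_angle,
                   w_ant = sh$w_ant, w_body = sh$w_body, w_post = sh$w_post,
                   coverage = sh$coverage,
                   thickness_mm = sh$thickness_mm * factor, side = sh$side)
  }
  knee_phantom_spec(lateral = sc_shape(spec$lateral),
                    medial = sc_shape(spec$medial),
                    tibia_ml_semi = spec$tibia_ml_semi * factor,
                    tibia_ap_semi = spec$tibia_ap_semi * factor,
                    tibia_thickness_mm = spec$tibia_thickness_mm * factor,
                    spacing = spec$spacing,
                    field_mm = spec$field_mm * factor,
                    jitter_mm = spec$jitter_mm, seed = spec$seed)
}
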