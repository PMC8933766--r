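#' Specification of a synthetic cerebellar phantom
#'
#' Describes the geometry, tissue contrast, coil bias and noise of a digital
#' phantom emulating a coronal T2-weighted mouse acquisition (default grid
#' 128 x 128 in-plane at 0.0781 mm and 0.5 mm slices). The phantom contains a
#' cerebellar ellipsoid split into an arborized white-matter core and a
#' grey-matter shell, plus a fourth-ventricle (CSF) compartment adjacent to
#' the cerebellum, all modulated by a smooth surface-coil gain profile.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param voxel_size_mm numeric length-3 spacing in mm.
#' @param cerebellum_radius_mm longest semi-axis of the cerebellar ellipsoid
#'   (mm); the other semi-axes scale as `c(1, 0.47, 0.935)` of it, giving a
#'   realistic ~50 mm^3 cerebellum at the default 3 mm.
#' @param wm_fraction fraction of cerebellar voxels assigned to white matter,
#'   in (0, 1). Default 0.5 (mouse cerebellar WM is roughly half the
#'   cerebellar volume).
#' @param ventricle_volume_mm3 target fourth-ventricle volume in mm^3. The
#'   generator selects exactly the voxel count closest to this target, so the
#'   label-derived volume is within half a voxel of it.
#' @param tissue_means named intensities (arbitrary scanner units) for
#'   `background`, `GM`, `WM`, `CSF`; must be pairwise distinct.
#' @param noise_sd additive Gaussian noise SD, same units as `tissue_means`.
#' @param bias_strength peak-to-trough ratio of the multiplicative coil gain
#'   (1 = flat field).
#' @param seed integer RNG seed; all randomness is drawn under it.
#' @return A validated list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(128L, 128L, 24L),
                         voxel_size_mm = c(0.0781, 0.0781, 0.5),
                         cerebellum_radius_mm = 3.0,
                         wm_fraction = 0.5,
                         ventricle_volume_mm3 = 1.5,
                         tissue_means = c(background = 800, GM = 6000,
                                          WM = 3500, CSF = 9000),
                         noise_sd = 100,
                         bias_strength = 1.5,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  stopifnot(length(grid_shape) == 3L, length(voxel_size_mm) == 3L)
  if (any(grid_shape < 4L)) stop("grid_shape axes must be >= 4", call. = FALSE)
  if (any(voxel_size_mm <= 0) || cerebellum_radius_mm <= 0 ||
      ventricle_volume_mm3 <= 0)
    stop("all geometric parameters must be strictly positive", call. = FALSE)
  if (!(wm_fraction > 0 && wm_fraction < 1))
    stop("wm_fraction must lie in (0, 1)", call. = FALSE)
  req <- c("background", "GM", "WM", "CSF")
  if (!all(req %in% names(tissue_means)))
    stop("tissue_means must name background, GM, WM and CSF", call. = FALSE)
  if (anyDuplicated(tissue_means[req]))
    stop("tissue_means must be pairwise distinct", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (bias_strength < 1)
    stop("bias_strength is a peak-to-trough ratio and must be >= 1",
         call. = FALSE)
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 cerebellum_radius_mm = cerebellum_radius_mm,
                 wm_fraction = wm_fraction,
                 ventricle_volume_mm3 = ventricle_volume_mm3,
                 tissue_means = tissue_means[req], noise_sd = noise_sd,
                 bias_strength = bias_strength, seed = as.integer(seed)),
            class = "phantom_spec")
}

cerebellum_semi_axes <- function(spec) {
  spec$cerebellum_radius_mm * c(1, 0.47, 0.935)
}

# world coordinates of voxel centres along each axis, origin at grid centre
grid_axes_mm <- function(spec) {
  lapply(1:3, function(a) {
    n <- spec$grid_shape[a]
    h <- spec$voxel_size_mm[a]
    (seq_len(n) - (n + 1) / 2) * h
  })
}

# smooth separable coil gain: exponential decay with depth along the y axis
# (coil on the dorsal surface of a coronally sliced head), normalized to
# mean 1 so correction preserves global intensity scale
phantom_bias_field <- function(spec) {
  n <- spec$grid_shape
  t <- if (n[2] > 1) (seq_len(n[2]) - 1) / (n[2] - 1) else 0
  profile <- exp(-log(spec$bias_strength) * t)
  g <- array(rep(rep(profile, each = n[1]), n[3]), dim = n)
  g / mean(g)
}

#' Generate a labeled cerebellar phantom
#'
#' Builds the ground-truth label map (0 background, 1 GM, 2 WM,
#' 3 CSF/ventricle) and the corresponding intensity volume
#' `tissue_means[label] * bias_field + noise`. The white-matter core is a
#' smooth lobed (arborized) region occupying exactly `wm_fraction` of the
#' cerebellar voxels, so the Laplacian-of-Gaussian stage has genuine closed
#' contours to detect. The ventricle is an ellipsoidal compartment placed
#' against the cerebellum whose voxel count matches `ventricle_volume_mm3`
#' to within half a voxel.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `cereb_phantom` with elements `image` ([image3d()]),
#'   `labels` ([label_map()]), `bias_field` (the true gain array) and `spec`.
#' @examples
#' ph <- make_phantom(phantom_spec(grid_shape = c(48, 48, 12), seed = 7))
#' measure_volumes(ph$labels)
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ax <- grid_axes_mm(spec)
  semi <- cerebellum_semi_axes(spec)
  extent <- spec$grid_shape * spec$voxel_size_mm

  # ventricle sizing (needed for the fit check): ellipsoid with semi-axis
  # ratios 1.4 : 1 : 1 whose analytic volume hits the target
  vr <- (spec$ventricle_volume_mm3 / (4 / 3 * pi * 1.4))^(1 / 3)
  vsemi <- vr * c(1.4, 1, 1)
  need <- 2 * (semi + c(0, 2 * vsemi[2], 0)) + 2 * spec$voxel_size_mm
  for (a in 1:3) {
    if (need[a] > extent[a])
      stop(sprintf(paste0("phantom does not fit the grid along axis %d: ",
                          "needs %.2f mm but the grid spans %.2f mm"),
                   a, need[a], extent[a]), call. = FALSE)
  }

  u <- ax[[1]] / semi[1]
  v <- ax[[2]] / semi[2]
  w <- ax[[3]] / semi[3]
  U <- array(u, dim = spec$grid_shape)
  V <- array(rep(v, each = spec$grid_shape[1]), dim = spec$grid_shape)
  W <- array(rep(w, each = prod(spec$grid_shape[1:2])), dim = spec$grid_shape)
  rho2 <- U^2 + V^2 + W^2
  cereb <- rho2 <= 1

  # arborized WM core: lobed level set of a smooth angular modulation of the
  # ellipsoidal radius; threshold at the wm_fraction quantile so the WM voxel
  # count is exact by construction
  rho <- sqrt(rho2)
  theta <- atan2(V, U)
  f <- rho - 0.18 * cos(4 * theta) * rho * (1 - rho)
  fc <- f[cereb]
  thr <- stats::quantile(fc, probs = spec$wm_fraction, type = 1)
  labels <- array(0L, dim = spec$grid_shape)
  labels[cereb] <- ifelse(fc <= thr, 2L, 1L)

  # ventricle: rank non-cerebellar voxels by ellipsoidal distance from a
  # centre just caudal to the cerebellum and keep exactly the target count
  vc <- c(0, semi[2] + 1.2 * vsemi[2], 0)
  dv <- ((array(ax[[1]], spec$grid_shape) - vc[1]) / vsemi[1])^2 +
    ((array(rep(ax[[2]], each = spec$grid_shape[1]), spec$grid_shape) -
        vc[2]) / vsemi[2])^2 +
    ((array(rep(ax[[3]], each = prod(spec$grid_shape[1:2])),
            spec$grid_shape) - vc[3]) / vsemi[3])^2
  n_target <- max(1L, round(spec$ventricle_volume_mm3 /
                              prod(spec$voxel_size_mm)))
  candidates <- which(!cereb)
  ord <- candidates[order(dv[candidates])[seq_len(n_target)]]
  labels[ord] <- 3L

  gain <- phantom_bias_field(spec)
  means <- spec$tissue_means
  intensity <- array(means[["background"]], dim = spec$grid_shape)
  intensity[labels == 1L] <- means[["GM"]]
  intensity[labels == 2L] <- means[["WM"]]
  intensity[labels == 3L] <- means[["CSF"]]
  intensity <- intensity * gain
  if (spec$noise_sd > 0) {
    noise <- withr::with_seed(spec$seed,
      array(stats::rnorm(length(intensity), sd = spec$noise_sd),
            dim = spec$grid_shape))
    intensity <- intensity + noise
  }

  structure(list(image = image3d(intensity, spec$voxel_size_mm),
                 labels = label_map(labels, spec$voxel_size_mm),
                 bias_field = gain, spec = spec),
            class = "cereb_phantom")
}

#' Generate a homogeneous calibration phantom
#'
#' Single-tissue volume (GM mean intensity) modulated only by the coil gain
#' field plus additive noise — the calibration acquisition used to estimate
#' the bias model. The true gain field is attached as attribute
#' `"bias_field"` for recovery checks.
#'
#' @param spec a [phantom_spec()]; only grid, tissue mean, noise and bias
#'   fields are used.
#' @return An [image3d()] with the true gain array in `attr(, "bias_field")`.
#' @export
make_homogeneous_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gain <- phantom_bias_field(spec)
  intensity <- spec$tissue_means[["GM"]] * gain
  if (spec$noise_sd > 0) {
    noise <- withr::with_seed(spec$seed,
      array(stats::rnorm(length(intensity), sd = spec$noise_sd),
            dim = spec$grid_shape))
    intensity <- intensity + noise
  }
  img <- image3d(intensity, spec$voxel_size_mm)
  attr(img, "bias_field") <- gain
  img
}

#' Analytic ellipsoid volume
#'
#' @param semi_axes numeric length-3 semi-axes in mm.
#' @return Volume in mm^3, `4/3 * pi * a * b * c`.
#' @export
ellipsoid_volume <- function(semi_axes) 4 / 3 * pi * prod(semi_axes)
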