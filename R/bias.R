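#' Estimate a surface-coil bias field from a homogeneous phantom
#'
#' A surface receive coil imposes a smooth multiplicative gain on the image.
#' Following the calibration-phantom approach, the gain is estimated from the
#' intensity curves of a homogeneous-phantom acquisition made with the same
#' coil and system configuration: the marginal mean intensity profile along
#' each axis is fitted with a low-order polynomial, and the gain field is the
#' (separable) product of the three fitted curves, normalized to mean 1.
#'
#' For a separable gain — the geometry a single surface coil produces — the
#' marginal profiles identify the field exactly up to a scalar, which the
#' mean-1 normalization removes.
#'
#' @param calibration an [image3d()] of a single-tissue phantom; all
#'   intensities must be strictly positive.
#' @param degree polynomial degree for smoothing each intensity curve.
#' @param cv_tol smoothness tolerance: a warning is raised if the corrected
#'   calibration volume still has coefficient of variation above this.
#' @return A `bias_model`: list with `field` (3D gain array, mean 1),
#'   `reference_mean` (1 after normalization) and the per-axis fitted
#'   `profiles`.
#' @export
estimate_bias <- function(calibration, degree = 4L, cv_tol = 0.1) {
  stopifnot(inherits(calibration, "image3d"))
  x <- calibration$data
  if (any(x <= 0))
    stop("calibration volume contains non-positive intensities", call. = FALSE)
  d <- dim(x)
  profiles <- vector("list", 3)
  for (a in 1:3) {
    prof <- apply(x, a, mean)
    t <- seq(0, 1, length.out = d[a])
    deg <- min(degree, d[a] - 1L)
    fit <- stats::lm(prof ~ stats::poly(t, deg))
    sm <- as.numeric(stats::fitted(fit))
    if (any(sm <= 0))
      stop("fitted intensity curve is non-positive along axis ", a,
           "; the calibration data do not look like a smooth gain",
           call. = FALSE)
    profiles[[a]] <- sm / mean(sm)
  }
  field <- array(profiles[[1]], dim = d) *
    array(rep(profiles[[2]], each = d[1]), dim = d) *
    array(rep(profiles[[3]], each = d[1] * d[2]), dim = d)
  field <- field / mean(field)
  model <- structure(list(field = field, reference_mean = 1,
                          profiles = profiles),
                     class = "bias_model")
  cv <- stats::sd(x / field) / mean(x / field)
  if (cv > cv_tol)
    warning(sprintf(paste0("corrected calibration CV = %.3f exceeds ",
                           "tolerance %.3f; the gain may not be separable"),
                    cv, cv_tol), call. = FALSE)
  model
}

#' @export
print.bias_model <- function(x, ...) {
  d <- dim(x$field)
  cat(sprintf("<bias_model> %d x %d x %d gain field, range [%.3f, %.3f]\n",
              d[1], d[2], d[3], min(x$field), max(x$field)))
  invisible(x)
}

#' Apply a bias model to an image
#'
#' Voxelwise division of the image by the gain field; grid and spacing are
#' unchanged. With the mean-1 gain normalization the global intensity scale
#' of the image is preserved.
#'
#' @param image an [image3d()].
#' @param bias a `bias_model` from [estimate_bias()], or a bare 3D gain array.
#' @return The corrected [image3d()].
#' @export
correct_bias <- function(image, bias) {
  stopifnot(inherits(image, "image3d"))
  field <- if (inherits(bias, "bias_model")) bias$field else bias
  if (!identical(dim(image$data), dim(field)))
    stop(sprintf("alignment error: image grid %s does not match gain grid %s",
                 paste(dim(image$data), collapse = "x"),
                 paste(dim(field), collapse = "x")), call. = FALSE)
  if (any(field <= 0))
    stop("gain field must be strictly positive", call. = FALSE)
  image3d(image$data / field, image$voxel_size_mm, image$origin)
}

#' Bounded intensity normalization with outlier exclusion
#'
#' Rescales image intensities to the 0-10,000 grey-level range after
#' excluding the extreme tails: values at or below the `low_tail` quantile
#' map to 0, values at or above the `1 - high_tail` quantile map to 10,000,
#' and the remainder maps linearly. The default tails implement a total 1%
#' outlier exclusion, split symmetrically 0.5% per tail.
#'
#' @param image an [image3d()]; must not be constant.
#' @param low_tail,high_tail tail fractions excluded at each end.
#' @return The normalized [image3d()] with values in `[0, 10000]`.
#' @export
normalize_intensity <- function(image, low_tail = 0.005, high_tail = 0.005) {
  stopifnot(inherits(image, "image3d"))
  stopifnot(low_tail >= 0, high_tail >= 0, low_tail + high_tail < 1)
  x <- image$data
  qs <- stats::quantile(x, probs = c(low_tail, 1 - high_tail), names = FALSE)
  if (qs[2] <= qs[1])
    stop("normalization error: image is constant over the kept range",
         call. = FALSE)
  y <- (x - qs[1]) / (qs[2] - qs[1])
  y <- pmin(pmax(y, 0), 1) * 10000
  image3d(array(y, dim = dim(x)), image$voxel_size_mm, image$origin)
}
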