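shift_array <- function(arr, axis, by) {
  d <- dim(arr)
  idx <- lapply(d, seq_len)
  src <- idx[[axis]] + by
  src <- pmin(pmax(src, 1L), d[axis])  # replicate boundary
  idx[[axis]] <- src
  do.call(`[`, c(list(arr), idx))
}

#' Segment cerebellar white and grey matter by LoG contour detection
#'
#' Implements the contour-based WM/GM split inside a supplied cerebellar
#' mask: the image is smoothed and a Laplacian-of-Gaussian response computed;
#' zero-crossings of the response whose local jump exceeds `edge_threshold`
#' (a fraction of the masked response range) form the candidate contours;
#' the contour-bounded regions (connected components of the mask minus the
#' contour band) are then each assigned WM or GM by their mean intensity
#' relative to an Otsu split of the masked intensity distribution. Contour
#' voxels themselves are classified by their own intensity, so every masked
#' voxel ends up labeled exactly one of GM or WM.
#'
#' The intensity rule replaces an interactive region-selection step and can
#' be overridden per region via `assignments`. On T2-weighted contrast white
#' matter is darker than grey matter, the default polarity.
#'
#' @param image an [image3d()], typically bias-corrected and normalized.
#' @param cerebellum_mask a [label_map()] (non-zero voxels are the mask) or a
#'   logical array on the image grid; the whole-cerebellum outline, supplied
#'   as an input in place of a manual tracing step.
#' @param log_sigma_mm Gaussian scale of the LoG in mm; default twice the
#'   in-plane voxel size. A per-axis sigma below one voxel triggers a warning
#'   and proceeds.
#' @param edge_threshold minimum zero-crossing jump as a fraction of the
#'   masked LoG response range; crossings weaker than this are ignored.
#' @param per_slice if `TRUE`, smooth and differentiate in-plane only,
#'   slice by slice; default is full 3D with per-axis scaling by spacing.
#' @param wm_polarity `"dark"` (T2-like, default) or `"bright"`: which side
#'   of the intensity split is white matter.
#' @param assignments optional data.frame with columns `region` and `tissue`
#'   (`"WM"` or `"GM"`) overriding the automatic rule for those regions.
#' @return A [label_map()] with 1 = GM and 2 = WM inside the mask, 0 outside.
#'   Attributes: `"regions"` (integer array of contour-bounded region ids)
#'   and `"region_table"` (per-region voxel count, mean intensity, tissue).
#' @export
segment_wm_gm <- function(image, cerebellum_mask, log_sigma_mm = NULL,
                          edge_threshold = 0.01, per_slice = FALSE,
                          wm_polarity = c("dark", "bright"),
                          assignments = NULL) {
  stopifnot(inherits(image, "image3d"))
  wm_polarity <- match.arg(wm_polarity)
  mask <- if (inherits(cerebellum_mask, "label_map"))
    cerebellum_mask$labels != 0L else cerebellum_mask
  if (!is.array(mask) || !identical(dim(mask), dim(image$data)))
    stop("mask error: mask grid does not match the image grid", call. = FALSE)
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask)) stop("mask error: cerebellum mask is empty", call. = FALSE)

  h <- image$voxel_size_mm
  if (is.null(log_sigma_mm)) log_sigma_mm <- 2 * min(h[1:2])
  if (log_sigma_mm <= 0) stop("log_sigma_mm must be positive", call. = FALSE)
  axes <- if (per_slice) 1:2 else 1:3
  sub_vox <- log_sigma_mm / h[axes] < 1
  if (any(sub_vox))
    warning("LoG sigma is below one voxel along axis ",
            paste(axes[sub_vox], collapse = ", "),
            "; proceeding with sub-voxel smoothing", call. = FALSE)

  resp <- log_response(image$data, h, log_sigma_mm, per_slice = per_slice)
  rng <- diff(range(resp[mask]))
  edge <- array(FALSE, dim = dim(mask))
  if (rng > 0) {
    jump_min <- edge_threshold * rng
    s <- sign(resp)
    for (a in axes) for (b in c(-1L, 1L)) {
      ns <- shift_array(s, a, b)
      nr <- shift_array(resp, a, b)
      edge <- edge | (s != ns & abs(resp - nr) >= jump_min)
    }
    edge <- edge & mask
  }

  labels <- array(0L, dim = dim(mask))
  intens <- image$data
  regions <- array(0L, dim = dim(mask))
  region_table <- data.frame(region = integer(0), n_voxels = integer(0),
                             mean_intensity = numeric(0),
                             tissue = character(0))
  if (!any(edge)) {
    # no contour above threshold: no internal contrast, whole mask is GM
    labels[mask] <- 1L
  } else {
    thr <- otsu_threshold(intens[mask])
    is_wm_side <- function(v) if (wm_polarity == "dark") v < thr else v > thr
    open <- mask & !edge
    if (per_slice) {
      # contours only separate in-plane, so regions must not leak across
      # slices: label each slice independently
      regions <- array(0L, dim = dim(mask))
      offset <- 0L
      for (k in seq_len(dim(mask)[3])) {
        sl <- connected_components_3d(array(open[, , k],
                                            dim = c(dim(mask)[1:2], 1L)))
        nk <- max(sl)
        sl[sl > 0L] <- sl[sl > 0L] + offset
        regions[, , k] <- sl[, , 1]
        offset <- offset + nk
      }
    } else {
      regions <- connected_components_3d(open)
    }
    ids <- setdiff(sort(unique(as.vector(regions[mask]))), 0L)
    means <- vapply(ids, function(i) mean(intens[regions == i]), numeric(1))
    tissue <- ifelse(is_wm_side(means), "WM", "GM")
    if (!is.null(assignments)) {
      stopifnot(all(c("region", "tissue") %in% names(assignments)),
                all(assignments$tissue %in% c("WM", "GM")))
      m <- match(assignments$region, ids)
      if (anyNA(m))
        stop("assignments refer to unknown region id(s): ",
             paste(assignments$region[is.na(m)], collapse = ", "),
             call. = FALSE)
      tissue[m] <- assignments$tissue
    }
    region_table <- data.frame(region = ids,
                               n_voxels = as.integer(tabulate(
                                 regions[regions > 0])[ids]),
                               mean_intensity = means, tissue = tissue)
    code <- ifelse(tissue == "WM", 2L, 1L)
    lut <- integer(max(ids))
    lut[ids] <- code
    inside_region <- mask & regions > 0L
    labels[inside_region] <- lut[regions[inside_region]]
    # contour voxels (and any stray masked voxels): per-voxel intensity rule
    rest <- mask & labels == 0L
    labels[rest] <- ifelse(is_wm_side(intens[rest]), 2L, 1L)
  }

  out <- label_map(labels, image$voxel_size_mm,
                   legend = c(`0` = "background", `1` = "GM", `2` = "WM"),
                   origin = image$origin)
  attr(out, "regions") <- regions
  attr(out, "region_table") <- region_table
  out
}

#' Dice overlap coefficient
#'
#' `2|A & B| / (|A| + |B|)` between two logical masks on the same grid.
#' Returns `NA` when both masks are empty.
#'
#' @param a,b logical arrays of identical dimension.
#' @return The Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NA_real_)
  2 * sum(a & b) / denom
}
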