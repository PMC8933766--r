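#' Voxel-count volumetry of a label map
#'
#' Tissue volumes are exact integer voxel counts times the voxel volume
#' (product of the per-axis spacings). When both GM and WM are present a
#' `cerebellum` row reporting their sum is appended.
#'
#' @param labels a [label_map()], or an integer array if `voxel_size_mm` and
#'   `legend` are supplied.
#' @param voxel_size_mm per-axis spacing, taken from `labels` when it is a
#'   `label_map`.
#' @param legend label-code legend, taken from `labels` when possible. An
#'   array containing codes outside the legend is a legend error.
#' @return A data.frame of class `tissue_volumes` with columns `tissue`,
#'   `voxel_count`, `volume_mm3` and attribute `voxel_volume_mm3`.
#' @examples
#' lm <- label_map(array(c(rep(2L, 10), rep(0L, 22)), c(4, 4, 2)),
#'                 voxel_size_mm = c(0.0781, 0.0781, 0.5))
#' measure_volumes(lm)
#' @export
measure_volumes <- function(labels, voxel_size_mm = NULL, legend = NULL) {
  if (inherits(labels, "label_map")) {
    if (is.null(voxel_size_mm)) voxel_size_mm <- labels$voxel_size_mm
    if (is.null(legend)) legend <- labels$legend
    arr <- labels$labels
  } else {
    if (is.null(voxel_size_mm) || is.null(legend))
      stop("voxel_size_mm and legend are required for a bare label array",
           call. = FALSE)
    arr <- labels
  }
  present <- sort(unique(as.vector(arr)))
  unknown <- setdiff(as.character(present), names(legend))
  if (length(unknown) > 0)
    stop("legend error: unknown label code(s) ",
         paste(unknown, collapse = ", "), call. = FALSE)
  vv <- prod(voxel_size_mm)
  codes <- as.integer(names(legend))
  counts <- vapply(codes, function(k) sum(arr == k), numeric(1))
  out <- data.frame(tissue = unname(legend),
                    voxel_count = as.integer(counts),
                    volume_mm3 = counts * vv)
  if (all(c("GM", "WM") %in% out$tissue)) {
    gmwm <- out[out$tissue %in% c("GM", "WM"), ]
    out <- rbind(out, data.frame(tissue = "cerebellum",
                                 voxel_count = sum(gmwm$voxel_count),
                                 volume_mm3 = sum(gmwm$volume_mm3)))
  }
  attr(out, "voxel_volume_mm3") <- vv
  class(out) <- c("tissue_volumes", "data.frame")
  out
}

#' Fold change between two group means
#'
#' Returns the max/min ratio of two strictly positive group means together
#' with the direction of the change in group b relative to group a, the form
#' in which volumetric and metabolite group differences are reported (e.g. a
#' 2.39-fold decrease of cerebellar volume).
#'
#' @param mean_a,mean_b strictly positive group means (reference group a).
#' @return A list with `ratio` (>= 1) and `direction` (`"increase"`,
#'   `"decrease"` or `"none"` for group b versus group a).
#' @examples
#' fold_change(49.62, 20.73)  # 2.39-fold decrease
#' @export
fold_change <- function(mean_a, mean_b) {
  if (!is.finite(mean_a) || !is.finite(mean_b) || mean_a <= 0 || mean_b <= 0)
    stop("fold_change requires strictly positive finite means", call. = FALSE)
  list(ratio = max(mean_a, mean_b) / min(mean_a, mean_b),
       direction = if (mean_b > mean_a) "increase"
       else if (mean_b < mean_a) "decrease" else "none")
}
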