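#' 3D scalar image with voxel geometry
#'
#' Lightweight container for a 3D acquisition (a T2-weighted stack or a
#' calibration phantom): a numeric array plus per-axis voxel spacing in mm and
#' a world-space origin. World coordinates follow
#' `world = (index - 1) * spacing + origin` (voxel indices are 1-based in R;
#' the first voxel centre sits at the origin).
#'
#' @param data numeric 3D array of intensities; all values must be finite.
#' @param voxel_size_mm numeric length-3, strictly positive spacing in mm.
#' @param origin numeric length-3 world offset in mm.
#' @return An object of class `image3d`.
#' @examples
#' img <- image3d(array(1, c(4, 4, 2)), voxel_size_mm = c(0.0781, 0.0781, 0.5))
#' voxel_volume(img)
#' @export
image3d <- function(data, voxel_size_mm = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop("image intensities must all be finite", call. = FALSE)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be 3 strictly positive values", call. = FALSE)
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("`origin` must have length 3", call. = FALSE)
  structure(list(data = data, voxel_size_mm = voxel_size_mm, origin = origin),
            class = "image3d")
}

#' @export
print.image3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image3d> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(signif(x$voxel_size_mm, 4), collapse = " x ")))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @rdname image3d
#' @param img an `image3d` or `label_map`.
#' @return `voxel_volume()`: the volume of one voxel in mm^3.
#' @export
voxel_volume <- function(img) prod(img$voxel_size_mm)

#' Per-voxel tissue label map
#'
#' Integer labels aligned with an [image3d()] grid. The default legend follows
#' the package's label coding: 0 = background, 1 = GM, 2 = WM,
#' 3 = CSF/ventricle.
#'
#' @param labels integer 3D array of label codes.
#' @param voxel_size_mm per-axis spacing in mm.
#' @param legend named character vector mapping label code (as name) to tissue
#'   name; must cover every code present in `labels`.
#' @param origin world offset in mm.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, voxel_size_mm = c(1, 1, 1),
                      legend = c(`0` = "background", `1` = "GM", `2` = "WM",
                                 `3` = "CSF"),
                      origin = c(0, 0, 0)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array", call. = FALSE)
  storage.mode(labels) <- "integer"
  present <- sort(unique(as.vector(labels)))
  missing_codes <- setdiff(as.character(present), names(legend))
  if (length(missing_codes) > 0)
    stop("legend does not cover label code(s): ",
         paste(missing_codes, collapse = ", "), call. = FALSE)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be 3 strictly positive values", call. = FALSE)
  structure(list(labels = labels, voxel_size_mm = voxel_size_mm,
                 legend = legend, origin = as.numeric(origin)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_map> %d x %d x %d voxels\n", d[1], d[2], d[3]))
  tab <- table(factor(as.vector(x$labels), levels = names(x$legend)))
  for (code in names(tab))
    cat(sprintf("  %s (%s): %d voxels\n", x$legend[[code]], code, tab[[code]]))
  invisible(x)
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  da <- dim(if (inherits(a, "label_map")) a$labels else a$data)
  db <- dim(if (inherits(b, "label_map")) b$labels else b$data)
  if (!identical(da, db))
    stop(sprintf("grid mismatch: %s have dimensions %s vs %s", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")),
         call. = FALSE)
  invisible(TRUE)
}

#' Read and write volumes as NIfTI-1
#'
#' Volumes travel as `.nii` / `.nii.gz` with voxel spacing in the header.
#' Label maps are stored as integer-valued NIfTI volumes using the package's
#' label coding (0 background, 1 GM, 2 WM, 3 CSF/ventricle).
#'
#' @param img an [image3d()] (or [label_map()] for `write_label_nifti()`).
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `read_image_nifti()` returns an `image3d`; `read_label_nifti()` a
#'   `label_map`; the writers return `path` invisibly.
#' @export
write_image_nifti <- function(img, path) {
  stopifnot(inherits(img, "image3d"))
  nii <- RNifti::asNifti(img$data)
  RNifti::pixdim(nii) <- img$voxel_size_mm
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname write_image_nifti
#' @export
read_image_nifti <- function(path) {
  nii <- RNifti::readNifti(path)
  image3d(array(as.numeric(nii), dim = dim(nii)[1:3]),
          voxel_size_mm = RNifti::pixdim(nii)[1:3])
}

#' @rdname write_image_nifti
#' @export
write_label_nifti <- function(img, path) {
  stopifnot(inherits(img, "label_map"))
  nii <- RNifti::asNifti(img$labels)
  RNifti::pixdim(nii) <- img$voxel_size_mm
  RNifti::writeNifti(nii, path, datatype = "int16")
  invisible(path)
}

#' @rdname write_image_nifti
#' @export
read_label_nifti <- function(path) {
  nii <- RNifti::readNifti(path)
  label_map(array(as.integer(nii), dim = dim(nii)[1:3]),
            voxel_size_mm = RNifti::pixdim(nii)[1:3])
}
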