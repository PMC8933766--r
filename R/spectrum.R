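#' Frequency-domain MRS spectrum
#'
#' A single-voxel proton spectrum on a strictly monotone chemical-shift axis
#' (conventionally descending ppm), with an optional unsuppressed-water area
#' used for water referencing.
#'
#' @param ppm numeric chemical-shift axis, strictly monotone.
#' @param intensity numeric, same length as `ppm`.
#' @param water_reference optional scalar area of the unsuppressed water
#'   signal.
#' @return An object of class `mrs_spectrum`.
#' @export
mrs_spectrum <- function(ppm, intensity, water_reference = NULL) {
  ppm <- as.numeric(ppm)
  intensity <- as.numeric(intensity)
  if (length(ppm) != length(intensity))
    stop("ppm axis and intensity must have the same length", call. = FALSE)
  d <- diff(ppm)
  if (length(d) == 0 || !(all(d > 0) || all(d < 0)))
    stop("ppm axis must be strictly monotone", call. = FALSE)
  if (!is.null(water_reference)) {
    water_reference <- as.numeric(water_reference)
    stopifnot(length(water_reference) == 1L, water_reference > 0)
  }
  structure(list(ppm = ppm, intensity = intensity,
                 water_reference = water_reference),
            class = "mrs_spectrum")
}

#' @export
print.mrs_spectrum <- function(x, ...) {
  cat(sprintf("<mrs_spectrum> %d points, ppm [%.2f, %.2f]%s\n",
              length(x$ppm), min(x$ppm), max(x$ppm),
              if (is.null(x$water_reference)) ""
              else sprintf(", water area %.3g", x$water_reference)))
  invisible(x)
}

#' Metabolite basis set
#'
#' Per-metabolite model signatures on one shared ppm axis, the linear-
#' combination dictionary the fitter projects a spectrum onto.
#'
#' @param ppm shared chemical-shift axis, strictly monotone.
#' @param signatures numeric matrix, one column per metabolite, with unique
#'   column names.
#' @return An object of class `mrs_basis`.
#' @export
mrs_basis <- function(ppm, signatures) {
  ppm <- as.numeric(ppm)
  signatures <- as.matrix(signatures)
  if (nrow(signatures) != length(ppm))
    stop("signatures must have one row per ppm point", call. = FALSE)
  if (is.null(colnames(signatures)) || anyDuplicated(colnames(signatures)))
    stop("signatures need unique metabolite column names", call. = FALSE)
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0)))
    stop("ppm axis must be strictly monotone", call. = FALSE)
  structure(list(ppm = ppm, signatures = signatures), class = "mrs_basis")
}

#' @export
print.mrs_basis <- function(x, ...) {
  cat(sprintf("<mrs_basis> %d metabolites on %d ppm points: %s\n",
              ncol(x$signatures), length(x$ppm),
              paste(colnames(x$signatures), collapse = ", ")))
  invisible(x)
}

#' Default chemical-shift line table and ppm axis
#'
#' The shipped basis is synthesized as sums of Lorentzian lines at
#' approximate literature chemical shifts for the 16 compounds of the mouse
#' cerebellar panel (Cr, PCr, Glu, Gln, Ins, Tau, Cho, PCh, GPC, GSH, NAA,
#' NAAG, GABA, Lac plus macromolecule and lipid resonances). Line positions
#' and relative amplitudes are coarse: the basis is a synthetic stand-in
#' with the same directory contract as a measured basis set, not a
#' quantum-mechanical simulation. Users can substitute measured signatures
#' via [read_basis_dir()].
#'
#' @return `default_basis_lines()`: data.frame with columns `metabolite`,
#'   `ppm`, `amplitude`, `hwhm_ppm`; `default_ppm_axis()`: descending ppm
#'   grid from 5.0 to 0.2.
#' @export
default_basis_lines <- function() {
  path <- system.file("extdata", "basis_lines.tsv", package = "cerebmrs",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname default_basis_lines
#' @param n number of spectral points.
#' @export
default_ppm_axis <- function(n = 1024L) seq(6.0, 0.2, length.out = n)

#' Synthesize a basis set from a line table
#'
#' Each metabolite signature is a sum of Lorentzian lines
#' `amplitude * hwhm^2 / ((ppm - ppm0)^2 + hwhm^2)`.
#'
#' @param lines line table as from [default_basis_lines()].
#' @param ppm target axis.
#' @return An [mrs_basis()].
#' @export
synth_basis <- function(lines = default_basis_lines(),
                        ppm = default_ppm_axis()) {
  stopifnot(all(c("metabolite", "ppm", "amplitude", "hwhm_ppm") %in%
                  names(lines)))
  mets <- unique(lines$metabolite)
  sig <- vapply(mets, function(m) {
    sub <- lines[lines$metabolite == m, ]
    rowSums(vapply(seq_len(nrow(sub)), function(i) {
      g <- sub$hwhm_ppm[i]
      sub$amplitude[i] * g^2 / ((ppm - sub$ppm[i])^2 + g^2)
    }, numeric(length(ppm))))
  }, numeric(length(ppm)))
  mrs_basis(ppm, sig)
}

# polynomial baseline design on the ppm axis, columns t^0 .. t^order with
# t scaled to [-1, 1] for conditioning
baseline_design <- function(ppm, order) {
  if (order < 0) return(matrix(numeric(0), nrow = length(ppm), ncol = 0))
  t <- 2 * (ppm - min(ppm)) / (max(ppm) - min(ppm)) - 1
  outer(t, 0:order, `^`)
}

#' Generate a synthetic spectrum from known concentrations
#'
#' Builds `sum(conc_m * basis_m) + smooth polynomial baseline + Gaussian
#' noise` and records the true concentrations as attribute
#' `"true_concentrations"` for recovery testing.
#'
#' @param basis an [mrs_basis()].
#' @param concentrations named non-negative amounts; names must exist in the
#'   basis.
#' @param baseline_coeffs coefficients of the polynomial baseline (constant
#'   first); `NULL` or `numeric(0)` for none.
#' @param noise_sd additive Gaussian noise SD; the default 0.2 produces a
#'   reliability profile like typical in vivo mouse spectra (sub-percent
#'   CRLB for strong singlets, high-teens for the weak choline compounds).
#' @param seed RNG seed for the noise draw.
#' @param water_reference optional unsuppressed-water area stored on the
#'   spectrum.
#' @return An [mrs_spectrum()].
#' @export
make_spectrum <- function(basis, concentrations, baseline_coeffs = NULL,
                          noise_sd = 0.2, seed = 1L, water_reference = NULL) {
  stopifnot(inherits(basis, "mrs_basis"))
  if (is.null(names(concentrations)) || anyNA(names(concentrations)))
    stop("concentrations must be a named vector", call. = FALSE)
  unknown <- setdiff(names(concentrations), colnames(basis$signatures))
  if (length(unknown) > 0)
    stop("axis error: concentration name(s) not in the basis: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (any(concentrations < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  y <- as.numeric(basis$signatures[, names(concentrations), drop = FALSE] %*%
                    concentrations)
  if (!is.null(baseline_coeffs) && length(baseline_coeffs) > 0) {
    P <- baseline_design(basis$ppm, length(baseline_coeffs) - 1L)
    y <- y + as.numeric(P %*% baseline_coeffs)
  }
  if (noise_sd > 0)
    y <- y + withr::with_seed(seed, stats::rnorm(length(y), sd = noise_sd))
  sp <- mrs_spectrum(basis$ppm, y, water_reference = water_reference)
  attr(sp, "true_concentrations") <- concentrations
  sp
}

#' Read and write spectra and basis directories
#'
#' Spectra travel as two-column whitespace-delimited text (ppm, intensity).
#' A basis directory holds one such file per metabolite plus a
#' `manifest.tsv` with columns `metabolite` and `file`.
#'
#' @param spectrum an [mrs_spectrum()].
#' @param path file path (or directory for the basis functions).
#' @return Readers return the parsed object; writers return the path
#'   invisibly.
#' @export
write_spectrum_txt <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "mrs_spectrum"))
  utils::write.table(data.frame(ppm = spectrum$ppm,
                                intensity = spectrum$intensity),
                     path, sep = " ", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_txt
#' @param water_reference optional water area to attach on read.
#' @export
read_spectrum_txt <- function(path, water_reference = NULL) {
  tab <- utils::read.table(path, header = FALSE)
  if (ncol(tab) < 2) stop("expected two columns: ppm, intensity",
                          call. = FALSE)
  mrs_spectrum(tab[[1]], tab[[2]], water_reference = water_reference)
}

#' @rdname write_spectrum_txt
#' @param basis an [mrs_basis()].
#' @param dir directory to create/read.
#' @export
write_basis_dir <- function(basis, dir) {
  stopifnot(inherits(basis, "mrs_basis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mets <- colnames(basis$signatures)
  files <- paste0(gsub("[^A-Za-z0-9_]", "_", mets), ".txt")
  for (i in seq_along(mets))
    utils::write.table(data.frame(basis$ppm, basis$signatures[, i]),
                       file.path(dir, files[i]), sep = " ",
                       row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(metabolite = mets, file = files),
                     file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_spectrum_txt
#' @export
read_basis_dir <- function(dir) {
  man <- utils::read.delim(file.path(dir, "manifest.tsv"),
                           stringsAsFactors = FALSE)
  stopifnot(all(c("metabolite", "file") %in% names(man)))
  ppm <- NULL
  cols <- lapply(seq_len(nrow(man)), function(i) {
    tab <- utils::read.table(file.path(dir, man$file[i]), header = FALSE)
    if (is.null(ppm)) ppm <<- tab[[1]]
    if (length(tab[[1]]) != length(ppm) ||
        max(abs(tab[[1]] - ppm)) > 1e-9)
      stop("axis error: basis file ", man$file[i],
           " is not on the shared ppm axis", call. = FALSE)
    tab[[2]]
  })
  sig <- do.call(cbind, cols)
  colnames(sig) <- man$metabolite
  mrs_basis(ppm, sig)
}
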