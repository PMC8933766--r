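#' Linear-combination fit of a spectrum to a basis set
#'
#' Solves the non-negative least-squares problem
#' `intensity ~ sum(c_m * basis_m) + polynomial baseline` (baseline
#' coefficients unconstrained; metabolite amounts constrained to be
#' non-negative by an active-set solver, never by silently clipping a
#' converged negative solution — amounts pinned at zero carry an `at_bound`
#' flag). Reliability per metabolite is reported as a Cramér–Rao lower bound
#' percentage computed from the Fisher information of the linear model, with
#' the noise variance estimated from the fit residuals in a signal-free ppm
#' window above all basis lines.
#'
#' @param spectrum an [mrs_spectrum()].
#' @param basis an [mrs_basis()] on the same ppm axis.
#' @param baseline_order polynomial baseline degree; `-1` disables the
#'   baseline.
#' @param noise_window ppm interval assumed free of metabolite signal, used
#'   for noise-variance estimation; it must contain at least 8 points, else
#'   the full-spectrum residual SD is used with a warning.
#' @param collinearity_limit absolute correlation between two basis columns
#'   above which the design is declared rank-deficient (a conditioning error
#'   naming the offending pair).
#' @return An object of class `mrs_fit`: list with `table` (data.frame of
#'   `metabolite`, `concentration`, `crlb_percent`, `included`, `at_bound`),
#'   `baseline_coeffs`, `residual_norm`, `noise_sd`, `reference` metadata
#'   and the spectrum's `water_reference`.
#' @export
fit_spectrum <- function(spectrum, basis, baseline_order = 2L,
                         noise_window = c(4.5, 6.0),
                         collinearity_limit = 0.9995) {
  stopifnot(inherits(spectrum, "mrs_spectrum"), inherits(basis, "mrs_basis"))
  if (ncol(basis$signatures) == 0) stop("basis is empty", call. = FALSE)
  if (length(spectrum$ppm) != length(basis$ppm) ||
      max(abs(spectrum$ppm - basis$ppm)) > 1e-9)
    stop("axis error: spectrum and basis ppm axes differ", call. = FALSE)

  S <- basis$signatures
  m <- ncol(S)
  mets <- colnames(S)
  cc <- stats::cor(S)
  cc[upper.tri(cc, diag = TRUE)] <- 0
  worst <- which(abs(cc) > collinearity_limit, arr.ind = TRUE)
  if (nrow(worst) > 0)
    stop(sprintf(paste0("conditioning error: basis signatures for %s and %s ",
                        "are collinear (|r| = %.5f)"),
                 mets[worst[1, 2]], mets[worst[1, 1]],
                 abs(cc[worst[1, , drop = FALSE]])), call. = FALSE)

  P <- baseline_design(basis$ppm, baseline_order)
  nb <- ncol(P)
  # unconstrained baseline under an NNLS solver: split each baseline column
  # into a +/- pair
  A <- cbind(S, P, -P)
  y <- spectrum$intensity
  sol <- pracma::lsqnonneg(A, y)
  coef <- sol$x
  conc <- coef[seq_len(m)]
  base_coef <- if (nb > 0) coef[m + seq_len(nb)] - coef[m + nb + seq_len(nb)]
  else numeric(0)
  fitted <- as.numeric(A %*% coef)
  resid <- y - fitted

  # residuals understate the noise by the model's degrees of freedom; the
  # usual n/(n - p) correction is applied to the window estimate
  n_pts <- length(y)
  p_eff <- m + nb
  df_scale <- n_pts / max(n_pts - p_eff, 1)
  in_window <- basis$ppm >= min(noise_window) & basis$ppm <= max(noise_window)
  if (sum(in_window) >= 8) {
    noise_sd <- stats::sd(resid[in_window]) * sqrt(df_scale)
  } else {
    warning("noise window contains fewer than 8 points; ",
            "using full-spectrum residual SD", call. = FALSE)
    noise_sd <- stats::sd(resid) * sqrt(df_scale)
  }

  # Fisher information of the unconstrained linear model (basis + one signed
  # copy of the baseline); CRLB is undefined for amounts pinned at zero
  A0 <- cbind(S, P)
  XtX <- crossprod(A0)
  cov_un <- noise_sd^2 * chol2inv(chol(XtX))
  crlb_abs <- sqrt(pmax(diag(cov_un)[seq_len(m)], 0))
  crlb_pct <- ifelse(conc > 0, 100 * crlb_abs / conc, NA_real_)

  structure(list(
    table = data.frame(metabolite = mets, concentration = conc,
                       crlb_percent = crlb_pct,
                       included = !is.na(crlb_pct),
                       at_bound = conc == 0,
                       row.names = NULL),
    baseline_coeffs = base_coef,
    residual_norm = sqrt(sum(resid^2)),
    noise_sd = noise_sd,
    crlb_absolute = crlb_abs,
    reference = list(mode = "raw", scale = 1),
    water_reference = spectrum$water_reference),
    class = "mrs_fit")
}

#' @export
print.mrs_fit <- function(x, ...) {
  cat(sprintf("<mrs_fit> %d metabolites, reference: %s, residual norm %.4g\n",
              nrow(x$table), x$reference$mode, x$residual_norm))
  print(x$table, digits = 4)
  invisible(x)
}

#' Filter fitted metabolites by CRLB reliability
#'
#' Marks as excluded every metabolite whose Cramér–Rao lower bound exceeds
#' the threshold (the reliability rule: CRLB strictly higher than 24% is
#' unreliable, exactly 24% is kept). Concentrations are preserved —
#' exclusion is downstream masking, never zeroing. Metabolites with an
#' undefined CRLB (amount pinned at zero) are excluded too.
#'
#' @param fit an `mrs_fit`.
#' @param threshold_percent CRLB threshold in percent; default 24.
#' @return The fit with its `included` flags updated.
#' @export
apply_crlb_filter <- function(fit, threshold_percent = 24) {
  stopifnot(inherits(fit, "mrs_fit"), threshold_percent > 0)
  fit$table$included <- !is.na(fit$table$crlb_percent) &
    fit$table$crlb_percent <= threshold_percent
  fit$crlb_threshold <- threshold_percent
  fit
}

#' Re-reference fitted concentrations
#'
#' Water mode scales every concentration by
#' `water_concentration / water_reference` (results relative to the tissue
#' water signal); creatine mode divides by total creatine (Cr + PCr); raw
#' mode restores the fitter's native scale. Referencing is recorded in the
#' fit metadata and is exactly invertible, so round-tripping restores the
#' original values.
#'
#' @param fit an `mrs_fit`.
#' @param mode `"water"`, `"creatine"` or `"raw"`.
#' @param water_concentration scale constant for water mode (the assumed
#'   tissue water signal amplitude the areas are quoted against).
#' @return The re-referenced `mrs_fit`.
#' @export
reference_concentrations <- function(fit, mode = c("water", "creatine", "raw"),
                                     water_concentration = 1) {
  stopifnot(inherits(fit, "mrs_fit"))
  mode <- match.arg(mode)
  raw <- fit$table$concentration / fit$reference$scale
  scale <- switch(mode,
    raw = 1,
    water = {
      if (is.null(fit$water_reference))
        stop("reference error: no water_reference present on this fit",
             call. = FALSE)
      water_concentration / fit$water_reference
    },
    creatine = {
      tab <- fit$table
      cr <- tab[tab$metabolite %in% c("Cr", "PCr"), ]
      if (nrow(cr) < 2 || !all(cr$included))
        stop("reference error: creatine mode needs Cr and PCr fitted and ",
             "included", call. = FALSE)
      raw_tcr <- sum(cr$concentration) / fit$reference$scale
      if (raw_tcr <= 0)
        stop("reference error: total creatine is not positive", call. = FALSE)
      1 / raw_tcr
    })
  fit$table$concentration <- raw * scale
  fit$reference <- list(mode = mode, scale = scale)
  fit
}

#' Diagnostic metabolite ratios
#'
#' Computes the clinical marker ratios NAA/Ins and NAA/tCho, where total
#' choline is PCh + GPC. A ratio whose numerator or any denominator
#' component is CRLB-excluded propagates a missing value with the reason,
#' never a zero.
#'
#' @param fit an `mrs_fit` (after [apply_crlb_filter()]).
#' @return data.frame with columns `ratio`, `value`, `reason` (`NA` reason
#'   when the ratio is defined).
#' @export
compute_ratios <- function(fit) {
  stopifnot(inherits(fit, "mrs_fit"))
  tab <- fit$table
  get <- function(met) {
    i <- match(met, tab$metabolite)
    if (is.na(i)) return(list(value = NA_real_, ok = FALSE,
                              why = paste0(met, " absent from panel")))
    if (!tab$included[i]) return(list(value = NA_real_, ok = FALSE,
                                      why = paste0(met, " excluded by CRLB")))
    list(value = tab$concentration[i], ok = TRUE, why = NA_character_)
  }
  one_ratio <- function(name, num, den_parts) {
    n <- get(num)
    dens <- lapply(den_parts, get)
    bad <- c(if (!n$ok) n$why,
             unlist(lapply(dens, function(d) if (!d$ok) d$why)))
    if (length(bad) > 0)
      return(data.frame(ratio = name, value = NA_real_,
                        reason = paste(bad, collapse = "; ")))
    den <- sum(vapply(dens, `[[`, numeric(1), "value"))
    if (den <= 0)
      stop("domain error: denominator of ", name, " is not positive",
           call. = FALSE)
    data.frame(ratio = name, value = n$value / den, reason = NA_character_)
  }
  rbind(one_ratio("NAA/Ins", "NAA", list("Ins")),
        one_ratio("NAA/tCho", "NAA", list("PCh", "GPC")))
}

#' Write a fit report as TSV
#'
#' @param fit an `mrs_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_tsv <- function(fit, path) {
  stopifnot(inherits(fit, "mrs_fit"))
  utils::write.table(fit$table[, c("metabolite", "concentration",
                                   "crlb_percent", "included")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
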