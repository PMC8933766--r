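#' The mouse cerebellar metabolite panel
#'
#' The 17 quantities carried per mouse: 16 fitted compounds (creatine,
#' phosphocreatine, glutamate, glutamine, myo-inositol, taurine, choline,
#' phosphocholine, glycerophosphocholine, glutathione, NAA, NAAG, GABA,
#' lactate, macromolecules, lipids) plus the composite NAA_NAAG
#' (NAA + NAAG), which is generated as the exact sum of its parts.
#'
#' @return Character vector of panel column names.
#' @export
metabolite_panel <- function() {
  c("Cr", "PCr", "Glu", "Gln", "Ins", "Tau", "Cho", "PCh", "GPC", "GSH",
    "NAA", "NAAG", "NAA_NAAG", "GABA", "Lac", "MM", "Lip")
}

mouse_base_means <- function() {
  c(cerebellum_volume_mm3 = 49.62, wm_volume_mm3 = 25.35,
    ventricle_volume_mm3 = 1.491,
    NAA = 1.02, NAAG = 0.22, Glu = 5.80, Tau = 5.73, Ins = 4.95,
    Cr = 3.9, PCr = 4.3, Gln = 2.5, Cho = 0.25, PCh = 0.35, GPC = 0.45,
    GSH = 1.1, GABA = 1.8, Lac = 1.0, MM = 6.0, Lip = 2.0)
}

# default disease shifts (MJD minus control); volumes and the five key
# neurochemicals follow the reported group means, macromolecules/lipids a
# modest increase, everything else null
mouse_group_effects <- function() {
  c(cerebellum_volume_mm3 = 20.73 - 49.62, wm_volume_mm3 = 19.03 - 25.35,
    ventricle_volume_mm3 = 2.772 - 1.491,
    NAA = 0.71 - 1.02, NAAG = 0.20 - 0.22, Glu = 4.29 - 5.80,
    Tau = 4.35 - 5.73, Ins = 6.97 - 4.95, MM = 0.8, Lip = 0.3)
}

mouse_sds <- function() {
  list(
    control = c(cerebellum_volume_mm3 = 3.19, wm_volume_mm3 = 1.41,
                ventricle_volume_mm3 = 0.209,
                NAA = 0.25, NAAG = 0.08, Glu = 1.27, Tau = 1.66, Ins = 1.25,
                Cr = 0.5, PCr = 0.5, Gln = 0.5, Cho = 0.06, PCh = 0.08,
                GPC = 0.1, GSH = 0.2, GABA = 0.35, Lac = 0.3, MM = 1.0,
                Lip = 0.5),
    MJD = c(cerebellum_volume_mm3 = 1.39, wm_volume_mm3 = 1.69,
            ventricle_volume_mm3 = 0.393,
            NAA = 0.22, NAAG = 0.08, Glu = 1.25, Tau = 1.22, Ins = 2.32,
            Cr = 0.5, PCr = 0.5, Gln = 0.5, Cho = 0.06, PCh = 0.08,
            GPC = 0.1, GSH = 0.2, GABA = 0.35, Lac = 0.3, MM = 1.1,
            Lip = 0.6))
}

# study layout: (group, age, males, females) cells of the mouse cohort
mouse_default_cells <- function() {
  data.frame(group = rep(c("control", "MJD"), 3),
             age_months = rep(c(2, 4, 16), each = 2),
             n_male = c(6, 4, 0, 0, 4, 1),
             n_female = c(8, 10, 7, 9, 3, 5))
}

#' Specification of a synthetic cohort table
#'
#' `mouse_cohort_spec()` describes a two-group (control vs MJD) mouse cohort
#' with ages 2/4/16 months, cerebellar and ventricle volumes, the
#' 17-quantity metabolite panel and rotarod latencies linearly dependent on
#' NAA. `human_cohort_spec()` describes a control/MJD patient cohort with
#' age and sex covariates, cerebellar GM/WM/CSF/total volumes whose age
#' slopes differ by group (and by sex for CSF), and for patients a
#' correlated clinical block (age of onset, disease duration, CAG repeats,
#' SARA score) with pairwise correlations above 0.7 between duration/CAG
#' and onset. Defaults reproduce the studied cohorts' sizes, group means and
#' dispersions.
#'
#' @param n_per_group `NULL` for the study layout, or an integer: subjects
#'   per (group, age) cell for mice, per group for humans. Must be >= 2.
#' @param group_effects named mean shifts (MJD minus control); unnamed
#'   variables shift by 0. Use `group_effects = 0` for a null cohort.
#' @param covariate_effects named list of slopes; see Details.
#' @param noise_sds named residual SDs overriding the defaults.
#' @param correlation_block 4x4 correlation matrix for (onset, duration,
#'   CAG, SARA) in the human spec.
#' @param seed integer RNG seed.
#' @details Mouse `covariate_effects`: `rotarod_slope_NAA` (s per mM, both
#'   rotarod modes scale from it), `rotarod_noise_sd`. Human
#'   `covariate_effects`: `gm_age` and `gm_age_mjd_extra` (GM-vs-age slope
#'   in controls and its MJD increment), `wm_age`, `wm_age_mjd_extra`,
#'   `csf_age_base`, `csf_age_male`, `csf_age_mjd`, `csf_age_mjd_male`,
#'   `gm_onset`, `gm_sara`, `csf_sara` (clinical slopes on MJD rows only).
#' @return A list of class `cohort_spec` with a `species` field.
#' @export
mouse_cohort_spec <- function(n_per_group = NULL, group_effects = NULL,
                              covariate_effects = NULL, noise_sds = NULL,
                              seed = 1L) {
  eff <- mouse_group_effects()
  if (!is.null(group_effects)) {
    if (identical(group_effects, 0)) eff[] <- 0
    else {
      stopifnot(!is.null(names(group_effects)))
      eff[names(group_effects)] <- group_effects
      eff <- c(eff, group_effects[setdiff(names(group_effects), names(eff))])
    }
  }
  cov_eff <- list(rotarod_slope_NAA = 120, rotarod_noise_sd = 36)
  if (!is.null(covariate_effects))
    cov_eff[names(covariate_effects)] <- covariate_effects
  sds <- mouse_sds()
  if (!is.null(noise_sds)) {
    stopifnot(!is.null(names(noise_sds)))
    sds$control[names(noise_sds)] <- noise_sds
    sds$MJD[names(noise_sds)] <- noise_sds
  }
  if (!is.null(n_per_group) && any(n_per_group < 2))
    stop("n_per_group must be at least 2 per cell", call. = FALSE)
  structure(list(species = "mouse", n_per_group = n_per_group,
                 base_means = mouse_base_means(), group_effects = eff,
                 covariate_effects = cov_eff, sds = sds,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# clinical correlation targets: disease duration and CAG load are strongly
# correlated (|r| > 0.7) with age of onset and with SARA (later onset means
# shorter duration and fewer repeats; severer ataxia means longer duration),
# while onset and SARA stay below the screening threshold
human_default_correlation <- function() {
  r <- matrix(c(1, -0.80, -0.80, -0.35,
                -0.80, 1, 0.90, 0.75,
                -0.80, 0.90, 1, 0.75,
                -0.35, 0.75, 0.75, 1), 4, 4)
  dimnames(r) <- list(c("onset", "duration", "cag", "sara"),
                      c("onset", "duration", "cag", "sara"))
  r
}

#' @rdname mouse_cohort_spec
#' @export
human_cohort_spec <- function(n_per_group = NULL, group_effects = NULL,
                              covariate_effects = NULL, noise_sds = NULL,
                              correlation_block = human_default_correlation(),
                              seed = 1L) {
  if (is.null(n_per_group)) n_per_group <- c(control = 18L, MJD = 16L)
  if (length(n_per_group) == 1L)
    n_per_group <- c(control = n_per_group, MJD = n_per_group)
  if (any(n_per_group < 2))
    stop("n_per_group must be at least 2 per group", call. = FALSE)
  eff <- c(gm = 8, wm = 4, age = 41.15 - 33.19)  # MJD minus control
  if (!is.null(group_effects)) {
    if (identical(group_effects, 0)) eff[] <- 0
    else eff[names(group_effects)] <- group_effects
  }
  cov_eff <- list(gm_age = -0.39, gm_age_mjd_extra = -0.33,
                  wm_age = -0.11, wm_age_mjd_extra = -0.17,
                  csf_age_base = -0.01, csf_age_male = 0.04,
                  csf_age_mjd = 0.09, csf_age_mjd_male = 0.03,
                  gm_onset = -0.54, gm_sara = -0.50, csf_sara = 0.29)
  if (!is.null(covariate_effects))
    cov_eff[names(covariate_effects)] <- covariate_effects
  sds <- c(age = 10, gm = 5.8, wm = 2.3, csf = 2.4,
           onset = 8, duration = 5, cag = 4, sara = 6)
  if (!is.null(noise_sds)) sds[names(noise_sds)] <- noise_sds
  ev <- eigen(correlation_block, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("correlation_block must be positive definite", call. = FALSE)
  structure(list(species = "human", n_per_group = n_per_group,
                 group_effects = eff, covariate_effects = cov_eff,
                 sds = sds, correlation_block = correlation_block,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort table
#'
#' Draws one row per subject under the spec's means, slopes, dispersions and
#' correlation structure, deterministically under the spec's seed. Mouse
#' tables carry group, age, sex, cerebellar/WM/ventricle volumes, the
#' 17-quantity metabolite panel and accelerated/stationary rotarod
#' latencies; human tables carry group, age, sex, GM/WM/CSF/total cerebellar
#' volumes and, for patients, the correlated clinical block.
#'
#' @param spec a [mouse_cohort_spec()] or [human_cohort_spec()].
#' @return A data.frame of class `cohort_table` with the spec attached as
#'   attribute `"spec"`.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  tab <- withr::with_seed(spec$seed,
    if (spec$species == "mouse") make_mouse_cohort(spec)
    else make_human_cohort(spec))
  attr(tab, "spec") <- spec
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

make_mouse_cohort <- function(spec) {
  cells <- mouse_default_cells()
  if (!is.null(spec$n_per_group)) {
    n <- spec$n_per_group
    cells$n_male <- floor(n / 2)
    cells$n_female <- ceiling(n / 2)
  }
  rows <- list()
  vars <- names(mouse_base_means())
  for (i in seq_len(nrow(cells))) {
    n <- cells$n_male[i] + cells$n_female[i]
    if (n == 0) next
    grp <- cells$group[i]
    mu <- spec$base_means
    if (grp == "MJD") {
      shift <- spec$group_effects
      mu[names(shift)] <- mu[names(shift)] + shift
    }
    sd_tab <- spec$sds[[grp]]
    draw <- vapply(vars, function(v)
      stats::rnorm(n, mu[[v]], sd_tab[[v]]), numeric(n))
    draw <- matrix(draw, nrow = n, dimnames = list(NULL, vars))
    df <- as.data.frame(draw)
    df$NAA_NAAG <- df$NAA + df$NAAG
    df$group <- grp
    df$age_months <- cells$age_months[i]
    df$sex <- c(rep("M", cells$n_male[i]), rep("F", cells$n_female[i]))
    rows[[i]] <- df
  }
  tab <- do.call(rbind, rows)
  ce <- spec$covariate_effects
  n_all <- nrow(tab)
  tab$rotarod_accel_s <- 40 + ce$rotarod_slope_NAA * tab$NAA +
    stats::rnorm(n_all, 0, ce$rotarod_noise_sd)
  tab$rotarod_stationary_s <- 100 + 0.7 * ce$rotarod_slope_NAA * tab$NAA +
    stats::rnorm(n_all, 0, 0.8 * ce$rotarod_noise_sd)
  tab$species <- "mouse"
  tab$subject <- sprintf("m%03d", seq_len(n_all))
  front <- c("subject", "species", "group", "age_months", "sex")
  tab[, c(front, setdiff(names(tab), front))]
}

make_human_cohort <- function(spec) {
  ce <- spec$covariate_effects
  sds <- spec$sds
  groups <- rep(c("control", "MJD"), spec$n_per_group[c("control", "MJD")])
  n <- length(groups)
  is_mjd <- groups == "MJD"
  n_mjd <- sum(is_mjd)
  sex <- unlist(lapply(spec$n_per_group[c("control", "MJD")], function(k)
    rep(c("M", "F"), length.out = k)))
  age <- stats::rnorm(n, 33.19 + ifelse(is_mjd, spec$group_effects[["age"]],
                                        0), sds[["age"]])
  age <- pmax(age, 18)

  # correlated clinical block for patients: onset, duration, CAG, SARA
  mu_clin <- c(onset = 36, duration = 8, cag = 68, sara = 12)
  sd_clin <- sds[c("onset", "duration", "cag", "sara")]
  names(sd_clin) <- names(mu_clin)
  Sigma <- diag(sd_clin) %*% spec$correlation_block %*% diag(sd_clin)
  clin <- MASS::mvrnorm(n_mjd, mu = mu_clin, Sigma = Sigma)
  clin[, "duration"] <- pmax(clin[, "duration"], 0.5)
  clin[, "sara"] <- pmax(clin[, "sara"], 0.5)
  clin[, "cag"] <- round(clin[, "cag"])

  onset_c <- sara_c <- numeric(n)
  onset_c[is_mjd] <- clin[, "onset"] - mu_clin[["onset"]]
  sara_c[is_mjd] <- clin[, "sara"] - mu_clin[["sara"]]
  male <- as.numeric(sex == "M")
  mjd <- as.numeric(is_mjd)

  gm <- 120 + ce$gm_age * age +
    mjd * (spec$group_effects[["gm"]] + ce$gm_age_mjd_extra * age) +
    mjd * (ce$gm_onset * onset_c + ce$gm_sara * sara_c) +
    stats::rnorm(n, 0, sds[["gm"]])
  wm <- 32 + ce$wm_age * age +
    mjd * (spec$group_effects[["wm"]] + ce$wm_age_mjd_extra * age) +
    stats::rnorm(n, 0, sds[["wm"]])
  csf <- 12 + age * (ce$csf_age_base + ce$csf_age_male * male +
                       mjd * (ce$csf_age_mjd + ce$csf_age_mjd_male * male)) +
    mjd * ce$csf_sara * sara_c +
    stats::rnorm(n, 0, sds[["csf"]])

  tab <- data.frame(subject = sprintf("h%03d", seq_len(n)),
                    species = "human", group = groups, age_years = age,
                    sex = sex, gm_volume_ml = gm, wm_volume_ml = wm,
                    csf_volume_ml = csf,
                    total_volume_ml = gm + wm + csf,
                    sara = NA_real_, onset_age_y = NA_real_,
                    disease_duration_y = NA_real_, cag_repeats = NA_real_)
  tab$sara[is_mjd] <- clin[, "sara"]
  tab$onset_age_y[is_mjd] <- clin[, "onset"]
  tab$disease_duration_y[is_mjd] <- clin[, "duration"]
  tab$cag_repeats[is_mjd] <- clin[, "cag"]
  tab
}

#' Write and read cohort tables as TSV
#'
#' @param table a `cohort_table` (or plain data.frame).
#' @param path file path.
#' @return Reader returns the data.frame; writer returns `path` invisibly.
#' @export
write_cohort_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(tab) <- c("cohort_table", "data.frame")
  tab
}
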