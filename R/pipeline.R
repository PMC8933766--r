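#' Pipeline run configuration
#'
#' One configuration object drives the full chain
#' synth -> morphometry -> spectroscopy -> stats. Defaults equal the
#' study-protocol values where one exists (24% CRLB threshold, 1% total
#' outlier exclusion split 0.5% per tail, r > 0.7 collinearity screen,
#' alpha = 0.05 covariate retention); the remaining knobs (LoG scale,
#' permutation count, baseline order) are flagged assumptions with
#' documented defaults.
#'
#' @param stages named logical: which of `synth`, `morphometry`,
#'   `spectroscopy`, `stats` to run.
#' @param seed global seed; stage seeds are derived from it.
#' @param low_tail,high_tail normalization tail fractions.
#' @param log_sigma_mm LoG scale in mm (`NULL`: twice the in-plane voxel).
#' @param crlb_threshold CRLB exclusion threshold in percent.
#' @param baseline_order spectral baseline polynomial order.
#' @param n_permutations PERMANOVA permutation count.
#' @param retention_alpha covariate retention threshold.
#' @param r_threshold collinearity screen threshold.
#' @param phantom a [phantom_spec()] override, or `NULL` for defaults under
#'   the derived seed.
#' @param mouse_cohort,human_cohort cohort spec overrides.
#' @return A list of class `run_config`.
#' @export
run_config <- function(stages = c(synth = TRUE, morphometry = TRUE,
                                  spectroscopy = TRUE, stats = TRUE),
                       seed = 1L, low_tail = 0.005, high_tail = 0.005,
                       log_sigma_mm = NULL, crlb_threshold = 24,
                       baseline_order = 2L, n_permutations = 9999L,
                       retention_alpha = 0.05, r_threshold = 0.7,
                       phantom = NULL, mouse_cohort = NULL,
                       human_cohort = NULL) {
  needed <- c("synth", "morphometry", "spectroscopy", "stats")
  st <- stats::setNames(rep(TRUE, 4), needed)
  st[names(stages)] <- stages
  structure(list(stages = st, seed = as.integer(seed), low_tail = low_tail,
                 high_tail = high_tail, log_sigma_mm = log_sigma_mm,
                 crlb_threshold = crlb_threshold,
                 baseline_order = baseline_order,
                 n_permutations = as.integer(n_permutations),
                 retention_alpha = retention_alpha,
                 r_threshold = r_threshold, phantom = phantom,
                 mouse_cohort = mouse_cohort, human_cohort = human_cohort),
            class = "run_config")
}

#' Per-group reference metabolite concentrations
#'
#' The mean concentration vectors used to synthesize the demonstration
#' spectra: control values from the mouse panel baseline, disease values
#' shifted by the default group effects (the five key neurochemicals plus
#' macromolecules/lipids).
#'
#' @return A list with named numeric vectors `control` and `MJD` over the 16
#'   fitted compounds.
#' @export
group_mean_concentrations <- function() {
  base <- mouse_base_means()
  eff <- mouse_group_effects()
  mets <- setdiff(metabolite_panel(), "NAA_NAAG")
  ctrl <- base[mets]
  mjd <- ctrl
  common <- intersect(names(eff), mets)
  mjd[common] <- mjd[common] + eff[common]
  list(control = ctrl, MJD = mjd)
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order and writes the
#' paper-shaped output tables plus a JSON run manifest to `out_dir`:
#' `cohort_mouse.tsv`, `cohort_human.tsv`, `volumes.tsv`,
#' `fold_changes.tsv`, `metabolites.tsv`, `ratios.tsv`, `stats/*.tsv`,
#' `manifest.json`. Later stages consume earlier stages' in-memory outputs;
#' disabling a stage another enabled stage depends on is a dependency
#' error. Output files from completed stages survive a later-stage failure.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the stage outputs and the manifest.
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  st <- config$stages
  if (st[["morphometry"]] && !st[["synth"]])
    stop("dependency error: morphometry requires the synth stage",
         call. = FALSE)
  if (st[["spectroscopy"]] && !st[["synth"]])
    stop("dependency error: spectroscopy requires the synth stage",
         call. = FALSE)
  if (st[["stats"]] && !(st[["synth"]] && st[["spectroscopy"]]))
    stop("dependency error: the stats stage requires synth and ",
         "spectroscopy outputs", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(
    utils::packageVersion("cerebmrs")),
    config = config[setdiff(names(config), c("phantom", "mouse_cohort",
                                             "human_cohort"))],
    stages = list(), files = list())
  outputs <- list()
  t_stage <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- expr
    list(value = val, seconds = proc.time()[["elapsed"]] - t0)
  }

  if (st[["synth"]]) {
    res <- t_stage({
      ph_spec <- if (is.null(config$phantom))
        phantom_spec(seed = config$seed) else config$phantom
      phantom <- make_phantom(ph_spec)
      calibration <- make_homogeneous_phantom(ph_spec)
      mouse <- make_cohort(if (is.null(config$mouse_cohort))
        mouse_cohort_spec(seed = config$seed + 1L) else config$mouse_cohort)
      human <- make_cohort(if (is.null(config$human_cohort))
        human_cohort_spec(seed = config$seed + 2L) else config$human_cohort)
      basis <- synth_basis()
      gm <- group_mean_concentrations()
      spectra <- list(
        control = make_spectrum(basis, gm$control, baseline_coeffs = c(2, 0.5),
                                seed = config$seed + 3L),
        MJD = make_spectrum(basis, gm$MJD, baseline_coeffs = c(2, 0.5),
                            seed = config$seed + 4L))
      write_cohort_tsv(mouse, file.path(out_dir, "cohort_mouse.tsv"))
      write_cohort_tsv(human, file.path(out_dir, "cohort_human.tsv"))
      list(phantom = phantom, calibration = calibration, mouse = mouse,
           human = human, basis = basis, spectra = spectra)
    })
    outputs$synth <- res$value
    manifest$stages$synth <- list(seconds = res$seconds,
                                  seed = config$seed)
  }

  if (st[["morphometry"]]) {
    res <- t_stage({
      syn <- outputs$synth
      bias <- estimate_bias(syn$calibration)
      corrected <- correct_bias(syn$phantom$image, bias)
      normalized <- normalize_intensity(corrected, config$low_tail,
                                        config$high_tail)
      mask <- syn$phantom$labels$labels %in% c(1L, 2L)
      mask <- array(mask, dim = dim(syn$phantom$labels$labels))
      seg <- suppressWarnings(
        segment_wm_gm(normalized, mask, log_sigma_mm = config$log_sigma_mm))
      vols <- measure_volumes(seg)
      utils::write.table(vols, file.path(out_dir, "volumes.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      grp_means <- function(v) tapply(syn$mouse[[v]], syn$mouse$group, mean)
      fc_rows <- do.call(rbind, lapply(
        c("cerebellum_volume_mm3", "wm_volume_mm3", "ventricle_volume_mm3"),
        function(v) {
          m <- grp_means(v)
          fc <- fold_change(m[["control"]], m[["MJD"]])
          data.frame(variable = v, mean_control = m[["control"]],
                     mean_mjd = m[["MJD"]], fold_change = fc$ratio,
                     direction = fc$direction)
        }))
      utils::write.table(fc_rows, file.path(out_dir, "fold_changes.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      list(bias = bias, segmentation = seg, volumes = vols,
           fold_changes = fc_rows)
    })
    outputs$morphometry <- res$value
    manifest$stages$morphometry <- list(seconds = res$seconds)
  }

  if (st[["spectroscopy"]]) {
    res <- t_stage({
      syn <- outputs$synth
      fits <- lapply(syn$spectra, function(sp) {
        f <- fit_spectrum(sp, syn$basis,
                          baseline_order = config$baseline_order)
        apply_crlb_filter(f, config$crlb_threshold)
      })
      met_tab <- do.call(rbind, lapply(names(fits), function(g) {
        cbind(group = g, fits[[g]]$table)
      }))
      utils::write.table(met_tab, file.path(out_dir, "metabolites.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      ratio_tab <- do.call(rbind, lapply(names(fits), function(g) {
        cbind(group = g, compute_ratios(fits[[g]]))
      }))
      utils::write.table(ratio_tab, file.path(out_dir, "ratios.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      list(fits = fits, metabolites = met_tab, ratios = ratio_tab)
    })
    outputs$spectroscopy <- res$value
    manifest$stages$spectroscopy <- list(seconds = res$seconds)
  }

  if (st[["stats"]]) {
    res <- t_stage({
      syn <- outputs$synth
      stats_dir <- file.path(out_dir, "stats")
      dir.create(stats_dir, showWarnings = FALSE)
      mouse <- syn$mouse
      ctrl <- mouse$cerebellum_volume_mm3[mouse$group == "control"]
      mjd <- mouse$cerebellum_volume_mm3[mouse$group == "MJD"]
      wt_res <- welch_t(ctrl, mjd)
      pca <- run_pca(mouse, metabolite_panel(), scale = TRUE)
      perm <- permanova(mouse, metabolite_panel(), "group",
                        n_permutations = config$n_permutations,
                        seed = config$seed + 10L, scale = TRUE)
      young <- mouse[mouse$group == "MJD" & mouse$age_months %in% c(2, 4), ]
      behav <- regress_behaviour(young, "NAA", "rotarod_accel_s")
      human <- syn$human
      mjd_rows <- human[human$group == "MJD", ]
      screen <- screen_collinearity(mjd_rows,
                                    c("onset_age_y", "disease_duration_y",
                                      "cag_repeats", "sara"),
                                    "gm_volume_ml",
                                    r_threshold = config$r_threshold)
      models <- lapply(c("gm_volume_ml", "wm_volume_ml", "csf_volume_ml",
                         "total_volume_ml"), function(v)
        fit_group_age_sex_model(human, v, alpha = config$retention_alpha))
      names(models) <- c("gm_volume_ml", "wm_volume_ml", "csf_volume_ml",
                         "total_volume_ml")

      utils::write.table(
        data.frame(test = "welch_cerebellar_volume",
                   statistic = wt_res$statistic, df = wt_res$df,
                   p = wt_res$p_value),
        file.path(stats_dir, "welch.tsv"), sep = "\t", row.names = FALSE,
        quote = FALSE)
      utils::write.table(
        data.frame(component = paste0("PC", seq_along(
          pca$variance_explained)),
          variance_explained_pct = pca$variance_explained),
        file.path(stats_dir, "pca_variance.tsv"), sep = "\t",
        row.names = FALSE, quote = FALSE)
      utils::write.table(pca$top_loadings,
                         file.path(stats_dir, "pca_top_loadings.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(
        data.frame(pseudo_F = perm$pseudo_F, p = perm$permutation_p,
                   n_permutations = perm$n_permutations),
        file.path(stats_dir, "permanova.tsv"), sep = "\t",
        row.names = FALSE, quote = FALSE)
      utils::write.table(
        data.frame(metabolite = "NAA", behaviour = "rotarod_accel_s",
                   slope = behav$slope, r_squared = behav$r_squared,
                   p = behav$p_value, n = behav$n),
        file.path(stats_dir, "behaviour_regression.tsv"), sep = "\t",
        row.names = FALSE, quote = FALSE)
      utils::write.table(screen$drop_log,
                         file.path(stats_dir, "collinearity_screen.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      coef_tab <- do.call(rbind, lapply(names(models), function(v)
        cbind(outcome = v, models[[v]]$coefficients)))
      utils::write.table(coef_tab,
                         file.path(stats_dir, "human_volume_models.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      slope_tab <- do.call(rbind, lapply(names(models), function(v)
        if (!is.null(models[[v]]$slopes))
          cbind(outcome = v, models[[v]]$slopes)))
      utils::write.table(slope_tab,
                         file.path(stats_dir, "human_age_slopes.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      list(welch = wt_res, pca = pca, permanova = perm, behaviour = behav,
           screen = screen, models = models)
    })
    outputs$stats <- res$value
    manifest$stages$stats <- list(seconds = res$seconds,
                                  seed = config$seed + 10L)
  }

  written <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  written <- setdiff(written, file.path(out_dir, "manifest.json"))
  manifest$files <- lapply(stats::setNames(written,
                                           sub(paste0(out_dir, "/"), "",
                                               written, fixed = TRUE)),
                           function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(outputs = outputs, manifest = manifest))
}
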