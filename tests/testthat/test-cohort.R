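test_that("cohort generation is deterministic and refuses degenerate sizes", {
  a <- make_cohort(mouse_cohort_spec(seed = 4))
  b <- make_cohort(mouse_cohort_spec(seed = 4))
  expect_identical(a, b)
  expect_error(mouse_cohort_spec(n_per_group = 1), "at least 2")
  expect_error(human_cohort_spec(n_per_group = 1), "at least 2")
})

test_that("the mouse table carries the full panel and composite NAA_NAAG", {
  tab <- make_cohort(mouse_cohort_spec(seed = 1))
  expect_true(all(metabolite_panel() %in% names(tab)))
  expect_length(metabolite_panel(), 17)
  expect_equal(tab$NAA_NAAG, tab$NAA + tab$NAAG)
  expect_setequal(unique(tab$group), c("control", "MJD"))
  expect_setequal(unique(tab$age_months), c(2, 4, 16))
  # study layout sizes
  expect_equal(nrow(tab), 57)
  expect_equal(sum(tab$group == "control"), 28)
})

test_that("null group effects give a uniform two-sample p-value distribution", {
  ps <- vapply(1:60, function(s) {
    tab <- make_cohort(mouse_cohort_spec(n_per_group = 5,
                                         group_effects = 0, seed = s))
    welch_t(tab$cerebellum_volume_mm3[tab$group == "control"],
            tab$cerebellum_volume_mm3[tab$group == "MJD"])$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the configured rotarod dependence on NAA is recovered by OLS", {
  tab <- make_cohort(mouse_cohort_spec(
    n_per_group = 34, covariate_effects = list(rotarod_noise_sd = 5),
    seed = 3))
  slope <- stats::coef(stats::lm(rotarod_accel_s ~ NAA, tab))[2]
  expect_lt(abs(slope - 120) / 120, 0.05)
})

test_that("the clinical correlation block is realized within tolerance", {
  tab <- make_cohort(human_cohort_spec(n_per_group = 500, seed = 6))
  mjd <- tab[tab$group == "MJD", ]
  r_do <- stats::cor(mjd$disease_duration_y, mjd$onset_age_y)
  expect_gte(abs(r_do), 0.7)
  expect_lte(abs(r_do), 0.9)
  target <- human_cohort_spec()$correlation_block
  got <- stats::cor(mjd[, c("onset_age_y", "disease_duration_y",
                            "cag_repeats", "sara")])
  expect_lt(max(abs(got - target)), 0.1)
})

test_that("marginal means converge to the configured values (3 SE at n = 1000)", {
  tab <- make_cohort(mouse_cohort_spec(n_per_group = 334, seed = 12))
  for (v in c("NAA", "Ins", "cerebellum_volume_mm3")) {
    for (g in c("control", "MJD")) {
      x <- tab[[v]][tab$group == g]
      mu <- cerebmrs:::mouse_base_means()[[v]]
      if (g == "MJD") {
        eff <- cerebmrs:::mouse_group_effects()
        if (v %in% names(eff)) mu <- mu + eff[[v]]
      }
      se <- stats::sd(x) / sqrt(length(x))
      expect_lt(abs(mean(x) - mu), 3 * se + 1e-9)
    }
  }
})

test_that("human volumes carry the configured group-by-age structure", {
  tab <- make_cohort(human_cohort_spec(n_per_group = 400, seed = 2))
  tab$group <- factor(tab$group, levels = c("control", "MJD"))
  fit <- stats::lm(gm_volume_ml ~ group * age_years, tab)
  co <- stats::coef(fit)
  se <- summary(fit)$coefficients[, 2]
  expect_lt(abs(co[["age_years"]] - (-0.39)), 3 * se[["age_years"]])
  expect_lt(abs(co[["groupMJD:age_years"]] - (-0.33)),
            3 * se[["groupMJD:age_years"]])
  expect_true(all(is.na(tab$sara[tab$group == "control"])))
  expect_true(all(!is.na(tab$sara[tab$group == "MJD"])))
  expect_equal(tab$total_volume_ml,
               tab$gm_volume_ml + tab$wm_volume_ml + tab$csf_volume_ml)
})

test_that("cohort tables round-trip through TSV", {
  withr::with_tempdir({
    tab <- make_cohort(mouse_cohort_spec(seed = 9))
    write_cohort_tsv(tab, "cohort.tsv")
    tab2 <- read_cohort_tsv("cohort.tsv")
    expect_equal(tab2$NAA, tab$NAA, tolerance = 1e-9)
    expect_identical(tab2$group, tab$group)
  })
})
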