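test_that("welch_t matches the hand-evaluated Welch formula", {
  x <- c(1, 2, 3)
  y <- c(1, 2, 3, 4, 5, 6)
  out <- welch_t(x, y)
  # arithmetic oracle: Welch statistic and Satterthwaite df from first
  # principles
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  t_exp <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df_exp <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  expect_equal(out$statistic, t_exp, tolerance = 1e-12)
  expect_equal(out$df, df_exp, tolerance = 1e-12)
  expect_equal(out$p_value, 2 * stats::pt(-abs(t_exp), df_exp),
               tolerance = 1e-12)

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(welch_t(1, c(1, 2)), "sample-size error")
})

test_that("volumes generated at the reported means separate at p < 0.0001", {
  hits <- vapply(1:40, function(s) {
    tab <- make_cohort(mouse_cohort_spec(seed = 500 + s))
    welch_t(tab$cerebellum_volume_mm3[tab$group == "control"],
            tab$cerebellum_volume_mm3[tab$group == "MJD"])$p_value < 1e-4
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("run_pca matches a brute-force covariance eigendecomposition", {
  x <- data.frame(a = c(1, 4, 2, 8, 5), b = c(2, 3, 9, 1, 4),
                  c = c(7, 1, 4, 2, 6))
  out <- run_pca(x, c("a", "b", "c"), scale = FALSE)
  ev <- eigen(stats::cov(as.matrix(x)), symmetric = TRUE)
  expect_equal(sort(100 * ev$values / sum(ev$values), decreasing = TRUE),
               out$variance_explained, tolerance = 1e-10)
  expect_equal(crossprod(out$loadings), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)

  # single direction of variation
  t <- 1:6
  y <- data.frame(u = 2 * t, v = -t, w = 3 * t)
  out1 <- run_pca(y, c("u", "v", "w"), scale = FALSE)
  expect_equal(out1$variance_explained[1], 100, tolerance = 1e-9)

  y$u[2] <- NA
  expect_error(run_pca(y, c("u", "v", "w")), "missing values")
})

test_that("PCA variance explained is invariant to variable order and rotation", {
  tab <- make_cohort(mouse_cohort_spec(seed = 3))
  vars <- metabolite_panel()[1:6]
  a <- run_pca(tab, vars, scale = TRUE)
  b <- run_pca(tab, rev(vars), scale = TRUE)
  expect_equal(a$variance_explained, b$variance_explained,
               tolerance = 1e-10)
  # consistent orthogonal rotation of unscaled data preserves the spectrum
  x <- as.matrix(tab[, vars])
  q <- qr.Q(qr(matrix(withr::with_seed(1, stats::rnorm(36)), 6)))
  rot <- as.data.frame(x %*% q)
  a2 <- run_pca(as.data.frame(x), names(as.data.frame(x)), scale = FALSE)
  b2 <- run_pca(rot, names(rot), scale = FALSE)
  expect_equal(a2$variance_explained, b2$variance_explained,
               tolerance = 1e-8)
})

test_that("group-shifted metabolites separate along PC1", {
  tab <- make_cohort(mouse_cohort_spec(seed = 8))
  out <- run_pca(tab, metabolite_panel(), scale = TRUE)
  pc1 <- out$scores[, 1]
  grp <- tab$group
  # silhouette-style check: centroids separated beyond within-group spread
  sep <- abs(mean(pc1[grp == "MJD"]) - mean(pc1[grp == "control"]))
  expect_gt(sep, 0)
  sil <- vapply(seq_along(pc1), function(i) {
    same <- grp == grp[i] & seq_along(pc1) != i
    own <- mean(abs(pc1[i] - pc1[same]))
    oth <- mean(abs(pc1[i] - pc1[grp != grp[i]]))
    (oth - own) / max(own, oth)
  }, numeric(1))
  expect_gt(mean(sil), 0)
})

test_that("pseudo-F equals the classical ANOVA F on univariate input", {
  for (s in 1:20) {
    df <- withr::with_seed(s, {
      n <- sample(8:24, 1)
      g <- sample(rep(c("a", "b", "c"), length.out = n))
      while (min(table(g)) < 2) g <- sample(g)
      data.frame(y = stats::rnorm(n), g = g)
    })
    pr <- permanova(df, "y", "g", n_permutations = 19, seed = s)
    f_aov <- summary(stats::aov(y ~ g, df))[[1]]$`F value`[1]
    expect_equal(pr$pseudo_F, f_aov, tolerance = 1e-10)
    expect_equal(unname(pr$ss["total"]),
                 unname(pr$ss["between"] + pr$ss["within"]),
                 tolerance = 1e-10)
  }
})

test_that("pseudo-F agrees with an independent PERMANOVA implementation", {
  skip_if_not_installed("vegan")
  df <- withr::with_seed(10, data.frame(matrix(stats::rnorm(80), 20, 4)))
  df$g <- rep(c("a", "b"), 10)
  ours <- permanova(df, paste0("X", 1:4), "g", n_permutations = 99,
                    seed = 1)
  ref <- vegan::adonis2(df[, 1:4] ~ g, data = df, permutations = 99,
                        method = "euclidean")
  expect_equal(ours$pseudo_F, ref$F[1], tolerance = 1e-10)
})

test_that("permanova is invariant to response column order and flags degeneracy", {
  tab <- make_cohort(mouse_cohort_spec(seed = 5))
  vars <- metabolite_panel()[1:5]
  a <- permanova(tab, vars, "group", n_permutations = 49, seed = 2)
  b <- permanova(tab, rev(vars), "group", n_permutations = 49, seed = 2)
  expect_equal(a$pseudo_F, b$pseudo_F, tolerance = 1e-12)
  expect_equal(a$permutation_p, b$permutation_p)
  expect_gte(a$permutation_p, 1 / 50)

  cst <- data.frame(y = rep(1, 10), g = rep(c("a", "b"), 5))
  expect_error(permanova(cst, "y", "g"), "degenerate-distance")
})

test_that("the collinearity screen keeps uncorrelated candidates and resolves cliques", {
  df <- withr::with_seed(2, data.frame(a = stats::rnorm(40),
                                       b = stats::rnorm(40),
                                       c = stats::rnorm(40)))
  df$y <- df$a + stats::rnorm(40)
  out <- screen_collinearity(df, c("a", "b", "c"), "y")
  expect_setequal(out$retained, c("a", "b", "c"))
  expect_equal(nrow(out$drop_log), 0)

  # three mutually collinear variables: exactly one survives, and it is the
  # one a brute-force pairwise AIC tournament keeps
  base <- withr::with_seed(3, stats::rnorm(60))
  df2 <- data.frame(a = base + stats::rnorm(60, 0, 0.1),
                    b = base + stats::rnorm(60, 0, 0.1),
                    c = base + stats::rnorm(60, 0, 0.1))
  df2$y <- base + stats::rnorm(60, 0, 0.5)
  out2 <- screen_collinearity(df2, c("a", "b", "c"), "y")
  expect_length(out2$retained, 1)
  aic <- vapply(c("a", "b", "c"), function(v) {
    fit <- stats::lm(df2$y ~ df2[[v]])
    60 * log(sum(stats::residuals(fit)^2) / 60) + 4
  }, numeric(1))
  expect_equal(out2$retained, names(which.min(aic)))

  dfz <- data.frame(a = rep(1, 10), b = stats::rnorm(10), y = stats::rnorm(10))
  expect_error(screen_collinearity(dfz, c("a", "b"), "y"),
               "screening error")
})

test_that("the screen drops duration and CAG and retains onset and SARA", {
  tab <- make_cohort(human_cohort_spec(n_per_group = 100, seed = 17))
  mjd <- tab[tab$group == "MJD", ]
  out <- screen_collinearity(mjd, c("onset_age_y", "disease_duration_y",
                                    "cag_repeats", "sara"), "gm_volume_ml")
  expect_setequal(out$retained, c("onset_age_y", "sara"))
  expect_setequal(out$drop_log$dropped,
                  c("disease_duration_y", "cag_repeats"))
})

test_that("group-age-sex model recovers the configured slopes and enforces n", {
  tab <- make_cohort(human_cohort_spec(
    n_per_group = 100, noise_sds = c(gm = 1),
    covariate_effects = list(gm_onset = 0, gm_sara = 0), seed = 23))
  m <- fit_group_age_sex_model(tab, "gm_volume_ml")
  sl <- m$slopes
  expect_lt(abs(sl$beta[sl$group == "MJD"][1] - (-0.72)) / 0.72, 0.1)
  expect_lt(abs(sl$beta[sl$group == "control"][1] - (-0.39)) / 0.39, 0.1)
  expect_true(all(m$coefficients$p_adjusted >= m$coefficients$p_raw,
                  na.rm = TRUE))
  expect_error(fit_group_age_sex_model(tab[1:5, ], "gm_volume_ml"),
               "sample-size error")
})

test_that("a null sex effect is removed by the covariate retention rule", {
  dropped <- vapply(1:20, function(s) {
    tab <- make_cohort(human_cohort_spec(seed = 700 + s))
    m <- fit_group_age_sex_model(tab, "gm_volume_ml")
    !any(grepl("sex", m$terms_retained))
  }, logical(1))
  # 20-seed spot check of the >= 90% specificity rate (allows 3 misses)
  expect_gte(mean(dropped), 0.85)
})

test_that("behaviour regression matches the closed-form least squares", {
  df <- data.frame(m = c(1, 2, 3, 4), r = c(2.1, 3.9, 6.2, 7.8))
  out <- regress_behaviour(df, "m", "r")
  sxx <- sum((df$m - mean(df$m))^2)
  sxy <- sum((df$m - mean(df$m)) * (df$r - mean(df$r)))
  slope <- sxy / sxx
  intercept <- mean(df$r) - slope * mean(df$m)
  r2 <- sxy^2 / (sxx * sum((df$r - mean(df$r))^2))
  expect_equal(out$slope, slope, tolerance = 1e-12)
  expect_equal(out$intercept, intercept, tolerance = 1e-12)
  expect_equal(out$r_squared, r2, tolerance = 1e-12)

  exact <- data.frame(m = 1:5, r = 2 * (1:5))
  oute <- suppressWarnings(regress_behaviour(exact, "m", "r"))
  expect_equal(oute$slope, 2, tolerance = 1e-12)
  expect_equal(oute$r_squared, 1, tolerance = 1e-12)

  flat <- data.frame(m = rep(1, 5), r = stats::rnorm(5))
  expect_error(regress_behaviour(flat, "m", "r"), "domain error")
})

test_that("rotarod r-squared sits in the reported regime across seeds", {
  r2s <- vapply(1:25, function(s) {
    tab <- make_cohort(mouse_cohort_spec(seed = 900 + s))
    young <- tab[tab$group == "MJD" & tab$age_months %in% c(2, 4), ]
    regress_behaviour(young, "NAA", "rotarod_accel_s")$r_squared
  }, numeric(1))
  expect_gte(stats::median(r2s), 0.15)
  expect_lte(stats::median(r2s), 0.55)
})

test_that("Bonferroni adjustment follows the definition and never shrinks p", {
  expect_equal(adjust_bonferroni(c(0.01, 0.04), m = 2), c(0.02, 0.08))
  expect_equal(adjust_bonferroni(0.3), 0.3)
  ps <- withr::with_seed(4, stats::runif(50))
  expect_true(all(adjust_bonferroni(ps, m = 7) >= ps))
  expect_true(all(adjust_bonferroni(ps, m = 7) <= 1))
  expect_error(adjust_bonferroni(c(0.5, 1.2)), "domain error")
})
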