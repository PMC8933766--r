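basis <- synth_basis()

test_that("a pure noiseless signature is recovered exactly", {
  sp <- make_spectrum(basis, c(NAA = 1.0), noise_sd = 0)
  fit <- fit_spectrum(sp, basis, baseline_order = -1)
  conc <- stats::setNames(fit$table$concentration, fit$table$metabolite)
  expect_equal(conc[["NAA"]], 1.0, tolerance = 1e-6)
  expect_true(all(conc[setdiff(names(conc), "NAA")] < 1e-6))
})

test_that("CRLB percentages double when the noise doubles", {
  conc <- c(NAA = 1.02, Ins = 4.95, Cr = 3.9, PCr = 4.3, Glu = 5.8)
  f1 <- fit_spectrum(make_spectrum(basis, conc, noise_sd = 0.1, seed = 5),
                     basis)
  f2 <- fit_spectrum(make_spectrum(basis, conc, noise_sd = 0.2, seed = 5),
                     basis)
  keep <- !is.na(f1$table$crlb_percent) & !is.na(f2$table$crlb_percent) &
    f1$table$concentration > 0.1
  ratio <- f2$table$crlb_percent[keep] / f1$table$crlb_percent[keep]
  expect_equal(median(ratio), 2, tolerance = 0.06)
})

test_that("CRLB vanishes as noise vanishes for fitted metabolites", {
  conc <- c(NAA = 1.0, Cr = 3.9)
  crlbs <- vapply(c(0.1, 0.01, 0.001), function(ns) {
    f <- fit_spectrum(make_spectrum(basis, conc, noise_sd = ns, seed = 2),
                      basis)
    f$table$crlb_percent[f$table$metabolite == "NAA"]
  }, numeric(1))
  expect_true(all(diff(crlbs) < 0))
  expect_lt(crlbs[3], 0.05)
})

test_that("residual norm is non-increasing in baseline order", {
  conc <- c(NAA = 1.02, Ins = 4.95, Cr = 3.9)
  sp <- make_spectrum(basis, conc, baseline_coeffs = c(1, 0.5, -0.3),
                      noise_sd = 0.1, seed = 11)
  norms <- vapply(-1:4, function(k)
    fit_spectrum(sp, basis, baseline_order = k)$residual_norm, numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("the CRLB filter masks strictly above threshold and keeps the boundary", {
  sp <- make_spectrum(basis, c(NAA = 1, Lac = 1), noise_sd = 0.05, seed = 1)
  fit <- fit_spectrum(sp, basis)
  fit$table$crlb_percent[fit$table$metabolite == "NAA"] <- 5
  fit$table$crlb_percent[fit$table$metabolite == "Lac"] <- 40
  out <- apply_crlb_filter(fit, 24)
  expect_true(out$table$included[out$table$metabolite == "NAA"])
  expect_false(out$table$included[out$table$metabolite == "Lac"])

  fit$table$crlb_percent[fit$table$metabolite == "Lac"] <- 24
  out2 <- apply_crlb_filter(fit, 24)
  expect_true(out2$table$included[out2$table$metabolite == "Lac"])

  out3 <- apply_crlb_filter(fit, Inf)
  expect_true(all(out3$table$included[!is.na(fit$table$crlb_percent)]))
  # concentrations are preserved, not zeroed
  expect_identical(out$table$concentration, fit$table$concentration)
})

test_that("referencing rescales, cancels in ratios, and round-trips", {
  conc <- c(NAA = 1.0, Ins = 2.0, Cr = 1.0, PCr = 1.0, PCh = 0.3,
            GPC = 0.4)
  sp <- make_spectrum(basis, conc, noise_sd = 0, water_reference = 50)
  fit <- apply_crlb_filter(fit_spectrum(sp, basis, baseline_order = -1))

  cr_mode <- reference_concentrations(fit, "creatine")
  # total creatine is 2, so every concentration halves
  expect_equal(cr_mode$table$concentration, fit$table$concentration / 2,
               tolerance = 1e-9)

  w_mode <- reference_concentrations(fit, "water", water_concentration = 3)
  r_w <- compute_ratios(w_mode)
  r_c <- compute_ratios(cr_mode)
  expect_equal(r_w$value, r_c$value, tolerance = 1e-9)
  expect_equal(r_w$value[r_w$ratio == "NAA/Ins"], 0.5, tolerance = 1e-6)

  back <- reference_concentrations(cr_mode, "raw")
  expect_equal(back$table$concentration, fit$table$concentration,
               tolerance = 1e-12)
})

test_that("excluded metabolites propagate missing ratios with a reason", {
  conc <- c(NAA = 1.0, Ins = 2.0, PCh = 0.3, GPC = 0.4)
  sp <- make_spectrum(basis, conc, noise_sd = 0)
  fit <- fit_spectrum(sp, basis, baseline_order = -1)
  fit$table$crlb_percent[fit$table$metabolite == "Ins"] <- 60
  fit <- apply_crlb_filter(fit, 24)
  out <- compute_ratios(fit)
  expect_true(is.na(out$value[out$ratio == "NAA/Ins"]))
  expect_match(out$reason[out$ratio == "NAA/Ins"], "Ins excluded")
  expect_false(is.na(out$value[out$ratio == "NAA/tCho"]))
})

test_that("axis mismatch and collinear bases raise the contracted errors", {
  sp <- make_spectrum(basis, c(NAA = 1), noise_sd = 0)
  other <- synth_basis(ppm = seq(5.9, 0.2, length.out = 1024))
  expect_error(fit_spectrum(sp, other), "axis error")

  dup <- mrs_basis(basis$ppm,
                   cbind(A = basis$signatures[, "NAA"],
                         B = basis$signatures[, "NAA"] * 2))
  spd <- mrs_spectrum(basis$ppm, basis$signatures[, "NAA"])
  expect_error(fit_spectrum(spd, dup), "conditioning error.*A.*B")
})

test_that("synthetic group-mean spectra echo the reported marker direction", {
  gm <- group_mean_concentrations()
  fits <- lapply(c(control = "control", MJD = "MJD"), function(g) {
    sp <- make_spectrum(basis, gm[[g]], baseline_coeffs = c(2, 0.5),
                        seed = if (g == "MJD") 41 else 40)
    apply_crlb_filter(fit_spectrum(sp, basis))
  })
  r <- lapply(fits, compute_ratios)
  naa_ins <- vapply(r, function(x) x$value[x$ratio == "NAA/Ins"],
                    numeric(1))
  expect_lt(naa_ins[["MJD"]], naa_ins[["control"]])
})
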