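#' Welch two-sample t-test
#'
#' Unpaired t-test with Welch's correction (unequal variances, Satterthwaite
#' degrees of freedom), two-sided. Thin wrapper around [stats::t.test()]
#' returning the statistic, df and p-value in a fixed shape.
#'
#' @param x,y numeric samples, each with at least 2 finite values.
#' @return List with `statistic`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @export
welch_t <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("sample-size error: each group needs at least 2 observations",
         call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0 && mean(x) == mean(y))
    return(list(statistic = 0, df = length(x) + length(y) - 2, p_value = 1,
                mean_x = mean(x), mean_y = mean(y)))
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Principal component analysis of cohort variables
#'
#' Eigen-decomposition of the (optionally scaled) covariance of the selected
#' variables via [stats::prcomp()], reporting per-subject scores, loadings,
#' percent variance explained, and the variables most correlated with the
#' leading components (the loading-inspection table used to pick the
#' disease-relevant metabolites). Scaling defaults on because metabolite
#' panels mix heterogeneous units.
#'
#' @param table a data.frame (e.g. a cohort table).
#' @param variables character vector of >= 2 numeric columns.
#' @param scale use the correlation form (default `TRUE`).
#' @param n_top how many top-|loading| variables to report per component.
#' @return A list of class `pca_result` with `scores`, `loadings`,
#'   `variance_explained` (percent), and `top_loadings`.
#' @export
run_pca <- function(table, variables, scale = TRUE, n_top = 5L) {
  stopifnot(length(variables) >= 2, all(variables %in% names(table)))
  x <- as.matrix(table[, variables])
  if (nrow(x) < 3) stop("PCA needs at least 3 subjects", call. = FALSE)
  if (anyNA(x))
    stop("missing values among selected variables; filter the table to ",
         "complete cases first", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = scale)
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  k <- min(2L, ncol(pc$rotation))
  top <- do.call(rbind, lapply(seq_len(k), function(j) {
    ord <- order(abs(pc$rotation[, j]), decreasing = TRUE)
    head_n <- utils::head(ord, n_top)
    data.frame(component = paste0("PC", j),
               variable = rownames(pc$rotation)[head_n],
               loading = pc$rotation[head_n, j], row.names = NULL)
  }))
  structure(list(scores = pc$x, loadings = pc$rotation,
                 variance_explained = ve, top_loadings = top,
                 scaled = scale),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> PC1 %.1f%%, PC2 %.1f%% of variance\n",
              x$variance_explained[1],
              if (length(x$variance_explained) > 1)
                x$variance_explained[2] else NA))
  print(x$top_loadings, digits = 3)
  invisible(x)
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Distance-based pseudo-F computed from the partition of the squared
#' Euclidean inter-point distances (the Gower-centered form): with groups
#' `g` of sizes `n_g`, `SS_total = sum_{i<j} d_ij^2 / n` and
#' `SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g`;
#' `F = (SS_between / (a - 1)) / (SS_within / (n - a))`. The p-value comes
#' from permuting the factor labels, with the observed statistic included
#' in the permutation reference set. Implemented directly from this
#' definition rather than delegating to an existing routine, so the
#' statistic and permutation scheme are fully auditable.
#'
#' @param table data.frame of subjects.
#' @param response_variables numeric response columns.
#' @param factor_name grouping column; >= 2 levels with >= 2 subjects each.
#' @param n_permutations number of label permutations (default 9999).
#' @param seed RNG seed for the permutations.
#' @param scale standardize responses to unit variance first.
#' @return A list of class `permanova_result`: `pseudo_F`, `permutation_p`,
#'   `n_permutations`, `ss` (total/between/within), `df`.
#' @export
permanova <- function(table, response_variables, factor_name,
                      n_permutations = 9999L, seed = 1L, scale = FALSE) {
  stopifnot(all(response_variables %in% names(table)),
            factor_name %in% names(table))
  x <- as.matrix(table[, response_variables, drop = FALSE])
  if (anyNA(x)) stop("missing values in responses; filter first",
                     call. = FALSE)
  g <- factor(table[[factor_name]])
  n <- nrow(x)
  a <- nlevels(g)
  if (a < 2 || any(table(g) < 2))
    stop("factor needs >= 2 levels with >= 2 subjects each", call. = FALSE)
  if (scale) x <- base::scale(x)
  d2 <- as.matrix(stats::dist(x))^2
  if (all(d2 == 0))
    stop("degenerate-distance error: all responses are constant",
         call. = FALSE)
  ss_total <- sum(d2) / (2 * n)
  within_ss <- function(gg) {
    s <- 0
    for (lev in levels(gg)) {
      idx <- which(gg == lev)
      s <- s + sum(d2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  ss_within <- within_ss(g)
  ss_between <- ss_total - ss_within
  f_obs <- (ss_between / (a - 1)) / (ss_within / (n - a))
  f_perm <- withr::with_seed(seed, vapply(seq_len(n_permutations),
    function(i) {
      gp <- g[sample.int(n)]
      sw <- within_ss(gp)
      ((ss_total - sw) / (a - 1)) / (sw / (n - a))
    }, numeric(1)))
  p <- (1 + sum(f_perm >= f_obs)) / (n_permutations + 1)
  structure(list(pseudo_F = f_obs, permutation_p = p,
                 n_permutations = n_permutations,
                 ss = c(total = ss_total, between = ss_between,
                        within = ss_within),
                 df = c(between = a - 1, within = n - a)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("<permanova_result> pseudo-F = %.4f (df %d, %d), p = %.4g (%d permutations)\n",
              x$pseudo_F, x$df[1], x$df[2], x$permutation_p,
              x$n_permutations))
  invisible(x)
}

# Gaussian univariate-regression AIC: n * log(RSS / n) + 2k, k counting the
# intercept and slope. Stated explicitly because AIC conventions differ by a
# constant; only differences matter here.
univariate_aic <- function(y, x) {
  fit <- stats::lm(y ~ x)
  rss <- sum(stats::residuals(fit)^2)
  n <- length(y)
  list(aic = n * log(rss / n) + 2 * 2,
       p = summary(fit)$coefficients[2, 4])
}

#' Collinearity screen with AIC-based selection
#'
#' For every pair of candidate predictors with `|r| > r_threshold`, only the
#' member whose univariate Gaussian regression on the outcome has the lower
#' AIC is kept (ties broken by the lower univariate p-value, then by
#' alphabetical order). Pairs are resolved in deterministic alphabetical
#' order until no retained pair exceeds the threshold. Cases where the AIC
#' and p-value rules disagree are resolved by AIC and flagged in the log.
#'
#' @param table data.frame with complete cases on the used columns.
#' @param candidates >= 2 candidate predictor columns.
#' @param outcome outcome column.
#' @param r_threshold absolute Pearson correlation threshold (default 0.7).
#' @return A list of class `collinearity_screen`: `retained` (character) and
#'   `drop_log` (one row per resolved pair: kept, dropped, r, AICs,
#'   p-values, conflict flag).
#' @export
screen_collinearity <- function(table, candidates, outcome,
                                r_threshold = 0.7) {
  stopifnot(length(candidates) >= 2,
            all(c(candidates, outcome) %in% names(table)))
  dat <- table[, c(candidates, outcome)]
  if (anyNA(dat))
    stop("missing values among candidates/outcome; subset to complete ",
         "cases first", call. = FALSE)
  vars <- vapply(candidates, function(v) stats::var(dat[[v]]), numeric(1))
  if (any(vars == 0))
    stop("screening error: zero-variance candidate(s): ",
         paste(candidates[vars == 0], collapse = ", "), call. = FALSE)
  y <- dat[[outcome]]
  uni <- lapply(candidates, function(v) univariate_aic(y, dat[[v]]))
  names(uni) <- candidates
  retained <- sort(candidates)
  log_rows <- list()
  repeat {
    if (length(retained) < 2) break
    cm <- stats::cor(dat[, retained, drop = FALSE])
    pairs <- which(abs(cm) > r_threshold & upper.tri(cm), arr.ind = TRUE)
    if (nrow(pairs) == 0) break
    # deterministic order: alphabetical by (first, second) member
    pr <- data.frame(a = rownames(cm)[pairs[, 1]],
                     b = colnames(cm)[pairs[, 2]])
    swap <- pr$a > pr$b
    tmp <- pr$a[swap]; pr$a[swap] <- pr$b[swap]; pr$b[swap] <- tmp
    pr <- pr[order(pr$a, pr$b), , drop = FALSE]
    va <- pr$a[1]; vb <- pr$b[1]
    ua <- uni[[va]]; ub <- uni[[vb]]
    keep_by_aic <- if (ua$aic < ub$aic) va else if (ub$aic < ua$aic) vb
    else if (ua$p < ub$p) va else if (ub$p < ua$p) vb else min(va, vb)
    keep_by_p <- if (ua$p < ub$p) va else vb
    drop <- setdiff(c(va, vb), keep_by_aic)
    log_rows[[length(log_rows) + 1]] <-
      data.frame(kept = keep_by_aic, dropped = drop,
                 r = cm[va, vb],
                 aic_kept = uni[[keep_by_aic]]$aic,
                 aic_dropped = uni[[drop]]$aic,
                 p_kept = uni[[keep_by_aic]]$p,
                 p_dropped = uni[[drop]]$p,
                 aic_p_conflict = keep_by_aic != keep_by_p)
    retained <- setdiff(retained, drop)
  }
  structure(list(retained = retained,
                 drop_log = if (length(log_rows) > 0)
                   do.call(rbind, log_rows)
                 else data.frame(kept = character(0), dropped = character(0),
                                 r = numeric(0), aic_kept = numeric(0),
                                 aic_dropped = numeric(0),
                                 p_kept = numeric(0), p_dropped = numeric(0),
                                 aic_p_conflict = logical(0))),
            class = "collinearity_screen")
}

find_age_column <- function(table) {
  hit <- intersect(c("age_years", "age_months", "age"), names(table))
  if (length(hit) == 0) stop("no age column found", call. = FALSE)
  hit[1]
}

#' Group x age x sex multiple regression with covariate retention
#'
#' Fits `outcome ~ group * age * sex`, then applies the covariate retention
#' rule: each covariate (age, sex) is kept only when the joint F-test of all
#' model terms involving it is significant at `alpha`. Covariates are
#' removed backward, least significant bundle first; the group effect is
#' never removed. Reports the coefficient table with raw and
#' Bonferroni-adjusted p-values (adjusted across the model's non-intercept
#' terms) and, when age is retained, the per-stratum age slopes
#' (beta +/- SE, t, p) for each group (by sex when sex is retained) — the
#' form in which group differences in volumetric ageing are reported.
#'
#' @param table cohort table with `group`, `sex` and an age column.
#' @param outcome numeric outcome column.
#' @param alpha retention threshold for covariate terms (default 0.05).
#' @param age_col,sex_col,group_col column names; age auto-detected.
#' @return A list of class `model_fit_result`: `model`, `terms_retained`,
#'   `removal_log`, `coefficients` (term, beta, se, t, p_raw, p_adjusted),
#'   `slopes` (per-stratum age slopes), `r_squared`.
#' @export
fit_group_age_sex_model <- function(table, outcome, alpha = 0.05,
                                    age_col = NULL, sex_col = "sex",
                                    group_col = "group") {
  stopifnot(outcome %in% names(table))
  if (is.null(age_col)) age_col <- find_age_column(table)
  dat <- data.frame(y = table[[outcome]],
                    group = factor(table[[group_col]]),
                    age = as.numeric(table[[age_col]]),
                    sex = factor(table[[sex_col]]))
  if ("control" %in% levels(dat$group))
    dat$group <- stats::relevel(dat$group, "control")
  if (anyNA(dat)) stop("missing values; subset to complete cases first",
                       call. = FALSE)
  if (nrow(dat) < 10)
    stop("sample-size error: need at least 10 subjects", call. = FALSE)

  fit <- stats::lm(y ~ group * age * sex, data = dat)
  if (any(is.na(stats::coef(fit))))
    stop("model error: design is rank deficient (aliased terms: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "), ")", call. = FALSE)
  removal_log <- data.frame(covariate = character(0),
                            p_at_removal = numeric(0))
  covariate_p <- function(fit, v) {
    tl <- attr(stats::terms(fit), "term.labels")
    with_v <- tl[vapply(strsplit(tl, ":"), function(p) v %in% p, logical(1))]
    if (length(with_v) == 0) return(NULL)
    reduced <- stats::update(fit, stats::as.formula(
      paste(". ~ .", paste("-", with_v, collapse = " "))))
    an <- stats::anova(reduced, fit)
    an[["Pr(>F)"]][2]
  }
  repeat {
    pv <- vapply(c("age", "sex"), function(v) {
      p <- covariate_p(fit, v)
      if (is.null(p)) NA_real_ else p
    }, numeric(1))
    pv <- pv[!is.na(pv)]
    if (length(pv) == 0 || min(1, max(pv)) < alpha) break
    drop_v <- names(pv)[which.max(pv)]
    removal_log <- rbind(removal_log,
                         data.frame(covariate = drop_v,
                                    p_at_removal = max(pv)))
    tl <- attr(stats::terms(fit), "term.labels")
    with_v <- tl[vapply(strsplit(tl, ":"),
                        function(p) drop_v %in% p, logical(1))]
    fit <- stats::update(fit, stats::as.formula(
      paste(". ~ .", paste("-", with_v, collapse = " "))))
  }

  sm <- summary(fit)
  co <- sm$coefficients
  terms_now <- attr(stats::terms(fit), "term.labels")
  non_int <- rownames(co) != "(Intercept)"
  padj <- rep(NA_real_, nrow(co))
  padj[non_int] <- adjust_bonferroni(co[non_int, 4], m = sum(non_int))
  coefficients <- data.frame(term = rownames(co), beta = co[, 1],
                             se = co[, 2], t = co[, 3], p_raw = co[, 4],
                             p_adjusted = padj, row.names = NULL)

  slopes <- NULL
  if (any(grepl("age", terms_now))) {
    V <- stats::vcov(fit)
    cn <- names(stats::coef(fit))
    strata <- expand.grid(group = levels(dat$group),
                          sex = if (any(grepl("sex", terms_now)))
                            levels(dat$sex) else NA,
                          stringsAsFactors = FALSE)
    slopes <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
      nd0 <- data.frame(group = factor(strata$group[i],
                                       levels(dat$group)),
                        age = 0,
                        sex = factor(if (is.na(strata$sex[i]))
                          levels(dat$sex)[1] else strata$sex[i],
                          levels(dat$sex)))
      nd1 <- nd0; nd1$age <- 1
      X <- stats::model.matrix(stats::delete.response(stats::terms(fit)),
                               rbind(nd1, nd0))
      ct <- X[1, ] - X[2, ]  # d fitted / d age in this stratum
      b <- sum(ct * stats::coef(fit))
      se <- sqrt(drop(t(ct) %*% V %*% ct))
      tval <- b / se
      data.frame(group = strata$group[i], sex = strata$sex[i], beta = b,
                 se = se, t = tval,
                 p = 2 * stats::pt(-abs(tval), df = fit$df.residual))
    }))
  }

  structure(list(model = fit, terms_retained = terms_now,
                 removal_log = removal_log, coefficients = coefficients,
                 slopes = slopes, r_squared = sm$r.squared,
                 outcome = outcome),
            class = "model_fit_result")
}

#' @export
print.model_fit_result <- function(x, ...) {
  cat(sprintf("<model_fit_result> %s ~ %s  (R^2 = %.3f)\n", x$outcome,
              paste(x$terms_retained, collapse = " + "), x$r_squared))
  print(x$coefficients, digits = 3)
  if (!is.null(x$slopes)) {
    cat("per-stratum age slopes:\n")
    print(x$slopes, digits = 3)
  }
  invisible(x)
}

#' Metabolite-behaviour linear regression
#'
#' Ordinary least squares of a behavioural score (e.g. rotarod latency to
#' fall) on a metabolite concentration, reporting slope, intercept, r^2 and
#' the two-sided p-value for the slope.
#'
#' @param table cohort table.
#' @param metabolite predictor column.
#' @param behaviour outcome column.
#' @return A list of class `behaviour_regression`: `slope`, `intercept`,
#'   `r_squared`, `p_value`, `se_slope`, `n`.
#' @export
regress_behaviour <- function(table, metabolite, behaviour) {
  stopifnot(all(c(metabolite, behaviour) %in% names(table)))
  dat <- data.frame(x = table[[metabolite]], y = table[[behaviour]])
  dat <- dat[stats::complete.cases(dat), ]
  if (nrow(dat) < 3)
    stop("need at least 3 paired observations", call. = FALSE)
  if (stats::var(dat$x) == 0)
    stop("domain error: predictor has zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x, data = dat)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 se_slope = sm$coefficients[2, 2],
                 n = nrow(dat)),
            class = "behaviour_regression")
}

#' Bonferroni adjustment
#'
#' `p * m` clipped at 1, with `m` the number of tested terms (defaults to
#' the number of p-values supplied).
#'
#' @param p_values numeric p-values in `[0, 1]`.
#' @param m multiplicity; default `length(p_values)`.
#' @return Adjusted p-values, never below the raw ones.
#' @export
adjust_bonferroni <- function(p_values, m = length(p_values)) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("domain error: p-values must lie in [0, 1]", call. = FALSE)
  stopifnot(m >= 1)
  pmin(1, p_values * m)
}
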