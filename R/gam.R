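#' Specify the regional age model
#'
#' Describes the penalized-spline generalized additive model fitted to each
#' region (or edge): the metric as response, age as a thin-plate regression
#' spline smooth with basis dimension `k`, and linear covariates (by default
#' sex and mean framewise displacement). `k = 3` keeps the smooth to gentle,
#' monotone-or-single-bend trajectories and guards against overfitting at
#' developmental sample sizes.
#'
#' @param k Smooth basis dimension (>= 3).
#' @param smoothing `"reml"` (default), `"gcv"`, or `"fixed"` (supply `sp`).
#' @param sp Fixed smoothing parameter; required when `smoothing = "fixed"`.
#'   `sp = 0` gives the unpenalized fit, very large `sp` collapses the smooth
#'   onto its linear null space.
#' @param covariates Character vector of linear covariate column names; must
#'   not include `"age"`.
#' @return A list of class `gam_spec`.
#' @export
gam_spec <- function(k = 3, smoothing = c("reml", "gcv", "fixed"), sp = NULL,
                     covariates = c("sex", "mean_fd")) {
  smoothing <- match.arg(smoothing)
  if (k < 3) abort("`k` must be >= 3.")
  if ("age" %in% covariates) abort("`covariates` must not include the age term.")
  if (smoothing == "fixed" && (is.null(sp) || sp < 0))
    abort("`smoothing = \"fixed\"` requires a non-negative `sp`.")
  structure(list(k = k, smoothing = smoothing, sp = sp, covariates = covariates),
            class = "gam_spec")
}

gam_formula <- function(spec, response = "y") {
  rhs <- paste(c(sprintf("s(age, k = %d, bs = \"tp\")", spec$k), spec$covariates),
               collapse = " + ")
  stats::as.formula(paste(response, "~", rhs))
}

check_design <- function(df, spec) {
  if (length(unique(df$age)) < 10)
    abort("degenerate design: fewer than 10 unique ages.")
  if (anyNA(df)) abort("model data contain missing values.")
  X <- model.matrix(stats::as.formula(
    paste("~", paste(c("age", spec$covariates), collapse = " + "))), df)
  if (qr(X)$rank < ncol(X))
    abort("rank-deficient covariate design.")
}

#' Fit the penalized-spline age model for one region
#'
#' Fits `y ~ s(age, k) + covariates` by penalized least squares via
#' [mgcv::gam()], with the smoothing parameter selected by REML (default),
#' GCV, or fixed. As the smoothing parameter grows the smooth collapses to
#' the linear-in-age fit (the penalty's null space).
#'
#' @param cohort Data frame with columns `age` and the spec's covariates.
#' @param y Numeric response vector (one value per row of `cohort`), or the
#'   name of a column of `cohort`.
#' @param spec A [gam_spec()].
#' @return Object of class `region_gam`: the mgcv fit plus the spec, the
#'   training age range, adjusted R-squared, smooth effective degrees of
#'   freedom, and smoothing parameter.
#' @export
fit_region_gam <- function(cohort, y, spec = gam_spec()) {
  if (is.character(y) && length(y) == 1) y <- cohort[[y]]
  if (length(y) != nrow(cohort)) abort("`y` length must match `cohort` rows.")
  if (!all(is.finite(y))) abort("`y` must be finite.")
  df <- as.data.frame(cohort[, c("age", spec$covariates), drop = FALSE])
  df$y <- y
  check_design(df, spec)
  # smoothness selection has no information in a constant response; any fixed
  # penalty gives the same flat fit, so pin it rather than let REML/GCV fail
  if (sd(y) == 0) spec <- gam_spec(k = spec$k, smoothing = "fixed", sp = 1,
                                   covariates = spec$covariates)
  fit <- switch(spec$smoothing,
    reml = mgcv::gam(gam_formula(spec), data = df, method = "REML"),
    gcv = mgcv::gam(gam_formula(spec), data = df, method = "GCV.Cp"),
    fixed = mgcv::gam(gam_formula(spec), data = df, sp = spec$sp)
  )
  structure(list(
    fit = fit, spec = spec, n = nrow(df),
    age_range = range(df$age),
    covariate_ref = covariate_reference(df, spec),
    edf = sum(fit$edf[grep("s\\(age\\)", names(coef(fit)))]),
    lambda = if (length(fit$sp)) unname(fit$sp) else spec$sp,
    r2_adj = adj_r2_fit(fit)
  ), class = "region_gam")
}

covariate_reference <- function(df, spec) {
  # numeric covariates at the sample mean; binary 0/1 at the sample proportion
  vapply(spec$covariates, function(v) mean(df[[v]]), numeric(1))
}

# adjusted R^2 with model df = total effective parameters (incl. intercept)
adj_r2 <- function(y, rss, edf_total) {
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(NA_real_)
  1 - (rss / (n - edf_total)) / (tss / (n - 1))
}

adj_r2_fit <- function(fit) {
  adj_r2(fit$y, sum(resid(fit)^2), sum(fit$edf))
}

#' @export
print.region_gam <- function(x, ...) {
  cat(sprintf("<region_gam> n = %d, ages %.1f-%.1f, edf = %.2f, lambda = %.3g, adj R2 = %.3f\n",
              x$n, x$age_range[1], x$age_range[2], x$edf,
              ifelse(is.null(x$lambda), NA, x$lambda[1]), x$r2_adj))
  invisible(x)
}

#' Signed age effect size for one region
#'
#' Quantifies the developmental effect as the change in adjusted R-squared
#' between the full model (`y ~ s(age) + covariates`) and a reduced model
#' without the age term. Significance comes from an approximate F comparison
#' of the two models' residual sums of squares, with the full model's degrees
#' of freedom based on its total effective degrees of freedom. The direction
#' of development is the sign of the age slope in the equivalent linear model
#' `y ~ age + covariates`; the signed effect is `direction * max(delta_r2_adj, 0)`.
#'
#' @inheritParams fit_region_gam
#' @return One-row tibble: `delta_r2_adj`, `direction`, `signed_effect`,
#'   `p_value`, `edf`, `lambda`, `r2_adj_full`, `r2_adj_reduced`.
#' @export
age_effect <- function(cohort, y, spec = gam_spec()) {
  if (is.character(y) && length(y) == 1) y <- cohort[[y]]
  full <- fit_region_gam(cohort, y, spec)
  df <- as.data.frame(cohort[, c("age", spec$covariates), drop = FALSE])
  df$y <- y
  red_form <- stats::as.formula(
    paste("y ~", paste(spec$covariates, collapse = " + ")))
  red <- lm(red_form, data = df)
  lin <- lm(stats::as.formula(
    paste("y ~", paste(c("age", spec$covariates), collapse = " + "))), data = df)

  n <- nrow(df)
  rss_f <- sum(resid(full$fit)^2)
  rss_r <- sum(resid(red)^2)
  edf_f <- sum(full$fit$edf)
  p_r <- length(coef(red))
  r2_f <- adj_r2(y, rss_f, edf_f)
  r2_r <- adj_r2(y, rss_r, p_r)

  out <- age_effect_from_parts(y, rss_f, rss_r, edf_f, p_r, n,
                               coef(lin)[["age"]], df_age = spec$k - 1)
  out$edf <- full$edf
  out$lambda <- if (is.null(full$lambda)) NA_real_ else full$lambda[1]
  out$r2_adj_full <- r2_f
  out$r2_adj_reduced <- r2_r
  out
}

age_effect_from_parts <- function(y, rss_f, rss_r, edf_f, p_r, n, age_slope,
                                  df_age) {
  r2_f <- adj_r2(y, rss_f, edf_f)
  r2_r <- adj_r2(y, rss_r, p_r)
  delta <- r2_f - r2_r
  # F comparison of the reduced model against the penalized fit: numerator df
  # is the age smooth's basis dimension (k - 1), denominator df the full
  # model's effective residual df. Using the basis dimension rather than the
  # realized edf keeps the test calibrated under the null, where adaptive
  # smoothness selection would otherwise inflate the type-I error.
  df1 <- df_age
  df2 <- n - edf_f
  if (rss_f <= 0) {
    p <- 0
  } else {
    Fstat <- max(0, (rss_r - rss_f) / df1) / (rss_f / df2)
    p <- pf(Fstat, df1, df2, lower.tail = FALSE)
  }
  direction <- if (sd(y) == 0 || abs(age_slope) < 1e-12 * (sd(y) + 1e-300)) {
    0
  } else {
    sign(age_slope)
  }
  if (is.na(delta)) delta <- 0  # constant response
  if (sd(y) == 0) p <- 1
  tibble(delta_r2_adj = delta,
         direction = direction,
         signed_effect = direction * max(delta, 0),
         p_value = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, monotone and capped at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length.
#' @export
fdr_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    abort("p-values must lie in [0, 1].")
  p.adjust(p_values, method = "BH")
}

#' Age effects for every parcel of a regional metric table
#'
#' Maps [age_effect()] over the parcels of a long metric table and applies
#' FDR correction across parcels.
#'
#' @param metric_table Long tibble from [regional_metric_table()].
#' @param cohort Cohort tibble (one row per subject) with `subject_id`, `age`,
#'   and the spec's covariates.
#' @param spec A [gam_spec()].
#' @return Tibble with one row per parcel: the [age_effect()] columns plus
#'   `parcel_id` and `q_value`. Parcels whose metric is missing for any
#'   subject (e.g. positive-only FC strength with no positive edges) are
#'   dropped with a warning.
#' @export
fit_age_effects <- function(metric_table, cohort, spec = gam_spec()) {
  wide <- metric_table %>%
    select("subject_id", "parcel_id", "value") %>%
    tidyr::pivot_wider(names_from = "parcel_id", values_from = "value")
  wide <- wide[match(cohort$subject_id, wide$subject_id), ]
  if (anyNA(wide$subject_id)) abort("metric table lacks some cohort subjects.")
  parcel_cols <- setdiff(names(wide), "subject_id")
  usable <- parcel_cols[vapply(parcel_cols, function(p) !anyNA(wide[[p]]), logical(1))]
  if (length(usable) < length(parcel_cols))
    warn(sprintf("dropping %d parcel(s) with missing metric values",
                 length(parcel_cols) - length(usable)))
  rows <- purrr::map(usable, function(p) {
    eff <- age_effect(cohort, wide[[p]], spec)
    eff$parcel_id <- as.integer(p)
    eff
  })
  out <- bind_rows(rows)
  out$q_value <- fdr_adjust(out$p_value)
  select(out, "parcel_id", dplyr::everything())
}

fitted_newdata <- function(fit, ages) {
  rng <- fit$age_range
  tol <- 1e-8 * diff(rng)
  if (any(ages < rng[1] - tol | ages > rng[2] + tol))
    abort(sprintf("extrapolation refused: ages must lie within [%.3f, %.3f].",
                  rng[1], rng[2]))
  nd <- data.frame(age = ages)
  for (v in names(fit$covariate_ref)) nd[[v]] <- fit$covariate_ref[[v]]
  nd
}

#' Model-predicted metric values along age
#'
#' Evaluates the fitted developmental trajectory at the requested ages with
#' covariates held at their sample means (binary covariates at the sample
#' proportion), i.e. the marginal age curve. Extrapolation beyond the
#' training age range is refused.
#'
#' @param fit A [fit_region_gam()] object.
#' @param ages Numeric vector of ages inside the training range.
#' @param center If `TRUE`, subtract the mean over the evaluation grid
#'   (zero-centered trajectory for plotting).
#' @return Tibble with `age` and `fitted` (plus `centered_fitted` when
#'   `center = TRUE`).
#' @export
fitted_values <- function(fit, ages, center = FALSE) {
  stopifnot(inherits(fit, "region_gam"))
  nd <- fitted_newdata(fit, ages)
  f <- as.numeric(predict(fit$fit, newdata = nd))
  out <- tibble(age = ages, fitted = f)
  if (center) out$centered_fitted <- f - mean(f)
  out
}

#' Posterior draws of the fitted age trajectory
#'
#' Samples coefficient vectors from the fit's Gaussian posterior (mean = the
#' estimates, covariance = the Bayesian posterior covariance conditional on
#' the smoothing parameter) and maps each through the model basis to a fitted
#' curve, covariates held as in [fitted_values()].
#'
#' @inheritParams fitted_values
#' @param n_draws Number of posterior draws (>= 1).
#' @param seed Integer seed for reproducibility; `NULL` leaves the RNG state
#'   untouched.
#' @return `n_draws` x `length(ages)` numeric matrix of fitted values.
#' @export
posterior_fitted_draws <- function(fit, ages, n_draws = 10000, seed = NULL) {
  stopifnot(inherits(fit, "region_gam"), n_draws >= 1)
  nd <- fitted_newdata(fit, ages)
  Xp <- predict(fit$fit, newdata = nd, type = "lpmatrix")
  V <- stats::vcov(fit$fit)
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    abort("posterior covariance is not positive semidefinite.")
  if (!is.null(seed)) set.seed(seed)
  B <- MASS::mvrnorm(n_draws, mu = coef(fit$fit), Sigma = V)
  if (n_draws == 1) B <- matrix(B, nrow = 1)
  B %*% t(Xp)
}

#' Tidy a regional age-model fit
#'
#' @param x A `region_gam` object.
#' @param ... Unused.
#' @return Tibble of coefficient estimates and posterior standard errors.
#' @export
tidy.region_gam <- function(x, ...) {
  co <- coef(x$fit)
  se <- sqrt(diag(stats::vcov(x$fit)))
  tibble(term = names(co), estimate = unname(co), std.error = unname(se))
}

#' One-row summary of a regional age-model fit
#'
#' @param x A `region_gam` object.
#' @param ... Unused.
#' @return One-row tibble: adjusted R-squared, smooth edf, smoothing
#'   parameter, sample size, and training age range.
#' @export
glance.region_gam <- function(x, ...) {
  tibble(r2_adj = x$r2_adj, edf = x$edf,
         lambda = if (is.null(x$lambda)) NA_real_ else x$lambda[1],
         n = x$n, age_min = x$age_range[1], age_max = x$age_range[2])
}
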