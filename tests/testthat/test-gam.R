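test_that("a noiseless linear trend is fit exactly with adjusted R^2 of 1", {
  co <- toy_cohort(n = 150, seed = 1)
  y <- 3 + 0.5 * co$age
  fit <- fit_region_gam(co, y)
  grid <- seq(6, 22, length.out = 25)
  fv <- fitted_values(fit, grid)
  expect_equal(fv$fitted, 3 + 0.5 * grid, tolerance = 1e-6)
  expect_lt(sum(resid(fit$fit)^2), 1e-12)
  expect_equal(fit$r2_adj, 1, tolerance = 1e-8)
})

test_that("a constant response yields a flat fit and a zero signed effect", {
  co <- toy_cohort(n = 120, seed = 2)
  y <- rep(2.5, 120)
  fit <- fit_region_gam(co, y)
  fv <- fitted_values(fit, c(8, 14, 22))
  expect_equal(fv$fitted, rep(2.5, 3), tolerance = 1e-8)
  eff <- age_effect(co, y)
  expect_identical(eff$direction, 0)
  expect_identical(eff$signed_effect, 0)
})

test_that("unpenalized fits match the explicit normal-equations solution", {
  for (s in 1:20) {
    co <- toy_cohort(n = 80, seed = 200 + s)
    y <- 0.2 * co$age + 0.5 * co$sex + rnorm(80, sd = 0.7)
    fit <- fit_region_gam(co, y, gam_spec(smoothing = "fixed", sp = 0))
    X <- model.matrix(fit$fit)
    beta <- solve(crossprod(X), crossprod(X, y))
    expect_lt(max(abs(coef(fit$fit) - beta)), 1e-8)
  }
})

test_that("an infinitely penalized smooth collapses to the ordinary linear fit", {
  co <- toy_cohort(n = 150, seed = 3)
  y <- 0.3 * co$age + 0.4 * co$sex - 0.8 * co$mean_fd + rnorm(150, sd = 0.5)
  fit <- fit_region_gam(co, y, gam_spec(smoothing = "fixed", sp = 1e12))
  ols <- lm(y ~ age + sex + mean_fd, data = cbind(co, y = y))
  grid <- seq(6, 22, length.out = 40)
  fv <- fitted_values(fit, grid)
  nd <- data.frame(age = grid, sex = mean(co$sex), mean_fd = mean(co$mean_fd))
  expect_lt(max(abs(fv$fitted - predict(ols, nd))), 1e-6)
})

test_that("smooth edf is monotone non-increasing in the smoothing parameter", {
  co <- toy_cohort(n = 200, seed = 4)
  y <- sin(co$age / 3) + rnorm(200, sd = 0.3)
  edfs <- sapply(10^seq(-3, 6, by = 1), function(sp) {
    fit_region_gam(co, y, gam_spec(smoothing = "fixed", sp = sp))$edf
  })
  expect_true(all(diff(edfs) <= 1e-8))
  expect_true(all(edfs >= 1 - 1e-6 & edfs <= 2 + 1e-6))  # k = 3 smooth
})

test_that("a strong linear age signal yields a near-total, positive effect", {
  set.seed(5)
  co <- toy_cohort(n = 200, seed = 5)
  y <- 2 * co$age + rnorm(200, sd = 0.5)
  eff <- age_effect(co, y)
  expect_gt(eff$delta_r2_adj, 0.95)
  expect_identical(eff$direction, 1)
  expect_lt(eff$p_value, 1e-10)
})

test_that("FDR adjustment follows the Benjamini-Hochberg step-up rule", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # q >= p always
  set.seed(6)
  p <- runif(50)
  expect_true(all(fdr_adjust(p) >= p))
})

test_that("fitted values refuse extrapolation and can be zero-centered", {
  co <- toy_cohort(n = 100, seed = 7)
  y <- 0.1 * co$age + rnorm(100, sd = 0.2)
  fit <- fit_region_gam(co, y)
  expect_error(fitted_values(fit, c(2, 10)), "extrapolation")
  expect_error(fitted_values(fit, 30), "extrapolation")
  fv <- fitted_values(fit, seq(6, 22, length.out = 11), center = TRUE)
  expect_equal(sum(fv$centered_fitted), 0, tolerance = 1e-10)
})

test_that("posterior draw means match fitted values within Monte Carlo error", {
  co <- toy_cohort(n = 200, seed = 8)
  y <- 0.2 * co$age + 0.5 * co$sex + rnorm(200, sd = 0.4)
  fit <- fit_region_gam(co, y)
  ages <- c(8, 14, 20)
  draws <- posterior_fitted_draws(fit, ages, n_draws = 5000, seed = 1)
  fv <- fitted_values(fit, ages)
  mc_se <- apply(draws, 2, sd) / sqrt(5000)
  expect_true(all(abs(colMeans(draws) - fv$fitted) < 3 * mc_se + 1e-8))
  # determinism
  draws2 <- posterior_fitted_draws(fit, ages, n_draws = 5000, seed = 1)
  expect_identical(draws, draws2)
})

test_that("posterior spread vanishes for a near-noiseless response", {
  co <- toy_cohort(n = 150, seed = 9)
  y <- 1 + 0.3 * co$age + rnorm(150, sd = 1e-5)
  fit <- fit_region_gam(co, y)
  draws <- posterior_fitted_draws(fit, c(10, 16), n_draws = 500, seed = 2)
  expect_lt(max(apply(draws, 2, sd)), 1e-4)
})

test_that("degenerate designs are rejected with clear errors", {
  co <- toy_cohort(n = 40, seed = 10)
  co$age <- rep(10, 40)
  expect_error(fit_region_gam(co, rnorm(40)), "unique ages")
  co2 <- toy_cohort(n = 40, seed = 11)
  co2$sex <- co2$mean_fd  # collinear covariates
  expect_error(fit_region_gam(co2, rnorm(40)), "rank-deficient")
})

test_that("tidy and glance return the expected broom-style summaries", {
  co <- toy_cohort(n = 100, seed = 12)
  y <- 0.1 * co$age + rnorm(100, sd = 0.3)
  fit <- fit_region_gam(co, y)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  expect_true(any(grepl("s\\(age\\)", td$term)))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$edf >= 1 && gl$edf <= 2 + 1e-6)
})

test_that("fit_age_effects maps regions, applies FDR, and keeps parcel ids", {
  px <- planted()
  eff <- px$effects
  expect_identical(nrow(eff), 100L)
  expect_true(all(eff$q_value >= eff$p_value))
  expect_true(all(eff$signed_effect[eff$direction == 0] == 0))
  # recovered directions match the planted truth for strong-effect parcels
  truth_dir <- truth_expected_effects(px$sim$truth, px$parc)
  joined <- merge(eff, truth_dir, by = "parcel_id")
  strong <- abs(joined$delta_r2_adj) > 0.1
  expect_gt(mean(joined$direction[strong] == joined$expected_direction[strong]),
            0.95)
})
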