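# small planted cohort shared by the edge tests
edge_fixture <- function() {
  memo("edge_fixture", {
    parc <- make_parcellation(10, n_networks = 2, seed = 4)
    sim <- simulate_cohort(parc, n_subjects = 80, n_timepoints = 120,
                           delta_max = 0.4, seed = 21)
    conn <- conn_stack(sim)
    effects <- edge_age_effects(conn, sim$cohort)
    list(parc = parc, sim = sim, conn = conn, effects = effects)
  })
}

test_that("edge effects cover every unordered pair exactly once", {
  fx <- edge_fixture()
  eff <- fx$effects
  expect_identical(nrow(eff), 45L)  # 10 choose 2
  expect_true(all(eff$parcel_i < eff$parcel_j))
  expect_identical(nrow(dplyr::distinct(eff, parcel_i, parcel_j)), 45L)
  expect_true(all(eff$q_value >= eff$p_value))
})

test_that("edge effects agree with the per-edge regional machinery", {
  fx <- edge_fixture()
  # recompute two edges through age_effect() directly
  for (k in c(1, 30)) {
    i <- fx$effects$parcel_i[k]; j <- fx$effects$parcel_j[k]
    y <- vapply(fx$conn, function(C) C[i, j], numeric(1))
    ref <- age_effect(fx$sim$cohort, unname(y))
    expect_equal(fx$effects$delta_r2_adj[k], ref$delta_r2_adj, tolerance = 1e-10)
    expect_equal(fx$effects$p_value[k], ref$p_value, tolerance = 1e-10)
    expect_identical(fx$effects$direction[k], ref$direction)
  }
})

test_that("planted edge signs follow the hierarchy: low-low up, low-high down", {
  fx <- edge_fixture()
  rank_of <- fx$parc$sa_rank
  low2 <- order(rank_of)[1:2]           # the two lowest-rank parcels
  hi <- order(rank_of)[10]              # the highest-rank parcel
  eff <- fx$effects
  pick <- function(a, b) {
    r <- eff[eff$parcel_i == min(a, b) & eff$parcel_j == max(a, b), ]
    r$direction
  }
  expect_identical(pick(low2[1], low2[2]), 1)
  expect_identical(pick(low2[1], hi), -1)
})

test_that("seed profiles index incident edges symmetrically", {
  fx <- edge_fixture()
  pr2 <- seed_profile(fx$effects, 2)
  expect_identical(nrow(pr2), 10L)
  expect_true(is.na(pr2$signed_effect[2]))
  expect_identical(sum(!is.na(pr2$signed_effect)), 9L)
  pr5 <- seed_profile(fx$effects, 5)
  expect_equal(pr2$signed_effect[5], pr5$signed_effect[2])
  expect_error(seed_profile(fx$effects, 99), "unknown parcel")
})

test_that("summing incident effects over all seeds double-counts each edge", {
  fx <- edge_fixture()
  total_incident <- sum(vapply(1:10, function(s)
    sum(seed_profile(fx$effects, s)$signed_effect, na.rm = TRUE), numeric(1)))
  expect_equal(total_incident, 2 * sum(fx$effects$signed_effect))
})

test_that("constant edge effects produce a flat surface", {
  pairs <- t(combn(10, 2))
  eff <- tibble::tibble(parcel_i = pairs[, 1], parcel_j = pairs[, 2],
                        signed_effect = 0.07)
  surf <- edge_rank_surface(eff, sample(10), grid_points = 20)
  expect_lt(max(abs(surf$matrix - 0.07)), 1e-6)
})

test_that("the rank surface is symmetric and rejects tiny grids", {
  fx <- edge_fixture()
  surf <- edge_rank_surface(fx$effects, fx$parc$sa_rank, grid_points = 25)
  expect_lt(max(abs(surf$matrix - t(surf$matrix))), 1e-8)
  expect_error(edge_rank_surface(fx$effects, fx$parc$sa_rank, grid_points = 5),
               ">= 10")
})

test_that("the surface recovers a known smooth bivariate signal", {
  set.seed(22)
  P <- 30
  pairs <- t(combn(P, 2))
  ranks <- sample(P)
  f <- function(a, b) 0.3 - 0.4 * ((a + b) / (2 * P)) # smooth in rank sum
  noise_sd <- 0.02
  eff <- tibble::tibble(
    parcel_i = pairs[, 1], parcel_j = pairs[, 2],
    signed_effect = f(ranks[pairs[, 1]], ranks[pairs[, 2]]) +
      rnorm(nrow(pairs), sd = noise_sd))
  surf <- edge_rank_surface(eff, ranks, grid_points = 30)
  truth <- outer(surf$axis_grid, surf$axis_grid, f)
  rmse <- sqrt(mean((surf$matrix - truth)^2))
  expect_lt(rmse, noise_sd)
})

test_that("regional effects cohere with the mean of incident edge effects", {
  fx <- edge_fixture()
  metrics <- regional_metric_table(fx$conn, fx$parc, "fc_strength")
  regional <- fit_age_effects(metrics, fx$sim$cohort)
  incident_mean <- vapply(1:10, function(s)
    mean(seed_profile(fx$effects, s)$signed_effect, na.rm = TRUE), numeric(1))
  expect_gt(cor(regional$signed_effect[order(regional$parcel_id)],
                incident_mean, method = "spearman"), 0.8)
})
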