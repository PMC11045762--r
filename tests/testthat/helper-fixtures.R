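# Shared fixtures, built once per test run and memoized.
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# small covariate table for GAM unit tests
toy_cohort <- function(n = 120, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    subject_id = sprintf("s%03d", seq_len(n)),
    age = runif(n, 5, 23),
    sex = rbinom(n, 1, 0.5),
    mean_fd = rlnorm(n, -2, 0.4)
  )
}

conn_stack <- function(sim) {
  conn <- lapply(split(sim$runs$ts, sim$runs$subject_id),
                 function(l) connectivity_matrix(concat_runs(l)))
  conn[sim$cohort$subject_id]
}

parc100 <- function() memo("parc100", make_parcellation(100, seed = 3))

# planted cohort at the default study conditions (P = 100, n = 300)
planted <- function() memo("planted", {
  parc <- parc100()
  sim <- simulate_cohort(parc, n_subjects = 300, seed = 3)
  conn <- conn_stack(sim)
  metrics <- regional_metric_table(conn, parc, "fc_strength")
  effects <- fit_age_effects(metrics, sim$cohort)
  list(parc = parc, sim = sim, conn = conn, metrics = metrics,
       effects = effects)
})

planted_fits <- function() memo("planted_fits", {
  px <- planted()
  wide <- tidyr::pivot_wider(px$metrics[, c("subject_id", "parcel_id", "value")],
                             names_from = "parcel_id", values_from = "value")
  wide <- wide[match(px$sim$cohort$subject_id, wide$subject_id), ]
  lapply(as.character(px$parc$parcel_id),
         function(p) fit_region_gam(px$sim$cohort, wide[[p]]))
})

planted_edges <- function() memo("planted_edges", {
  px <- planted()
  edge_age_effects(px$conn, px$sim$cohort)
})

# matched null cohort (no planted age effect)
null_cohort <- function() memo("null_cohort", {
  parc <- parc100()
  sim <- simulate_cohort(parc, n_subjects = 300, delta_max = 0, seed = 5)
  conn <- conn_stack(sim)
  metrics <- regional_metric_table(conn, parc, "fc_strength")
  effects <- fit_age_effects(metrics, sim$cohort)
  list(parc = parc, sim = sim, effects = effects)
})

random_symmetric_corr <- function(P, seed) {
  set.seed(seed)
  X <- matrix(rnorm((P + 5) * P), P + 5, P)
  cor(X)
}
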