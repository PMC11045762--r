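#' Configure a full analysis run
#'
#' Assembles and validates the configuration for [run_full_pipeline()].
#' Either a `simulate` stanza (a list of [simulate_cohort()] /
#' [make_parcellation()] arguments) or pre-built `cohort` + `runs` +
#' `parcellation` inputs must be supplied.
#'
#' @param simulate Optional list of generator settings: any of `n_parcels`,
#'   `hierarchy_smoothness`, `n_subjects`, `n_runs`, `n_timepoints`,
#'   `delta_max`, and other [simulate_cohort()] arguments.
#' @param cohort,runs,parcellation Pre-built inputs (ignored when `simulate`
#'   is given).
#' @param fd_threshold,min_minutes QC thresholds (mm, minutes).
#' @param k Smooth basis dimension for the age model.
#' @param n_rot Spin-test rotations.
#' @param n_draws Posterior draws for the age-resolved analysis.
#' @param grid_points Age-grid length for the age-resolved analysis.
#' @param variant FC-strength variant.
#' @param gsr Apply parcel-level global signal regression.
#' @param run_edges Also run the edge-level analysis (slower).
#' @param seed Master seed controlling every stochastic stage.
#' @param out_dir Optional directory; when given, all stage outputs are
#'   written as TSV plus a JSON manifest.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, cohort = NULL, runs = NULL,
                            parcellation = NULL, fd_threshold = 0.3,
                            min_minutes = 7, k = 3, n_rot = 1000,
                            n_draws = 2000, grid_points = 200,
                            variant = c("signed", "absolute", "positive_only"),
                            gsr = FALSE, run_edges = FALSE, seed = 1,
                            out_dir = NULL) {
  variant <- match.arg(variant)
  if (fd_threshold <= 0 || min_minutes <= 0)
    abort("thresholds must be positive.")
  if (is.null(simulate) && (is.null(cohort) || is.null(runs) || is.null(parcellation)))
    abort("invalid config: supply a `simulate` stanza or cohort + runs + parcellation.")
  structure(list(simulate = simulate, cohort = cohort, runs = runs,
                 parcellation = parcellation, fd_threshold = fd_threshold,
                 min_minutes = min_minutes, k = k, n_rot = n_rot,
                 n_draws = n_draws, grid_points = grid_points,
                 variant = variant, gsr = gsr, run_edges = run_edges,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full connectivity-development pipeline
#'
#' Orchestrates every stage on one cohort: quality control, run
#' concatenation, connectivity matrices, regional FC-strength metrics,
#' per-region age models with FDR, axis-alignment spin test, the
#' age-resolved alignment trajectory, and (optionally) the edge-level
#' analysis with its rank-surface summary. Identical configuration and seed
#' give identical numerical outputs.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result` with the per-stage outputs
#'   (`parcellation`, `cohort`, `qc`, `conn`, `metrics`, `effects`,
#'   `alignment`, `age_resolved`, `edges`, `surface`, `truth`) and a
#'   `manifest` recording the configuration, package version, subject counts
#'   before/after each exclusion stage, and files written (if `out_dir` was
#'   set).
#' @export
run_full_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    abort("`config` must come from pipeline_config().")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e))))
  }

  truth <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    parc_args <- sim_args[intersect(names(sim_args),
                                    names(formals(make_parcellation)))]
    parc_args$seed <- config$seed
    parcellation <- stage("simulate", do.call(make_parcellation, parc_args))
    cargs <- sim_args[intersect(names(sim_args), names(formals(simulate_cohort)))]
    cargs$parcellation <- parcellation
    cargs$seed <- config$seed + 1L
    sim <- stage("simulate", do.call(simulate_cohort, cargs))
    cohort <- sim$cohort
    runs <- sim$runs
    truth <- sim$truth
  } else {
    parcellation <- config$parcellation
    cohort <- config$cohort
    runs <- config$runs
  }
  validate_parcellation(parcellation)
  n_input <- length(unique(runs$subject_id))

  qc <- stage("qc", qc_filter(runs, config$fd_threshold, config$min_minutes))
  retained_subjects <- unique(qc$retained$subject_id)
  cohort_kept <- filter(cohort, .data$subject_id %in% retained_subjects)
  # motion covariate: mean FD averaged over the retained runs only
  fd_kept <- qc$retained %>%
    group_by(.data$subject_id) %>%
    summarise(mean_fd = mean(.data$mean_fd), .groups = "drop")
  cohort_kept <- cohort_kept %>%
    select(-"mean_fd") %>%
    left_join(fd_kept, by = "subject_id")

  conn <- stage("connectivity", {
    by_subj <- split(qc$retained$ts, qc$retained$subject_id)
    lapply(by_subj, function(ts_list) {
      connectivity_matrix(concat_runs(ts_list, "zscore_per_run"),
                          gsr = config$gsr)
    })
  })
  conn <- conn[cohort_kept$subject_id]

  spec <- gam_spec(k = config$k)
  metrics <- stage("metrics",
    regional_metric_table(conn, parcellation, "fc_strength", config$variant))
  effects <- stage("gam", fit_age_effects(metrics, cohort_kept, spec))

  eff_map <- effects$signed_effect[match(parcellation$parcel_id, effects$parcel_id)]
  perms <- stage("alignment",
    generate_spin_permutations(parcellation, config$n_rot, seed = config$seed + 2L))
  alignment <- stage("alignment",
    spin_test_correlation(eff_map, parcellation$sa_rank, perms, "spearman"))

  age_resolved <- stage("age_resolved", {
    wide <- metrics %>%
      select("subject_id", "parcel_id", "value") %>%
      tidyr::pivot_wider(names_from = "parcel_id", values_from = "value")
    wide <- wide[match(cohort_kept$subject_id, wide$subject_id), ]
    fits <- lapply(as.character(parcellation$parcel_id), function(p)
      fit_region_gam(cohort_kept, wide[[p]], spec))
    age_resolved_alignment(fits, parcellation$sa_rank,
                           n_draws = config$n_draws,
                           grid_points = config$grid_points,
                           seed = config$seed + 3L)
  })

  edges <- surface <- NULL
  if (config$run_edges) {
    edges <- stage("edges", edge_age_effects(conn, cohort_kept, spec))
    surface <- stage("edges",
      edge_rank_surface(edges,
                        parcellation$sa_rank[order(parcellation$parcel_id)]))
  }

  motion_kept_runs <- runs %>%
    filter(.data$mean_fd < config$fd_threshold)
  counts <- tibble(
    stage = c("input", "after_motion", "after_scan_time"),
    n_subjects = c(n_input,
                   length(unique(motion_kept_runs$subject_id)),
                   length(retained_subjects)))

  manifest <- list(
    config = config[setdiff(names(config), c("cohort", "runs", "parcellation"))],
    package_version = as.character(utils::packageVersion("saxdev")),
    subject_counts = counts,
    exclusions = qc$exclusions,
    files = character(0)
  )

  result <- structure(list(
    parcellation = parcellation, cohort = cohort_kept, qc = qc, conn = conn,
    metrics = metrics, effects = effects, alignment = alignment,
    age_resolved = age_resolved, edges = edges, surface = surface,
    truth = truth, manifest = manifest), class = "pipeline_result")

  if (!is.null(config$out_dir))
    result$manifest$files <- write_pipeline_outputs(result, config$out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d subjects x %d parcels\n",
              nrow(x$cohort), nrow(x$parcellation)))
  cat(sprintf("  alignment: r = %.3f (%s), p_spin = %.4g (%d rotations)\n",
              x$alignment$r, x$alignment$method, x$alignment$p_spin,
              x$alignment$n_rot))
  sig <- mean(x$effects$q_value < 0.05)
  cat(sprintf("  regions with Q < 0.05: %.1f%%\n", 100 * sig))
  invisible(x)
}

#' Write pipeline outputs as TSV files plus a JSON manifest
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of files written.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    participants = file.path(out_dir, "participants.tsv"),
    parcels = file.path(out_dir, "parcels.tsv"),
    effects = file.path(out_dir, "age_effects.tsv"),
    alignment = file.path(out_dir, "alignment.tsv"),
    age_resolved = file.path(out_dir, "age_resolved.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  readr::write_tsv(select(result$cohort, -dplyr::any_of("run_durations")),
                   paths["participants"])
  readr::write_tsv(result$parcellation, paths["parcels"])
  readr::write_tsv(result$effects, paths["effects"])
  readr::write_tsv(result$alignment, paths["alignment"])
  readr::write_tsv(result$age_resolved, paths["age_resolved"])
  if (!is.null(result$edges)) {
    paths["edges"] <- file.path(out_dir, "edge_effects.tsv")
    readr::write_tsv(result$edges, paths["edges"])
    paths["surface"] <- file.path(out_dir, "rank_surface.tsv")
    readr::write_tsv(result$surface$grid, paths["surface"])
  }
  manifest <- result$manifest
  manifest$files <- unname(paths)
  manifest$config$out_dir <- NULL
  jsonlite::write_json(
    list(package_version = manifest$package_version,
         subject_counts = manifest$subject_counts,
         n_exclusions = nrow(manifest$exclusions),
         files = manifest$files),
    paths["manifest"], auto_unbox = TRUE, digits = NA)
  unname(paths)
}
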