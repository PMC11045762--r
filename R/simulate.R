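#' Construct a single-run parcellated timeseries object
#'
#' Light container for one run of parcellated BOLD-like data: a T x P numeric
#' matrix with subject, run, and repetition-time metadata attached.
#'
#' @param data T x P numeric matrix (rows = timepoints, columns = parcels).
#' @param subject_id,run_id Identifiers.
#' @param tr Repetition time in seconds.
#' @return An object of class `run_timeseries`.
#' @export
run_timeseries <- function(data, subject_id, run_id, tr = 3) {
  data <- as.matrix(data)
  if (nrow(data) < 2) abort("a run needs at least 2 timepoints.")
  if (anyNA(data)) abort("timeseries must not contain missing values.")
  structure(list(data = data, subject_id = subject_id, run_id = run_id, tr = tr),
            class = "run_timeseries")
}

#' @export
print.run_timeseries <- function(x, ...) {
  cat(sprintf("<run_timeseries> subject %s, run %s: %d timepoints x %d parcels (TR %gs)\n",
              x$subject_id, x$run_id, nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

#' Simulate a developmental cohort with axis-aligned connectivity effects
#'
#' Generates a cross-sectional cohort of subjects aged uniformly on
#' `age_range`, each with multi-run parcellated timeseries whose correlation
#' structure carries a planted, hierarchically organized age effect. Parcel
#' `p`'s signal is a factor model
#' \deqn{x_p(t) = w_p(s)\,g(t) + u_0 f_{net(p)}(t) + \sigma_s\,\epsilon_p(t)}
#' with a cortex-wide shared factor `g`, one factor per network, and white
#' noise. The shared-factor loading drifts linearly with age from a common
#' baseline at birth, \eqn{w_p(s) = w_0 + \delta_p\, age_s / age_{max}}, so
#' the hierarchical gradient in connectivity accumulates over development:
#' partial differentiation has already built up by the youngest observed age
#' and keeps strengthening to the oldest — the developmental phenomenon the
#' pipeline is built to detect. The planted slope decreases strictly along
#' the S-A axis,
#' \eqn{\delta_p = \delta_{max} (1 - 2 (rank_p - 1)/(P - 1))}: connectivity
#' involving sensorimotor-pole parcels strengthens with age while the
#' association pole weakens. Head motion (mean framewise displacement) is
#' drawn from a lognormal whose median decreases with age, and inflates the
#' noise scale multiplicatively, reproducing the usual age-motion confound.
#'
#' @param parcellation Tibble from [make_parcellation()].
#' @param n_subjects Number of subjects (>= 20).
#' @param n_runs Runs per subject; run 1 is labelled `"rest"`, later runs
#'   `"task1"`, `"task2"`, ...
#' @param n_timepoints Timepoints per run (>= 50).
#' @param delta_max Maximum planted age slope of the shared-factor loading;
#'   0 yields a null cohort with no age effect.
#' @param w0 Baseline shared-factor loading.
#' @param u0 Network-factor loading.
#' @param sigma Baseline noise scale.
#' @param fd_gain Multiplicative noise inflation per mm of mean FD.
#' @param age_range Two-vector of ages in years.
#' @param tr Repetition time, seconds.
#' @param seed Integer seed; identical arguments and seed give bit-identical
#'   output.
#'
#' @return A list with elements:
#' \describe{
#'   \item{cohort}{tibble: `subject_id`, `age`, `sex` (0/1), `mean_fd`
#'     (subject average, mm), `site`, `run_durations` (minutes, list-column).}
#'   \item{runs}{tibble of per-run records: `subject_id`, `run_id`,
#'     `mean_fd`, `duration_min`, and the run's [run_timeseries()] object in
#'     list-column `ts`.}
#'   \item{truth}{list of class `truth_record`: planted `delta` per parcel,
#'     `w0`, `u0`, `sigma`, and `expected_alignment`, the Spearman
#'     correlation between the planted signed effect and `sa_rank` (-1
#'     whenever `delta_max > 0`, 0 for the null cohort).}
#' }
#' @export
simulate_cohort <- function(parcellation, n_subjects = 300, n_runs = 2,
                            n_timepoints = 200, delta_max = 0.3, w0 = 0.5,
                            u0 = 0.5, sigma = 1, fd_gain = 1,
                            age_range = c(5, 23), tr = 3, seed = 1) {
  validate_parcellation(parcellation)
  if (n_subjects < 20) abort("`n_subjects` must be >= 20.")
  if (n_timepoints < 50) abort("`n_timepoints` must be >= 50.")
  if (delta_max < 0) abort("`delta_max` must be >= 0 (0 gives a null cohort).")
  P <- nrow(parcellation)
  rank_p <- parcellation$sa_rank
  delta <- delta_max * (1 - 2 * (rank_p - 1) / (P - 1))
  net_idx <- as.integer(parcellation$network)
  n_nets <- nlevels(parcellation$network)
  age_mid <- mean(age_range)
  age_half <- diff(age_range) / 2

  set.seed(seed)
  age <- runif(n_subjects, age_range[1], age_range[2])
  sex <- rbinom(n_subjects, 1, 0.5)
  # motion: lognormal, median falling from ~0.17 mm at the youngest age to
  # ~0.08 mm at the oldest; right-skewed as empirical FD distributions are
  fd_run <- matrix(rlnorm(n_subjects * n_runs,
                          meanlog = log(0.12) - 0.4 * rep((age - age_mid) / age_half, n_runs),
                          sdlog = 0.45),
                   nrow = n_subjects)
  mean_fd <- rowMeans(fd_run)
  subject_id <- sprintf("sub-%04d", seq_len(n_subjects))

  run_labels <- c("rest", if (n_runs > 1) paste0("task", seq_len(n_runs - 1)))
  run_rows <- vector("list", n_subjects * n_runs)
  k <- 0L
  for (s in seq_len(n_subjects)) {
    w_s <- w0 + delta * age[s] / age_range[2]
    for (r in seq_len(n_runs)) {
      g <- rnorm(n_timepoints)
      f <- matrix(rnorm(n_timepoints * n_nets), n_timepoints, n_nets)
      eps <- matrix(rnorm(n_timepoints * P), n_timepoints, P)
      s_noise <- sigma * (1 + fd_gain * fd_run[s, r])
      X <- g %*% t(w_s) + f[, net_idx, drop = FALSE] * u0 + s_noise * eps
      colnames(X) <- parcellation$label
      k <- k + 1L
      run_rows[[k]] <- tibble(
        subject_id = subject_id[s], run_id = run_labels[r],
        mean_fd = fd_run[s, r], duration_min = n_timepoints * tr / 60,
        ts = list(run_timeseries(X, subject_id[s], run_labels[r], tr = tr))
      )
    }
  }
  runs <- bind_rows(run_rows)

  cohort <- tibble(
    subject_id = subject_id, age = age, sex = sex, mean_fd = mean_fd,
    site = "synthetic",
    run_durations = rep(list(rep(n_timepoints * tr / 60, n_runs)), n_subjects)
  )

  expected_alignment <- if (delta_max > 0) -1 else 0
  truth <- structure(
    list(delta = delta, w0 = w0, u0 = u0, sigma = sigma,
         delta_max = delta_max, expected_alignment = expected_alignment),
    class = "truth_record")

  list(cohort = cohort, runs = runs, truth = truth)
}

#' Expected per-parcel age-effect directions from a planted truth record
#'
#' The recovery oracle: the sign of the planted shared-factor loading slope
#' per parcel, the direction in which each parcel's connectivity is expected
#' to change with age.
#'
#' @param truth A `truth_record` from [simulate_cohort()].
#' @param parcellation The matching parcellation tibble.
#' @return Tibble with `parcel_id`, `sa_rank`, and `expected_direction`
#'   (-1, 0, +1).
#' @export
truth_expected_effects <- function(truth, parcellation) {
  if (!inherits(truth, "truth_record")) abort("`truth` must be a truth_record.")
  validate_parcellation(parcellation)
  if (length(truth$delta) != nrow(parcellation))
    abort("truth and parcellation disagree on parcel count.")
  tibble(parcel_id = parcellation$parcel_id,
         sa_rank = parcellation$sa_rank,
         expected_direction = sign(truth$delta))
}
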