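#' Concatenate runs of parcellated timeseries
#'
#' Stacks the runs of one subject in time. Under the default
#' `"zscore_per_run"` policy each parcel column of each run is standardized
#' (mean 0, unit variance) before stacking, so runs of unequal amplitude
#' contribute equally to the concatenated correlation structure.
#'
#' @param runs List of [run_timeseries()] objects from one subject, all with
#'   the same parcel count.
#' @param policy `"zscore_per_run"` or `"none"`.
#' @return A single [run_timeseries()] with `run_id = "concat"` and total
#'   timepoints equal to the sum over runs.
#' @export
concat_runs <- function(runs, policy = c("zscore_per_run", "none")) {
  policy <- match.arg(policy)
  if (inherits(runs, "run_timeseries")) runs <- list(runs)
  if (!length(runs)) abort("`runs` must contain at least one run.")
  P <- ncol(runs[[1]]$data)
  subj <- runs[[1]]$subject_id
  for (r in runs) {
    if (!inherits(r, "run_timeseries")) abort("every element must be a run_timeseries.")
    if (ncol(r$data) != P) abort("runs have mismatched parcel counts.")
    if (!identical(r$subject_id, subj)) abort("runs belong to different subjects.")
  }
  if (length(runs) == 1 && policy == "none") return(runs[[1]])
  mats <- lapply(runs, function(r) {
    X <- r$data
    if (policy == "zscore_per_run") X <- scale(X)[, , drop = FALSE]
    X
  })
  run_timeseries(do.call(rbind, mats), subj, "concat", tr = runs[[1]]$tr)
}

#' Pearson connectivity matrix from a timeseries
#'
#' Computes the P x P matrix of sample Pearson correlations between parcel
#' timeseries. With `gsr = TRUE`, a parcel-level analogue of global signal
#' regression is applied first: the cross-parcel mean timecourse is regressed
#' out of every column.
#'
#' @param ts A [run_timeseries()] (typically concatenated).
#' @param gsr Logical; regress out the global (cross-parcel mean) signal.
#' @return A symmetric P x P correlation matrix with unit diagonal and the
#'   parcel labels as dimnames.
#' @export
connectivity_matrix <- function(ts, gsr = FALSE) {
  if (!inherits(ts, "run_timeseries")) abort("`ts` must be a run_timeseries.")
  X <- ts$data
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(X)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    abort(paste0("zero-variance parcel column(s): ", paste(bad, collapse = ", ")))
  }
  if (gsr) {
    g <- rowMeans(X)
    X <- apply(X, 2, function(col) lm.fit.quick(g, col)$residuals)
    sds <- apply(X, 2, sd)
    if (any(sds == 0)) abort("global signal regression left a zero-variance column.")
  }
  C <- cor(X)
  dimnames(C) <- list(colnames(ts$data), colnames(ts$data))
  C
}

# simple-regression residuals of y on (1, g); avoids lm() overhead in loops
lm.fit.quick <- function(g, y) {
  gc_ <- g - mean(g)
  b <- sum(gc_ * y) / sum(gc_^2)
  list(residuals = y - mean(y) - b * gc_)
}

#' Regional FC strength from a connectivity matrix
#'
#' FC strength for a parcel is the mean edge strength between that parcel and
#' every other parcel, without thresholding (variant `"signed"`). Sensitivity
#' variants: `"absolute"` averages |r|; `"positive_only"` averages only the
#' strictly positive edges of the row (NA when a parcel has none).
#'
#' @param conn P x P connectivity matrix.
#' @param variant `"signed"`, `"absolute"`, or `"positive_only"`.
#' @return Named numeric vector of length P.
#' @export
fc_strength <- function(conn, variant = c("signed", "absolute", "positive_only")) {
  variant <- match.arg(variant)
  stopifnot(is.matrix(conn), nrow(conn) == ncol(conn))
  P <- nrow(conn)
  off <- conn
  diag(off) <- NA
  out <- switch(variant,
    signed = rowMeans(off, na.rm = TRUE),
    absolute = rowMeans(abs(off), na.rm = TRUE),
    positive_only = apply(off, 1, function(r) {
      pos <- r[!is.na(r) & r > 0]
      if (!length(pos)) NA_real_ else mean(pos)
    })
  )
  names(out) <- rownames(conn)
  out
}

#' Between- and within-network decomposition of regional connectivity
#'
#' Splits each parcel's edges into those leaving its functional network
#' (between-network connectivity: mean edge strength to all parcels outside
#' the network) and those staying inside (within-network connectivity). Also
#' returns the network-pair mean connectivity matrix, whose diagonal holds
#' each network's mean internal edge. The decomposition satisfies the exact
#' identity `fc_strength = ((n_within - 1) * within + n_between * between) / (P - 1)`.
#'
#' @param conn P x P connectivity matrix.
#' @param parcellation Parcellation tibble aligned with `conn`'s row order.
#' @return List with `regional` (tibble: `parcel_id`, `within`, `between`;
#'   `within` is NA for singleton networks) and `pairs` (N x N symmetric
#'   matrix of network-pair mean edges).
#' @export
network_decomposition <- function(conn, parcellation) {
  validate_parcellation(parcellation)
  network_decomposition_unchecked(conn, parcellation)
}

# computation core without parcellation validation (usable on fragments)
network_decomposition_unchecked <- function(conn, parcellation) {
  P <- nrow(conn)
  if (P != nrow(parcellation)) abort("matrix and parcellation disagree on P.")
  nets <- as.character(parcellation$network)
  levs <- levels(parcellation$network)
  off <- conn
  diag(off) <- NA

  within <- between <- numeric(P)
  for (i in seq_len(P)) {
    same <- nets == nets[i]
    same[i] <- FALSE
    within[i] <- if (any(same)) mean(off[i, same]) else NA_real_
    between[i] <- mean(off[i, !same & seq_len(P) != i])
  }

  N <- length(levs)
  pairs <- matrix(NA_real_, N, N, dimnames = list(levs, levs))
  for (a in seq_len(N)) for (b in seq_len(a)) {
    ia <- which(nets == levs[a]); ib <- which(nets == levs[b])
    block <- off[ia, ib, drop = FALSE]
    v <- mean(block, na.rm = a == b)
    if (a == b && all(is.na(block))) v <- NA_real_
    pairs[a, b] <- pairs[b, a] <- v
  }

  list(regional = tibble(parcel_id = parcellation$parcel_id,
                         within = within, between = between),
       pairs = pairs)
}

#' Long-format regional metric table for a stack of subjects
#'
#' Applies [fc_strength()] or [network_decomposition()] to each subject's
#' connectivity matrix and assembles the long table downstream models consume.
#'
#' @param conn_list Named list of P x P matrices (names = subject ids).
#' @param parcellation Parcellation tibble.
#' @param metric `"fc_strength"`, `"between_net"`, or `"within_net"`.
#' @param variant FC-strength variant (ignored for network metrics, which are
#'   always signed).
#' @return Tibble: `subject_id`, `parcel_id`, `metric`, `variant`, `value`.
#' @export
regional_metric_table <- function(conn_list, parcellation,
                                  metric = c("fc_strength", "between_net", "within_net"),
                                  variant = c("signed", "absolute", "positive_only")) {
  metric <- match.arg(metric)
  variant <- match.arg(variant)
  if (is.null(names(conn_list))) abort("`conn_list` must be named by subject id.")
  rows <- purrr::imap(conn_list, function(conn, sid) {
    vals <- if (metric == "fc_strength") {
      unname(fc_strength(conn, variant))
    } else {
      dec <- network_decomposition(conn, parcellation)
      if (metric == "within_net") dec$regional$within else dec$regional$between
    }
    variant_out <- if (metric == "fc_strength") variant else "signed"
    tibble(subject_id = sid, parcel_id = parcellation$parcel_id,
           metric = metric, variant = variant_out, value = vals)
  })
  bind_rows(rows)
}
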