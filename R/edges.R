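#' Per-edge age effects across a stack of connectivity matrices
#'
#' Applies the regional age-effect machinery to every unordered parcel pair:
#' the edge's per-subject correlation values are modeled with the same
#' penalized-spline age model, giving a signed delta adjusted-R-squared, an
#' approximate F p-value, and FDR-corrected q-values across all
#' P(P-1)/2 edges. The reduced (no-age) model and the linear direction model
#' share their design across edges and are solved in one pass; the full
#' penalized fit is per edge.
#'
#' @param conn_list Named list of P x P connectivity matrices, one per
#'   subject, in cohort order.
#' @param cohort Cohort tibble with `subject_id`, `age`, and the spec's
#'   covariates.
#' @param spec A [gam_spec()].
#' @return Tibble with one row per edge (`parcel_i < parcel_j`):
#'   `parcel_i`, `parcel_j`, `delta_r2_adj`, `direction`, `signed_effect`,
#'   `p_value`, `q_value`.
#' @export
edge_age_effects <- function(conn_list, cohort, spec = gam_spec()) {
  if (is.null(names(conn_list))) abort("`conn_list` must be named by subject id.")
  conn_list <- conn_list[cohort$subject_id]
  if (any(vapply(conn_list, is.null, logical(1))))
    abort("`conn_list` lacks matrices for some cohort subjects.")
  P <- nrow(conn_list[[1]])
  lower <- which(lower.tri(matrix(0, P, P)))
  pair_j <- ((lower - 1) %/% P) + 1  # column index (smaller id)
  pair_i <- ((lower - 1) %% P) + 1   # row index (larger id)
  E <- t(vapply(conn_list, function(C) {
    if (nrow(C) != P) abort("inconsistent parcel counts across subjects.")
    C[lower]
  }, numeric(length(lower))))

  df <- as.data.frame(cohort[, c("age", spec$covariates), drop = FALSE])
  df$y <- 0
  check_design(df, spec)
  n <- nrow(df)

  X_red <- model.matrix(stats::as.formula(
    paste("~", paste(spec$covariates, collapse = " + "))), df)
  X_lin <- model.matrix(stats::as.formula(
    paste("~", paste(c("age", spec$covariates), collapse = " + "))), df)
  qr_red <- qr(X_red)
  qr_lin <- qr(X_lin)
  rss_red <- colSums(qr.resid(qr_red, E)^2)
  age_slopes <- qr.coef(qr_lin, E)["age", ]

  form <- gam_formula(spec)
  rows <- vector("list", ncol(E))
  for (e in seq_len(ncol(E))) {
    y <- E[, e]
    df$y <- y
    fit <- switch(spec$smoothing,
      reml = mgcv::gam(form, data = df, method = "REML"),
      gcv = mgcv::gam(form, data = df, method = "GCV.Cp"),
      fixed = mgcv::gam(form, data = df, sp = spec$sp))
    rows[[e]] <- age_effect_from_parts(
      y, sum(resid(fit)^2), rss_red[e], sum(fit$edf), ncol(X_red), n,
      age_slopes[e], df_age = spec$k - 1)
  }
  out <- bind_rows(rows)
  out$parcel_i <- pmin(pair_i, pair_j)
  out$parcel_j <- pmax(pair_i, pair_j)
  out$q_value <- fdr_adjust(out$p_value)
  select(out, "parcel_i", "parcel_j", dplyr::everything())
}

#' Smooth topography of edge age effects over pairs of axis ranks
#'
#' Summarizes edge-level developmental effects as a penalized tensor-product
#' smooth surface over the S-A ranks of the two endpoint parcels,
#' `signed_effect ~ te(rank_1, rank_2)`. Every edge contributes both
#' orderings of its endpoints so the fitted surface is symmetric; it is
#' evaluated on a `grid_points` x `grid_points` grid spanning `[1, P]^2`.
#'
#' @param effects Edge-effect tibble from [edge_age_effects()].
#' @param axis_ranks Integer vector of S-A ranks indexed by parcel id.
#' @param grid_points Evaluation grid size per margin (>= 10, default 100).
#' @param k_margin Marginal basis dimension of the tensor smooth (default 5).
#' @return List of class `rank_surface`: `grid` (long tibble `rank_1`,
#'   `rank_2`, `fitted`), `matrix` (the G x G fitted surface), and the mgcv
#'   fit in `fit`.
#' @export
edge_rank_surface <- function(effects, axis_ranks, grid_points = 100,
                              k_margin = 5) {
  if (grid_points < 10) abort("`grid_points` must be >= 10.")
  P <- length(axis_ranks)
  if (max(effects$parcel_j) > P) abort("effects reference parcels beyond the axis.")
  dat <- tibble(
    r1 = c(axis_ranks[effects$parcel_i], axis_ranks[effects$parcel_j]),
    r2 = c(axis_ranks[effects$parcel_j], axis_ranks[effects$parcel_i]),
    effect = rep(effects$signed_effect, 2)
  )
  fit <- if (sd(dat$effect) == 0) {
    # constant response: smoothness selection is vacuous, pin the penalties
    mgcv::gam(effect ~ te(r1, r2, k = c(k_margin, k_margin)),
              data = dat, sp = c(1, 1))
  } else {
    mgcv::gam(effect ~ te(r1, r2, k = c(k_margin, k_margin)),
              data = dat, method = "REML")
  }
  g <- seq(1, P, length.out = grid_points)
  nd <- expand.grid(r1 = g, r2 = g)
  z <- matrix(as.numeric(predict(fit, newdata = nd)), grid_points, grid_points)
  grid_tbl <- tibble(rank_1 = nd$r1, rank_2 = nd$r2, fitted = as.numeric(z))
  structure(list(grid = grid_tbl, matrix = z, axis_grid = g, fit = fit),
            class = "rank_surface")
}

#' @export
print.rank_surface <- function(x, ...) {
  cat(sprintf("<rank_surface> %d x %d grid over ranks [%g, %g]; fitted range [%.4f, %.4f]\n",
              nrow(x$matrix), ncol(x$matrix), min(x$axis_grid), max(x$axis_grid),
              min(x$matrix), max(x$matrix)))
  invisible(x)
}

#' Seed-based profile of edge age effects
#'
#' Extracts the signed age effects of all edges incident to one seed parcel,
#' indexed by the partner parcel; the seed's own entry is `NA`.
#'
#' @param effects Edge-effect tibble from [edge_age_effects()].
#' @param seed_parcel Parcel id of the seed region.
#' @return Tibble with `parcel_id` (partner) and `signed_effect` for all P
#'   parcels (seed row `NA`).
#' @export
seed_profile <- function(effects, seed_parcel) {
  P <- max(effects$parcel_j)
  if (!(seed_parcel %in% seq_len(P)))
    abort(sprintf("unknown parcel id %s.", seed_parcel))
  inc <- filter(effects, .data$parcel_i == seed_parcel | .data$parcel_j == seed_parcel)
  partner <- ifelse(inc$parcel_i == seed_parcel, inc$parcel_j, inc$parcel_i)
  vals <- rep(NA_real_, P)
  vals[partner] <- inc$signed_effect
  tibble(parcel_id = seq_len(P), signed_effect = vals)
}
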