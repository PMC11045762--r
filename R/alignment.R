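#' Generate hemisphere-locked spherical rotation permutations
#'
#' Builds the index maps of a spin-based spatial permutation test. For each
#' rotation a uniformly random 3x3 rotation matrix is applied to the
#' left-hemisphere centroids and its x-mirrored counterpart to the right, so
#' homologous geometry is preserved; each rotated centroid is then assigned
#' the nearest original centroid of the same hemisphere (many-to-one allowed).
#' Permuting a map by a row of the result preserves its spatial
#' autocorrelation structure while breaking its alignment with any other map.
#'
#' @param parcellation Parcellation tibble with unit-sphere centroids and
#'   hemisphere labels.
#' @param n_rot Number of rotations.
#' @param seed Integer seed; the same inputs always give identical output.
#' @return Object of class `spin_perms`: integer `indices` (`n_rot` x P, each
#'   row an index map into the original parcels), plus `n_rot`, `seed`, and
#'   `hemisphere_locked = TRUE`.
#' @export
generate_spin_permutations <- function(parcellation, n_rot = 1000, seed = 1) {
  validate_parcellation(parcellation)
  P <- nrow(parcellation)
  coords <- as.matrix(parcellation[, c("x", "y", "z")])
  dup <- duplicated(round(coords, 12))
  if (any(dup)) abort("degenerate geometry: coincident centroids.")
  hemi <- parcellation$hemisphere
  idx_L <- which(hemi == "L")
  idx_R <- which(hemi == "R")
  CL <- coords[idx_L, , drop = FALSE]
  CR <- coords[idx_R, , drop = FALSE]
  M <- diag(c(-1, 1, 1))

  set.seed(seed)
  indices <- matrix(NA_integer_, n_rot, P)
  identity_row <- seq_len(P)
  for (i in seq_len(n_rot)) {
    # on a coarse lattice a very small random rotation can collapse to the
    # exact identity reassignment; the identity arrangement is already
    # accounted for by the +1 in the permutation p-value, so such draws are
    # redrawn rather than double-counted in the null
    for (try in 1:100) {
      R <- random_rotation()
      RL <- CL %*% t(R)
      RR <- CR %*% t(M %*% R %*% M)
      row <- integer(P)
      row[idx_L] <- idx_L[nearest_index(RL, CL)]
      row[idx_R] <- idx_R[nearest_index(RR, CR)]
      if (!identical(row, identity_row)) break
    }
    indices[i, ] <- row
  }
  structure(list(indices = indices, n_rot = n_rot, seed = seed,
                 hemisphere_locked = TRUE),
            class = "spin_perms")
}

# uniform random rotation (QR of a Gaussian matrix, sign-fixed, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

# row-wise nearest neighbour of `rotated` among `originals` (unit vectors:
# maximal dot product = minimal chordal distance)
nearest_index <- function(rotated, originals) {
  max.col(rotated %*% t(originals), ties.method = "first")
}

#' @export
print.spin_perms <- function(x, ...) {
  cat(sprintf("<spin_perms> %d rotations over %d parcels (seed %d, hemisphere-locked)\n",
              x$n_rot, ncol(x$indices), x$seed))
  invisible(x)
}

#' Spatial correlation of two parcel maps with a spin-test p-value
#'
#' Correlates two per-parcel maps and assesses significance against a
#' spatial-autocorrelation-preserving null built by rotating one of the maps
#' (by default `map_b`, intended to be the axis) with precomputed spin
#' permutations. The two-sided permutation p-value is
#' `(1 + #\{|r_null| >= |r_obs|\}) / (n_rot + 1)`, so its attainable floor at
#' 10,000 rotations is 1/10,001, which rounds to 0.0001.
#'
#' @param map_a,map_b Numeric vectors of length P (parcel order must match
#'   the parcellation used to build `perms`).
#' @param perms A [generate_spin_permutations()] object.
#' @param method `"spearman"` (default, used for axis alignment) or
#'   `"pearson"` (used for map-vs-map comparisons).
#' @param rotate Which map the null rotates: `"map_b"` (default) or
#'   `"map_a"`.
#' @return One-row tibble: `r`, `p_spin`, `method`, `n_rot`; the null
#'   distribution's mean, sd and quantiles are in attribute `"null_summary"`,
#'   the raw null correlations in `"null_r"`.
#' @export
spin_test_correlation <- function(map_a, map_b, perms,
                                  method = c("spearman", "pearson"),
                                  rotate = c("map_b", "map_a")) {
  method <- match.arg(method)
  rotate <- match.arg(rotate)
  if (!inherits(perms, "spin_perms")) abort("`perms` must be a spin_perms object.")
  P <- ncol(perms$indices)
  if (length(map_a) != P || length(map_b) != P)
    abort("maps must have one value per parcel of the spin permutations.")
  if (!all(is.finite(map_a)) || !all(is.finite(map_b)))
    abort("maps must be finite.")

  r_obs <- cor(map_a, map_b, method = method)
  fixed <- if (rotate == "map_b") map_a else map_b
  moving <- if (rotate == "map_b") map_b else map_a
  null_r <- vapply(seq_len(perms$n_rot), function(i) {
    cor(fixed, moving[perms$indices[i, ]], method = method)
  }, numeric(1))
  p_spin <- (1 + sum(abs(null_r) >= abs(r_obs))) / (perms$n_rot + 1)

  out <- tibble(r = r_obs, p_spin = p_spin, method = method,
                n_rot = perms$n_rot)
  attr(out, "null_summary") <- c(mean = mean(null_r), sd = sd(null_r),
                                 quantile(null_r, c(0.025, 0.5, 0.975)))
  attr(out, "null_r") <- null_r
  out
}

#' Age-resolved alignment of fitted connectivity with the axis
#'
#' Traces how strongly the spatial pattern of model-predicted connectivity
#' correlates with S-A axis ranks across development. The cohort age range is
#' covered by a grid of `grid_points` evenly spaced ages (200 by default,
#' roughly monthly over an 18-year span). For every posterior draw of every
#' region's fitted trajectory, fitted values across regions are correlated
#' with axis ranks at each grid age; the per-age distribution over draws
#' yields the median alignment and a 95% credible band.
#'
#' @param fits List of [fit_region_gam()] objects, one per parcel, in axis
#'   order; all must share the same training age range.
#' @param axis_ranks Integer vector of S-A ranks, one per fit.
#' @param n_draws Posterior draws (default 10000).
#' @param grid_points Number of grid ages (default 200).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param seed Integer seed for the posterior draws.
#' @return Tibble of class `age_resolved_alignment`: `age`, `median_r`,
#'   `ci_lower`, `ci_upper` (2.5 and 97.5 percentiles across draws); number
#'   of draws in attribute `"n_draws"`. Ages where fitted values are constant
#'   across regions in some draw yield `NA` correlations for those draws,
#'   which are dropped from the summaries (all-NA ages stay `NA`).
#' @export
age_resolved_alignment <- function(fits, axis_ranks, n_draws = 10000,
                                   grid_points = 200,
                                   method = c("spearman", "pearson"),
                                   seed = 1) {
  method <- match.arg(method)
  if (length(fits) != length(axis_ranks))
    abort("`fits` and `axis_ranks` must have the same length.")
  rngs <- vapply(fits, function(f) f$age_range, numeric(2))
  if (max(abs(rngs[1, ] - rngs[1, 1])) > 1e-8 ||
      max(abs(rngs[2, ] - rngs[2, 1])) > 1e-8)
    abort("all fits must share the same training age range.")
  grid <- seq(rngs[1, 1], rngs[2, 1], length.out = grid_points)
  Pn <- length(fits)

  set.seed(seed)
  # per-region posterior coefficient draws and prediction bases
  draws <- vector("list", Pn)
  bases <- vector("list", Pn)
  for (p in seq_len(Pn)) {
    f <- fits[[p]]
    nd <- fitted_newdata(f, grid)
    bases[[p]] <- predict(f$fit, newdata = nd, type = "lpmatrix")
    V <- stats::vcov(f$fit)
    draws[[p]] <- MASS::mvrnorm(n_draws, mu = coef(f$fit), Sigma = (V + t(V)) / 2)
  }

  y_ref <- if (method == "spearman") rank(axis_ranks) else axis_ranks
  yc <- y_ref - mean(y_ref)
  ss_y <- sum(yc^2)

  med <- lo <- hi <- rep(NA_real_, grid_points)
  Fmat <- matrix(0, n_draws, Pn)
  for (a in seq_len(grid_points)) {
    for (p in seq_len(Pn)) Fmat[, p] <- draws[[p]] %*% bases[[p]][a, ]
    G <- if (method == "spearman") row_ranks(Fmat) else Fmat
    Gc <- G - rowMeans(G)
    den <- sqrt(rowSums(Gc^2) * ss_y)
    r <- as.numeric(Gc %*% yc) / den
    r[den == 0] <- NA
    if (any(!is.na(r))) {
      qs <- quantile(r, c(0.025, 0.5, 0.975), na.rm = TRUE)
      lo[a] <- qs[1]; med[a] <- qs[2]; hi[a] <- qs[3]
    }
  }
  out <- tibble(age = grid, median_r = med, ci_lower = lo, ci_upper = hi)
  attr(out, "n_draws") <- n_draws
  attr(out, "method") <- method
  class(out) <- c("age_resolved_alignment", class(out))
  out
}

row_ranks <- function(M) {
  t(apply(M, 1, rank))
}
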