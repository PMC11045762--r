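#' Build a synthetic bilateral cortical parcellation with S-A axis ranks
#'
#' Lays out `n_parcels / 2` parcel centroids per hemisphere on the unit sphere
#' with a deterministic Fibonacci spiral lattice (the right hemisphere is the
#' x-mirrored counterpart of the left, with interleaved colatitudes so polar
#' angles are distinct across the whole set). Each parcel receives a unique
#' sensorimotor-association (S-A) axis rank from 1 (sensorimotor pole) to
#' `n_parcels` (association pole): parcels are ranked by polar angle from a
#' designated sensorimotor pole at (0, 0, 1), plus spatially autocorrelated
#' noise whose amplitude is controlled by `hierarchy_smoothness`. Networks are
#' assigned either as contiguous rank bands (default) or interleaved across
#' the axis.
#'
#' @param n_parcels Even integer >= 10; total number of parcels.
#' @param hierarchy_smoothness Non-negative scalar; standard-deviation ratio
#'   of the spatially smooth rank noise to the polar-angle signal. 0 gives
#'   ranks strictly ordered by polar angle.
#' @param n_networks Number of functional networks (default 7).
#' @param network_layout `"bands"` (contiguous rank bands) or `"interleaved"`
#'   (networks cycle along the axis).
#' @param seed Integer seed; the same `(n_parcels, seed)` always yields an
#'   identical parcellation.
#'
#' @return A tibble with one row per parcel: `parcel_id`, `label`,
#'   `hemisphere` (`"L"`/`"R"`), `network`, unit-sphere centroid coordinates
#'   `x`, `y`, `z`, and `sa_rank` (a permutation of `1:n_parcels`).
#' @export
#' @examples
#' parc <- make_parcellation(20, seed = 1)
#' all(sort(parc$sa_rank) == 1:20)
make_parcellation <- function(n_parcels = 100, hierarchy_smoothness = 0.5,
                              n_networks = 7,
                              network_layout = c("bands", "interleaved"),
                              seed = 1) {
  network_layout <- match.arg(network_layout)
  if (length(n_parcels) != 1 || n_parcels < 10 || n_parcels %% 2 != 0)
    abort("`n_parcels` must be a single even integer >= 10.")
  if (hierarchy_smoothness < 0)
    abort("`hierarchy_smoothness` must be non-negative.")
  m <- n_parcels / 2

  # Fibonacci spiral lattice; per-hemisphere colatitude offsets 0.25 / 0.75
  # interleave polar angles so the combined set has no exact angular ties.
  lattice <- function(offset) {
    i <- seq_len(m)
    z <- 1 - 2 * (i - offset) / m
    golden <- pi * (3 - sqrt(5))
    phi <- golden * i
    r <- sqrt(pmax(0, 1 - z^2))
    cbind(x = r * cos(phi), y = r * sin(phi), z = z)
  }
  left <- lattice(0.25)
  right <- lattice(0.75)
  right[, "x"] <- -right[, "x"]
  coords <- rbind(left, right)
  hemisphere <- rep(c("L", "R"), each = m)

  theta <- acos(pmin(1, pmax(-1, coords[, "z"])))

  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  noise <- withr_seed({
    # bilaterally symmetric smooth field: right-hemisphere points are mirrored
    # through the x-plane before the kernel, so homologous locations coincide
    # and the field's law is invariant under hemisphere-locked rotations
    folded <- coords
    folded[hemisphere == "R", "x"] <- -folded[hemisphere == "R", "x"]
    d2 <- as.matrix(stats::dist(folded))^2
    K <- exp(-d2 / (2 * 0.5^2))
    raw <- as.numeric(K %*% rnorm(n_parcels))
    raw / sd(raw)
  })

  score <- theta + hierarchy_smoothness * sd(theta) * noise
  sa_rank <- rank(score, ties.method = "first")

  network_levels <- paste0("net", seq_len(n_networks))
  network <- if (network_layout == "bands") {
    network_levels[ceiling(sa_rank / (n_parcels / n_networks))]
  } else {
    network_levels[((sa_rank - 1) %% n_networks) + 1]
  }

  tibble(
    parcel_id = seq_len(n_parcels),
    label = sprintf("%s_parcel%03d", hemisphere, seq_len(n_parcels)),
    hemisphere = hemisphere,
    network = factor(network, levels = network_levels),
    x = coords[, "x"], y = coords[, "y"], z = coords[, "z"],
    sa_rank = as.integer(sa_rank)
  )
}

#' Spatially autocorrelated random parcel maps
#'
#' Draws smooth random maps over the parcellation from a Gaussian-kernel
#' process on the sphere, with right-hemisphere points mirrored through the
#' x-plane before the kernel so the maps are bilaterally symmetric in
#' distribution. This is the class of fields whose law is preserved by the
#' hemisphere-locked rotations of [generate_spin_permutations()], making
#' these maps the appropriate nulls for calibration studies of the spin
#' test.
#'
#' @param parcellation Tibble from [make_parcellation()].
#' @param n_maps Number of maps to draw.
#' @param length_scale Kernel length scale (chordal distance on the unit
#'   sphere; default 0.5).
#' @param seed Integer seed.
#' @return P x `n_maps` numeric matrix, each column one smooth map.
#' @export
random_smooth_maps <- function(parcellation, n_maps, length_scale = 0.5,
                               seed = 1) {
  validate_parcellation(parcellation)
  coords <- as.matrix(parcellation[, c("x", "y", "z")])
  coords[parcellation$hemisphere == "R", 1] <-
    -coords[parcellation$hemisphere == "R", 1]
  K <- exp(-as.matrix(stats::dist(coords))^2 / (2 * length_scale^2))
  set.seed(seed)
  K %*% matrix(rnorm(nrow(coords) * n_maps), nrow(coords), n_maps)
}

#' Validate a parcellation table
#'
#' Checks the structural invariants every parcellation-consuming function
#' relies on: unique contiguous parcel ids, unit-length centroids, sa_rank a
#' permutation, and an even hemisphere split.
#'
#' @param parcellation A tibble as returned by [make_parcellation()].
#' @return The parcellation, invisibly; aborts with a message on violation.
#' @export
validate_parcellation <- function(parcellation) {
  req <- c("parcel_id", "hemisphere", "network", "x", "y", "z", "sa_rank")
  missing <- setdiff(req, names(parcellation))
  if (length(missing))
    abort(paste0("parcellation lacks columns: ", paste(missing, collapse = ", ")))
  P <- nrow(parcellation)
  if (!identical(sort(parcellation$parcel_id), seq_len(P)) &&
      !identical(as.integer(sort(parcellation$parcel_id)), seq_len(P)))
    abort("parcel_id must be the contiguous integers 1..P.")
  if (!identical(sort(as.integer(parcellation$sa_rank)), seq_len(P)))
    abort("sa_rank must be a permutation of 1..P.")
  norms <- with(parcellation, sqrt(x^2 + y^2 + z^2))
  if (any(abs(norms - 1) > 1e-9))
    abort("centroids must lie on the unit sphere (norm 1 +/- 1e-9).")
  tab <- table(parcellation$hemisphere)
  if (!all(c("L", "R") %in% names(tab)) || tab[["L"]] != tab[["R"]])
    abort("each hemisphere must hold exactly P/2 parcels.")
  invisible(parcellation)
}
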