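#' Derive a sensorimotor-association axis by rank-averaging feature maps
#'
#' Each input map is rank-ordered across units (vertices or parcels), with
#' orientation flags determining whether high feature values point toward the
#' association pole; per-map ranks are averaged across maps and the averages
#' re-ranked to a unique 1..P ordering. Because only ranks enter, the axis is
#' invariant to any strictly monotone transform of any map. A constant map
#' carries no ordering information: it contributes the uniform mid-rank to
#' the average, with a warning.
#'
#' @param maps Units x maps numeric matrix or data frame (one column per
#'   feature map). An optional `unit_id` column is carried through.
#' @param orientation Logical vector, one per map: `TRUE` (default) if high
#'   values lie toward the association pole; `FALSE` maps are reversed before
#'   ranking.
#' @return Tibble with `unit_id` and `sa_rank` (a permutation of 1..P); the
#'   map names are recorded in the `"provenance"` attribute. Final ties in
#'   the average rank are broken by stable input order.
#' @export
derive_axis <- function(maps, orientation = NULL) {
  df <- as.data.frame(maps)
  unit_id <- if ("unit_id" %in% names(df)) {
    ids <- df$unit_id
    df$unit_id <- NULL
    ids
  } else {
    seq_len(nrow(df))
  }
  if (!ncol(df)) abort("`maps` must contain at least one feature map.")
  if (anyNA(df)) abort("feature maps must not contain missing values.")
  n <- nrow(df)
  rank_mat <- vapply(seq_along(df), function(j) {
    v <- df[[j]]
    if (!is.null(orientation) && !orientation[j]) v <- -v
    if (sd(v) == 0) {
      warn(sprintf("map '%s' is constant; it contributes a uniform mid-rank.",
                   names(df)[j]))
      rep((n + 1) / 2, n)
    } else {
      rank(v, ties.method = "average")
    }
  }, numeric(n))
  avg <- rowMeans(rank_mat)
  out <- tibble(unit_id = unit_id,
                sa_rank = as.integer(rank(avg, ties.method = "first")))
  attr(out, "provenance") <- names(df)
  out
}

#' Parcellate a unit-level axis
#'
#' Averages member-unit ranks within each parcel and re-ranks the parcel
#' scores to a unique 1..P ordering.
#'
#' @param unit_ranks Numeric vector of unit-level axis ranks.
#' @param unit_to_parcel Vector (or factor) of parcel assignments, one per
#'   unit; `NA` marks background units. Factor levels with no member units
#'   raise an error naming the parcel.
#' @return Tibble with `parcel_id` and `sa_rank`.
#' @export
parcellate_axis <- function(unit_ranks, unit_to_parcel) {
  if (length(unit_ranks) != length(unit_to_parcel))
    abort("`unit_ranks` and `unit_to_parcel` must have the same length.")
  f <- if (is.factor(unit_to_parcel)) unit_to_parcel
       else factor(unit_to_parcel, exclude = NA)
  counts <- table(f)
  if (any(counts == 0))
    abort(paste0("empty parcel(s): ",
                 paste(names(counts)[counts == 0], collapse = ", ")))
  keep <- !is.na(f)
  score <- tapply(unit_ranks[keep], f[keep], mean)
  tibble(parcel_id = names(score),
         sa_rank = as.integer(rank(as.numeric(score), ties.method = "first")))
}

#' Summarize axis ranks by functional network
#'
#' @param axis Tibble with `parcel_id` and `sa_rank` (e.g. from
#'   [parcellate_axis()], or the `sa_rank` column of a parcellation).
#' @param parcellation Parcellation tibble with `parcel_id` and `network`.
#' @return Tibble per network: `mean_rank`, `min_rank`, `max_rank`,
#'   `n_parcels`.
#' @export
network_axis_summary <- function(axis, parcellation) {
  joined <- dplyr::inner_join(
    dplyr::mutate(axis, parcel_id = as.integer(.data$parcel_id)),
    select(parcellation, "parcel_id", "network"), by = "parcel_id")
  joined %>%
    group_by(.data$network) %>%
    summarise(mean_rank = mean(.data$sa_rank),
              min_rank = min(.data$sa_rank),
              max_rank = max(.data$sa_rank),
              n_parcels = dplyr::n(), .groups = "drop")
}
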