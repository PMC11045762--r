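#' Scatter of regional age effects against S-A axis rank
#'
#' Reproduces the canonical alignment view: each point is one parcel, the
#' signed age effect plotted against the parcel's axis rank, colored by FDR
#' significance, with a least-squares trend line.
#'
#' @param effects Tibble from [fit_age_effects()].
#' @param parcellation Parcellation tibble providing `sa_rank`.
#' @param q_threshold Significance threshold on `q_value` (default 0.05).
#' @return A ggplot object.
#' @export
plot_alignment <- function(effects, parcellation, q_threshold = 0.05) {
  dat <- left_join(effects, select(parcellation, "parcel_id", "sa_rank"),
                   by = "parcel_id") %>%
    mutate(significant = .data$q_value < q_threshold)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$sa_rank, y = .data$signed_effect)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$significant), size = 1.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "black", linewidth = 0.5) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#B2182B", `FALSE` = "grey60"),
                                name = sprintf("Q < %.2g", q_threshold)) +
    ggplot2::labs(x = "S-A axis rank (sensorimotor → association)",
                  y = expression(paste("signed ", Delta, R[adj]^2))) +
    ggplot2::theme_minimal()
}

#' Plot an age-resolved alignment trajectory
#'
#' Median alignment correlation across posterior draws as a line, the 95%
#' credible band as a ribbon.
#'
#' @param object An `age_resolved_alignment` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.age_resolved_alignment <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$age, y = .data$median_r)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
                         fill = "grey75", alpha = 0.6) +
    ggplot2::geom_line(color = "black") +
    ggplot2::labs(x = "age (years)",
                  y = sprintf("alignment with S-A axis (%s r)",
                              attr(object, "method"))) +
    ggplot2::theme_minimal()
}

#' Plot an edge-effect rank surface
#'
#' Heat map with contours of the fitted tensor-smooth surface of edge age
#' effects over pairs of S-A ranks.
#'
#' @param surface A `rank_surface` from [edge_rank_surface()].
#' @return A ggplot object.
#' @export
plot_rank_surface <- function(surface) {
  ggplot2::ggplot(surface$grid,
                  ggplot2::aes(x = .data$rank_1, y = .data$rank_2,
                               fill = .data$fitted, z = .data$fitted)) +
    ggplot2::geom_raster() +
    ggplot2::geom_contour(color = "grey30", linewidth = 0.2) +
    ggplot2::scale_fill_gradient2(low = "#542788", mid = "white",
                                  high = "#E08214", name = "age effect") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "S-A rank, parcel 1", y = "S-A rank, parcel 2") +
    ggplot2::theme_minimal()
}

#' Plot regional developmental trajectories colored by axis rank
#'
#' Zero-centered fitted age curves for a list of regional fits, one line per
#' parcel, colored by S-A rank.
#'
#' @param fits Named list of [fit_region_gam()] objects (names = parcel ids).
#' @param parcellation Parcellation tibble providing `sa_rank`.
#' @param n_ages Grid resolution (default 100).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(fits, parcellation, n_ages = 100) {
  rng <- fits[[1]]$age_range
  grid <- seq(rng[1], rng[2], length.out = n_ages)
  dat <- purrr::imap(fits, function(f, id) {
    fv <- fitted_values(f, grid, center = TRUE)
    fv$parcel_id <- as.integer(id)
    fv
  }) %>% bind_rows() %>%
    left_join(select(parcellation, "parcel_id", "sa_rank"), by = "parcel_id")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$age, y = .data$centered_fitted,
                                    group = .data$parcel_id,
                                    color = .data$sa_rank)) +
    ggplot2::geom_line(alpha = 0.7, linewidth = 0.4) +
    ggplot2::scale_color_gradientn(colors = c("#2166AC", "#FEE090", "#B2182B"),
                                   name = "S-A rank") +
    ggplot2::labs(x = "age (years)", y = "fitted metric (zero-centered)") +
    ggplot2::theme_minimal()
}
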