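#' @export
autoplot.depth_map <- function(object, ...) {
  df <- tidyr::expand_grid(v = seq_len(nrow(object$values)) - 1,
                           u = seq_len(ncol(object$values)) - 1)
  df$depth_mm <- as.vector(t(object$values))
  df$depth_mm[!as.vector(t(object$valid))] <- NA
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v,
                                   fill = .data$depth_mm)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20") +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "depth (mm)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.meal_report <- function(object, ...) {
  df <- object$items |>
    select("fine_category", dplyr::all_of(c("kcal", "cho_g", "protein_g",
                                            "fat_g"))) |>
    tidyr::pivot_longer(-"fine_category", names_to = "nutrient",
                        values_to = "amount")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nutrient, y = .data$amount,
                                   fill = .data$fine_category)) +
    ggplot2::geom_col() +
    ggplot2::labs(title = sprintf("Meal nutrients (%s)", object$meal_label),
                  x = NULL, y = "kcal / grams", fill = "item") +
    ggplot2::theme_minimal()
}

#' MAPE summary plot for a daily evaluation
#'
#' @param x A `daily_evaluation` from [evaluate_daily()].
#' @return A ggplot: per-nutrient mean absolute percentage error with
#'   one-standard-deviation whiskers.
#' @export
plot_mape <- function(x) {
  stopifnot(inherits(x, "daily_evaluation"))
  ggplot2::ggplot(x$mape, ggplot2::aes(x = .data$nutrient,
                                       y = .data$mean_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$mean_pct -
                                                      .data$sd_pct, 0),
                                        ymax = .data$mean_pct + .data$sd_pct),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "mean absolute percentage error (%)") +
    ggplot2::theme_minimal()
}
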