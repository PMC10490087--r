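#' Per-participant mean absolute percentage error
#'
#' For each participant-day the absolute percentage error of a nutrient is
#' `100 * |estimated - reference| / reference`; the summary over
#' participants is the mean and the sample (n - 1) standard deviation. A
#' single participant gets sd 0 with a warning rather than an error, so
#' tiny fixtures stay runnable.
#'
#' @param days Tibble with columns `participant_id`, `nutrient`,
#'   `estimated`, `reference` (long form, one row per participant x
#'   nutrient).
#' @param nutrient Optional nutrient name(s) to restrict to.
#' @return Tibble with one row per nutrient: `nutrient`, `mean_pct`,
#'   `sd_pct`, `n`.
#' @export
mape <- function(days, nutrient = NULL) {
  days <- as_tibble(days)
  stopifnot(all(c("participant_id", "nutrient", "estimated", "reference")
                %in% names(days)))
  if (!is.null(nutrient)) days <- days[days$nutrient %in% nutrient, ]
  if (nrow(days) == 0) abort("no participant-days to evaluate")
  bad <- days$reference <= 0
  if (any(bad)) {
    abort(sprintf("non-positive reference for participant %s (%s)",
                  days$participant_id[bad][1], days$nutrient[bad][1]))
  }
  if (any(days |> count(nutrient) |> pull(n) < 2)) {
    warn("single participant: sd reported as 0")
  }
  days |>
    mutate(ape = 100 * abs(.data$estimated - .data$reference) /
             .data$reference) |>
    group_by(nutrient) |>
    summarise(mean_pct = mean(.data$ape),
              sd_pct = if (n() > 1) sd(.data$ape) else 0,
              n = n(), .groups = "drop")
}

#' Absolute percentage errors per participant
#'
#' Helper feeding [compare_methods()]: the raw APE values underlying
#' [mape()].
#'
#' @inheritParams mape
#' @return Tibble `participant_id`, `nutrient`, `ape`.
#' @export
ape_values <- function(days, nutrient = NULL) {
  days <- as_tibble(days)
  if (!is.null(nutrient)) days <- days[days$nutrient %in% nutrient, ]
  days |>
    mutate(ape = 100 * abs(.data$estimated - .data$reference) /
             .data$reference) |>
    select("participant_id", "nutrient", "ape")
}

#' Bland-Altman agreement analysis
#'
#' Differences are estimated minus reference; the limits of agreement are
#' the mean difference plus/minus 1.96 sample standard deviations (the 95%
#' convention). The returned object carries the per-participant
#' (mean-of-pair, difference) points for plotting.
#'
#' @inheritParams mape
#' @param nutrient Single nutrient name.
#' @return A `bland_altman` object: `mean_diff`, `sd_diff`, `loa_low`,
#'   `loa_high`, `n`, `nutrient`, and `points` (tibble `participant_id`,
#'   `mean_pair`, `diff`).
#' @export
bland_altman <- function(days, nutrient) {
  days <- as_tibble(days)
  days <- days[days$nutrient == nutrient, ]
  if (nrow(days) < 2) {
    abort("Bland-Altman analysis needs at least 2 participants")
  }
  d <- days$estimated - days$reference
  m <- (days$estimated + days$reference) / 2
  mean_diff <- mean(d)
  sd_diff <- sd(d)
  structure(
    list(mean_diff = mean_diff, sd_diff = sd_diff,
         loa_low = mean_diff - 1.96 * sd_diff,
         loa_high = mean_diff + 1.96 * sd_diff,
         n = nrow(days), nutrient = nutrient,
         points = tibble(participant_id = days$participant_id,
                         mean_pair = m, diff = d)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> %s, n=%d: mean diff %.2f, LoA [%.2f, %.2f]\n",
              x$nutrient, x$n, x$mean_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
tidy.bland_altman <- function(x, ...) x$points

#' @export
glance.bland_altman <- function(x, ...) {
  tibble(nutrient = x$nutrient, mean_diff = x$mean_diff,
         sd_diff = x$sd_diff, loa_low = x$loa_low, loa_high = x$loa_high,
         n = x$n)
}

#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$mean_pair, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$mean_diff, linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::labs(
      x = "Mean of estimate and reference",
      y = "Estimate - reference",
      title = sprintf("Bland-Altman agreement (%s, n = %d)", object$nutrient,
                      object$n),
      subtitle = sprintf("mean difference %.2f, 95%% limits [%.2f, %.2f]",
                         object$mean_diff, object$loa_low, object$loa_high)
    ) +
    ggplot2::theme_minimal()
}

#' Compare two methods' absolute percentage errors
#'
#' Welch two-sample t-test on the per-participant APE lists of two methods.
#' Identical zero-variance lists are degenerate for the t statistic and are
#' reported as `t = 0, p = 1` by convention.
#'
#' @param ape_a,ape_b Numeric vectors of absolute percentage errors (one per
#'   participant), length >= 2 each.
#' @return One-row tibble: `t_statistic`, `p_value`, `df`.
#' @export
compare_methods <- function(ape_a, ape_b) {
  stopifnot(length(ape_a) >= 2, length(ape_b) >= 2)
  if (sd(ape_a) == 0 && sd(ape_b) == 0) {
    if (isTRUE(all.equal(mean(ape_a), mean(ape_b)))) {
      return(tibble(t_statistic = 0, p_value = 1, df = NA_real_))
    }
    return(tibble(t_statistic = sign(mean(ape_a) - mean(ape_b)) * Inf,
                  p_value = 0, df = NA_real_))
  }
  tt <- t.test(ape_a, ape_b, var.equal = FALSE)
  tibble(t_statistic = unname(tt$statistic), p_value = tt$p.value,
         df = unname(tt$parameter))
}
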