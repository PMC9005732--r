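#' Per-cell sensitivity ratios of wetland change to forest change
#'
#' Computes, per cell, the marginal sensitivities that decompose the wetland
#' response to afforestation:
#' \deqn{\frac{\delta A_{wet}}{\delta A_{forest}}
#'   = \frac{\delta A_{wet}}{\delta SM} \times \frac{\delta SM}{\delta A_{forest}},}
#' where \eqn{\delta A_{wet}} and \eqn{\delta SM} are the end-minus-start
#' period changes of the attributed (S1 - S0) wetland area and annual-mean
#' soil moisture, and \eqn{\delta A_{forest}} the period change in forest
#' area. Cells failing any filter — never any forest, no forest change, not a
#' wetland cell — are excluded (flagged, not dropped), as are cells with a
#' residual nonfinite ratio.
#'
#' @param changes Tibble with columns `cell`, `d_awet` (km^2), `d_aforest`
#'   (km^2), `d_sm` (mm), `has_forest` (logical), `wetland_cell` (logical).
#' @return A tibble of class `sensitivity_result` with the inputs plus
#'   `dawet_daforest` (km^2 km^-2), `dawet_dsm` (km^2 mm^-1), `dsm_daforest`
#'   (mm km^-2), `included` (logical) and `exclude_reason`.
#' @export
sensitivity_ratios <- function(changes) {
  need <- c("cell", "d_awet", "d_aforest", "d_sm", "has_forest",
            "wetland_cell")
  if (!all(need %in% names(changes)))
    abort_afw(paste("`changes` must have columns:",
                    paste(need, collapse = ", ")), "invalid_argument")
  out <- changes |>
    dplyr::mutate(
      forest_changed = .data$d_aforest != 0,
      dawet_daforest = dplyr::if_else(.data$forest_changed,
                                      .data$d_awet / .data$d_aforest,
                                      NA_real_),
      dawet_dsm = dplyr::if_else(.data$d_sm != 0,
                                 .data$d_awet / .data$d_sm, NA_real_),
      dsm_daforest = dplyr::if_else(.data$forest_changed,
                                    .data$d_sm / .data$d_aforest, NA_real_),
      exclude_reason = dplyr::case_when(
        !.data$has_forest ~ "no_forest",
        !.data$forest_changed ~ "no_forest_change",
        !.data$wetland_cell ~ "not_wetland_cell",
        !is.finite(.data$dawet_daforest) | !is.finite(.data$dawet_dsm) |
          !is.finite(.data$dsm_daforest) ~ "nonfinite_ratio",
        TRUE ~ NA_character_
      ),
      included = is.na(.data$exclude_reason)
    )
  class(out) <- c("sensitivity_result", class(out))
  out
}

#' Drop percentile outliers
#'
#' Retains values inside the closed percentile band (default 5th-95th).
#' Percentiles are linear interpolations of the empirical CDF
#' (`stats::quantile()` type 4), under which e.g. the 5th/95th percentiles of
#' 1..100 are exactly 5 and 95.
#'
#' @param values Numeric vector (nonfinite values are dropped and counted).
#' @param lower_pct,upper_pct Percentile bounds (defaults 5 and 95).
#' @return A list with `values` (retained), `n_dropped`, and `bounds`.
#' @export
drop_outliers <- function(values, lower_pct = 5, upper_pct = 95) {
  v <- values[is.finite(values)]
  if (length(v) == 0)
    return(list(values = numeric(0), n_dropped = length(values),
                bounds = c(NA_real_, NA_real_)))
  b <- quantile(v, c(lower_pct, upper_pct) / 100, type = 4, names = FALSE)
  keep <- v >= b[1] & v <= b[2]
  list(values = v[keep], n_dropped = length(values) - sum(keep), bounds = b)
}

#' Box statistics of sensitivities by climate zone
#'
#' Per zone: minimum, the 20/40/50/60/80% quantiles, maximum, mean and count
#' — the whisker-box summary used to compare zones. Quantiles use the
#' standard sample definition (`stats::quantile()` type 7). Outlier screening
#' is the caller's job ([drop_outliers()] per zone beforehand).
#'
#' @param df Tibble with a `zone` column and the value column.
#' @param value Value column (tidy-eval).
#' @return A tibble: one row per zone with `min`, `q20`, `q40`, `q50`, `q60`,
#'   `q80`, `max`, `mean`, `n`. Empty zones yield all-missing rows.
#' @export
zone_box_stats <- function(df, value) {
  value <- rlang::enquo(value)
  df |>
    dplyr::group_by(.data$zone, .drop = FALSE) |>
    dplyr::summarise(
      dplyr::across(!!value, list(
        min = ~ if (length(.x)) min(.x) else NA_real_,
        q20 = ~ if (length(.x)) quantile(.x, 0.2, names = FALSE) else NA_real_,
        q40 = ~ if (length(.x)) quantile(.x, 0.4, names = FALSE) else NA_real_,
        q50 = ~ if (length(.x)) quantile(.x, 0.5, names = FALSE) else NA_real_,
        q60 = ~ if (length(.x)) quantile(.x, 0.6, names = FALSE) else NA_real_,
        q80 = ~ if (length(.x)) quantile(.x, 0.8, names = FALSE) else NA_real_,
        max = ~ if (length(.x)) max(.x) else NA_real_,
        mean = ~ if (length(.x)) mean(.x) else NA_real_
      ), .names = "{.fn}"),
      n = dplyr::n(),
      .groups = "drop"
    )
}
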