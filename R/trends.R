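#' Ordinary least-squares trend with t-test
#'
#' Slope of `y` against calendar year by ordinary least squares, with the
#' two-sided t-test p-value on the slope. Fewer than 3 finite points gives a
#' missing result (`NA` slope and p); a constant series gives slope 0 with
#' p = 1 by convention (no evidence of trend).
#'
#' @param y Numeric series.
#' @param years Matching calendar years.
#' @return A one-row tibble `slope`, `p_value`, `n`.
#' @export
linear_trend <- function(y, years) {
  ok <- is.finite(y) & is.finite(years)
  y <- y[ok]; x <- years[ok]
  n <- length(y)
  if (n < 3 || stats::sd(x) == 0)
    return(tibble(slope = NA_real_, p_value = NA_real_, n = n))
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  if (stats::sd(y) == 0)
    return(tibble(slope = 0, p_value = 1, n = n))
  res <- y - mean(y) - slope * (x - mean(x))
  s2 <- sum(res^2) / (n - 2)
  if (s2 == 0) return(tibble(slope = slope, p_value = 0, n = n))
  tval <- slope / sqrt(s2 / sxx)
  tibble(slope = slope, p_value = 2 * pt(-abs(tval), df = n - 2), n = n)
}

#' Per-cell trend field
#'
#' Applies [linear_trend()] per cell to a long cell-year table.
#'
#' @param field Tibble with columns `cell`, `year` and the value column.
#' @param value Column to take the trend of (tidy-eval).
#' @return A tibble `cell`, `slope`, `p_value`, `n`.
#' @export
trend_field <- function(field, value) {
  value <- rlang::enquo(value)
  field |>
    dplyr::group_by(.data$cell) |>
    dplyr::group_modify(~ linear_trend(dplyr::pull(.x, !!value), .x$year)) |>
    dplyr::ungroup()
}

#' Quadrant classification of paired trends
#'
#' Classifies each cell by the signs of its forest-cover and wetland-fraction
#' trends (forest on the x-axis, wetland on the y-axis). Quadrant 4 — forest
#' expanding while wetlands shrink — is the configuration diagnostic of a
#' planting-driven wetland loss. Zero trends fall on a `boundary`.
#'
#' @param forest_trend,wetland_trend Finite trend values; vectorised.
#' @return Factor with levels `"1"`..`"4"`, `"boundary"`.
#' @export
classify_quadrant <- function(forest_trend, wetland_trend) {
  out <- dplyr::case_when(
    forest_trend == 0 | wetland_trend == 0 ~ "boundary",
    forest_trend > 0 & wetland_trend > 0 ~ "1",
    forest_trend < 0 & wetland_trend > 0 ~ "2",
    forest_trend < 0 & wetland_trend < 0 ~ "3",
    forest_trend > 0 & wetland_trend < 0 ~ "4"
  )
  factor(out, levels = c("1", "2", "3", "4", "boundary"))
}

#' Climate zone from mean aridity
#'
#' Partitions cells into the three aridity zones: `wet` (PET/P < 1), `mesic`
#' (1 <= PET/P <= 2, closed interval — the boundary values 1 and 2 belong to
#' mesic) and `dry` (PET/P > 2).
#'
#' @param phi_mean Positive long-term mean PET/P; vectorised.
#' @return Factor with levels `wet`, `mesic`, `dry`.
#' @export
climate_zone <- function(phi_mean) {
  if (any(!is.finite(phi_mean)) || any(phi_mean <= 0))
    abort_afw("`phi_mean` must be finite and > 0.", "invalid_argument")
  factor(dplyr::case_when(
    phi_mean < 1 ~ "wet",
    phi_mean <= 2 ~ "mesic",
    TRUE ~ "dry"
  ), levels = c("wet", "mesic", "dry"))
}

#' Wetland grid-cell mask
#'
#' A cell counts as a wetland cell iff its mean annual maximum wetland
#' fraction exceeds the threshold (default 1%, strict inequality: exactly 1%
#' is excluded).
#'
#' @param annual_frac Tibble `cell`, `year`, `annual_max_frac`.
#' @param threshold Mean-fraction threshold (default 0.01).
#' @return A tibble `cell`, `mean_annual_max`, `wetland_cell` (logical).
#' @export
wetland_cell_mask <- function(annual_frac, threshold = 0.01) {
  annual_frac |>
    dplyr::group_by(.data$cell) |>
    dplyr::summarise(mean_annual_max = mean(.data$annual_max_frac),
                     .groups = "drop") |>
    dplyr::mutate(wetland_cell = .data$mean_annual_max > threshold)
}

#' Rice-paddy exclusion filter
#'
#' Removes (sets the mask `FALSE` for) cells whose rice-paddy coverage
#' exceeds the threshold (default 10%, strict: exactly 10% is kept), to avoid
#' attributing human-managed flooding to natural wetlands.
#'
#' @param mask Tibble with `cell` and a logical `wetland_cell` column.
#' @param rice Tibble `cell`, `rice_frac`.
#' @param threshold Rice-fraction threshold (default 0.10).
#' @return `mask` with `wetland_cell` updated and a `rice_excluded` column.
#' @export
rice_filter <- function(mask, rice, threshold = 0.10) {
  mask |>
    dplyr::left_join(rice, by = "cell") |>
    dplyr::mutate(
      rice_excluded = dplyr::coalesce(.data$rice_frac, 0) > threshold,
      wetland_cell = .data$wetland_cell & !.data$rice_excluded
    )
}

#' Factorial attribution difference (S1 - S0)
#'
#' Elementwise difference between a simulation with the driver (forest
#' change, S1) and the paired control without it (S0): the change attributed
#' to the driver. Both tables must share their key columns.
#'
#' @param s1,s0 Tibbles with identical key columns and the value column.
#' @param value Value column (tidy-eval).
#' @return A tibble with the keys and the attributed difference in the value
#'   column.
#' @export
attribution_diff <- function(s1, s0, value) {
  value <- rlang::enquo(value)
  vname <- rlang::as_name(value)
  keys <- setdiff(names(s1), vname)
  if (!identical(sort(names(s1)), sort(names(s0))) ||
      nrow(s1) != nrow(s0))
    abort_afw("`s1` and `s0` must have identical shape.", "shape_mismatch")
  merged <- dplyr::inner_join(s1, s0, by = keys, suffix = c("_s1", "_s0"))
  if (nrow(merged) != nrow(s1))
    abort_afw("`s1` and `s0` keys do not match.", "shape_mismatch")
  merged[[vname]] <- merged[[paste0(vname, "_s1")]] -
    merged[[paste0(vname, "_s0")]]
  dplyr::select(merged, dplyr::all_of(c(keys, vname)))
}
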