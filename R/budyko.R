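#' Budyko plant-available-water coefficients
#'
#' The two-parameter Budyko curve used throughout the package carries one
#' shape coefficient `w` per land-cover class: deep-rooted forest retains more
#' plant-available water (`w = 2`) than grass (`w = 0.5`), so converting grass
#' to forest raises ET/P and lowers Q/P at any aridity.
#'
#' @param w_forest,w_grass Positive coefficients (defaults 2 and 0.5).
#' @return A list of class `budyko_params`.
#' @export
budyko_params <- function(w_forest = 2, w_grass = 0.5) {
  if (w_forest <= 0 || w_grass <= 0)
    abort_afw("Budyko coefficients must be > 0.", "invalid_argument")
  structure(list(w_forest = w_forest, w_grass = w_grass),
            class = "budyko_params")
}

check_phi <- function(phi) {
  if (any(!is.finite(phi)) || any(phi <= 0))
    abort_afw("Aridity index `phi` = PET/P must be finite and > 0.",
              "invalid_argument")
  invisible(phi)
}

#' Budyko evaporative and runoff fractions
#'
#' `et_ratio()` returns the fraction of annual precipitation lost as
#' evapotranspiration under the two-parameter Budyko curve,
#' \deqn{ET/P = \frac{1 + w\,\phi}{1 + w\,\phi + \phi^{-1}},}
#' with \eqn{\phi =} PET/P the aridity index and `w` the plant-available-water
#' coefficient. `runoff_ratio()` is its exact complement
#' \eqn{Q/P = \phi^{-1} / (1 + w\,\phi + \phi^{-1})}; the two share a
#' denominator so `et_ratio(phi, w) + runoff_ratio(phi, w) == 1` identically.
#' ET/P is strictly increasing in both `phi` and `w`, tends to 0 as
#' \eqn{\phi \to 0^+} (energy-limited) and to 1 as \eqn{\phi \to \infty}
#' (water-limited).
#'
#' @param phi Aridity index PET/P, positive; vectorised.
#' @param w Plant-available-water coefficient, positive; vectorised.
#' @return Numeric vector of fractions in (0, 1).
#' @examples
#' et_ratio(1, w = 2)      # 0.75
#' runoff_ratio(1, w = 0.5) # 0.4
#' @export
et_ratio <- function(phi, w) {
  check_phi(phi)
  if (any(w <= 0)) abort_afw("`w` must be > 0.", "invalid_argument")
  (1 + w * phi) / (1 + w * phi + 1 / phi)
}

#' @rdname et_ratio
#' @export
runoff_ratio <- function(phi, w) {
  check_phi(phi)
  if (any(w <= 0)) abort_afw("`w` must be > 0.", "invalid_argument")
  (1 / phi) / (1 + w * phi + 1 / phi)
}

#' Annual runoff change caused by a forest-cover change
#'
#' The runoff change attributable to converting grass to forest (or back)
#' over one step is
#' \deqn{\delta Q = P (f_t - f_{t-1}) \left[ Q/P(\phi, w_f) - Q/P(\phi, w_g) \right],}
#' i.e. the forest-cover change times the gap between the forest and grass
#' runoff fractions at the local aridity. With the default coefficients the
#' bracket is negative, so forest gain always reduces runoff.
#'
#' @param p Annual precipitation, mm yr^-1; positive.
#' @param phi Aridity index PET/P.
#' @param f_prev,f_curr Forest cover fractions in \[0, 1\] at the start and end
#'   of the step.
#' @param params A [budyko_params()] object.
#' @return \eqn{\delta Q} in mm yr^-1 (vectorised).
#' @examples
#' delta_runoff(1000, 1, 0, 0.2) # -30
#' @export
delta_runoff <- function(p, phi, f_prev, f_curr, params = budyko_params()) {
  if (any(p <= 0)) abort_afw("`p` must be > 0.", "invalid_argument")
  if (any(f_prev < 0 | f_prev > 1 | f_curr < 0 | f_curr > 1))
    abort_afw("Forest fractions must lie in [0, 1].", "invalid_argument")
  p * (f_curr - f_prev) *
    (runoff_ratio(phi, params$w_forest) - runoff_ratio(phi, params$w_grass))
}

#' Area-weighted effective Budyko coefficient of a mixed cell
#'
#' A grid cell with forest fraction `f` (the rest grass) gets the linear mix
#' \eqn{w = f\,w_f + (1-f)\,w_g}; the endpoints return the pure class
#' coefficients. This mixing rule feeds the bucket soil-moisture surrogate.
#'
#' @inheritParams delta_runoff
#' @param forest_frac Forest cover fraction in \[0, 1\]; vectorised.
#' @return Effective `w`.
#' @export
effective_w <- function(forest_frac, params = budyko_params()) {
  if (any(forest_frac < 0 | forest_frac > 1))
    abort_afw("`forest_frac` must lie in [0, 1].", "invalid_argument")
  forest_frac * params$w_forest + (1 - forest_frac) * params$w_grass
}

#' Tabulate Budyko curves over aridity and coefficient grids
#'
#' @param phi_values Positive aridity values.
#' @param w_values Positive coefficients.
#' @return A tibble of class `budyko_curves` with one row per (phi, w) pair and
#'   columns `phi`, `w`, `et_over_p`, `q_over_p`.
#' @export
budyko_curve_table <- function(phi_values, w_values) {
  check_phi(phi_values)
  tidyr::expand_grid(phi = phi_values, w = w_values) |>
    dplyr::mutate(
      et_over_p = et_ratio(.data$phi, .data$w),
      q_over_p = runoff_ratio(.data$phi, .data$w)
    ) |>
    structure(class = c("budyko_curves", class(tibble::tibble())))
}

#' Gridded runoff change attributable to forest change
#'
#' Applies [delta_runoff()] per cell and year: each year's precipitation,
#' the cell's aridity, and the consecutive-year forest fractions give that
#' year's attributable runoff change. By default the aridity entering the
#' curve is the cell's long-term mean PET/P (climatology); set
#' `phi_mode = "annual"` to use each year's ratio instead.
#'
#' @param climate Tibble with columns `cell`, `year`, `p`, `pet` (see
#'   [gen_climate()]).
#' @param forest Tibble with columns `cell`, `year`, `forest_frac`.
#' @param params A [budyko_params()] object.
#' @param phi_mode `"climatology"` (default) or `"annual"`.
#' @param summarise If `TRUE`, return one row per cell with the period-total
#'   `delta_q_total` (mm) and its value normalised by mean annual
#'   precipitation, `delta_q_over_p`.
#' @return A tibble: per cell-year `delta_q` (first year is 0 — no preceding
#'   year), or the per-cell summary.
#' @export
grid_delta_runoff <- function(climate, forest, params = budyko_params(),
                              phi_mode = c("climatology", "annual"),
                              summarise = FALSE) {
  phi_mode <- match.arg(phi_mode)
  if (!setequal(unique(climate$cell), unique(forest$cell)) ||
      !setequal(unique(climate$year), unique(forest$year)))
    abort_afw("`climate` and `forest` must share cells and years.",
              "shape_mismatch")

  df <- dplyr::inner_join(climate, forest, by = c("cell", "year")) |>
    dplyr::arrange(.data$cell, .data$year) |>
    dplyr::group_by(.data$cell) |>
    dplyr::mutate(
      phi_used = if (phi_mode == "climatology")
        mean(.data$pet) / mean(.data$p) else .data$pet / .data$p,
      f_prev = dplyr::lag(.data$forest_frac),
      delta_q = dplyr::if_else(
        is.na(.data$f_prev), 0,
        delta_runoff(.data$p, .data$phi_used, dplyr::coalesce(.data$f_prev, 0),
                     .data$forest_frac, params)
      )
    ) |>
    dplyr::ungroup()

  if (!summarise)
    return(dplyr::select(df, "cell", "year", "delta_q"))

  df |>
    dplyr::group_by(.data$cell) |>
    dplyr::summarise(
      delta_q_total = sum(.data$delta_q),
      delta_q_over_p = sum(.data$delta_q) / mean(.data$p),
      .groups = "drop"
    )
}
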