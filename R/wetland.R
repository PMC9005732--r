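#' Default shape of the deficit-to-wetland-fraction sigmoid
#'
#' The diagnostic maps grid-cell soil-moisture deficit to saturated (wetland)
#' fraction through a generalized sigmoid (see [wetland_fraction()]). The
#' shape defaults place the steep limb of the curve at deficits typical of
#' dry and mesic cells (half-saturation `d0 = 85` mm, sensitivity
#' `k = 0.1` mm^-1) while wet cells, whose deficit stays far below `d0`, sit
#' on the flat plateau near `f_max` — the TOPMODEL intuition that nearly
#' saturated soils flood readily and insensitively.
#'
#' @param k Deficit sensitivity, mm^-1 (> 0).
#' @param d0 Half-saturation deficit, mm (>= 0).
#' @param v Asymmetry exponent (> 0; 1 = symmetric logistic).
#' @return A list of class `wetland_shape`.
#' @export
wetland_shape <- function(k = 0.1, d0 = 85, v = 1) {
  if (k <= 0 || d0 < 0 || v <= 0)
    abort_afw("Invalid wetland shape parameters.", "invalid_argument")
  structure(list(k = k, d0 = d0, v = v), class = "wetland_shape")
}

#' Soil-moisture deficit
#'
#' The deficit with respect to saturation, \eqn{D = SM_{sat} - SM}, per
#' cell-timestep. Zero at saturation, equal to capacity when the bucket is
#' empty.
#'
#' @param sm A tibble with columns `sm` and `sm_sat` (e.g. from
#'   [bucket_soil_moisture()]); any key columns are carried through.
#' @return The input with a `deficit` column (mm) added.
#' @export
soil_moisture_deficit <- function(sm) {
  if (any(sm$sm < 0) || any(sm$sm > sm$sm_sat + 1e-9))
    abort_afw("Soil moisture must lie in [0, sm_sat].", "invariant_violation")
  dplyr::mutate(sm, deficit = .data$sm_sat - .data$sm)
}

#' Wetland (saturated) fraction from soil-moisture deficit
#'
#' The diagnostic sigmoid
#' \deqn{f(D) = f_{max} \left(1 + v\, e^{k (D - d_0)}\right)^{-1/v},}
#' a CDF-like, strictly decreasing function of the deficit \eqn{D}: it
#' approaches the attainable maximum \eqn{f_{max}} as the soil saturates
#' (\eqn{D \to 0}, for \eqn{d_0} large relative to \eqn{1/k}) and 0 as the
#' soil dries out. With `v = 1` it is the symmetric logistic and
#' \eqn{f(d_0) = f_{max}/2}.
#'
#' @param deficit Nonnegative deficit, mm; vectorised.
#' @param f_max Attainable maximum wetland fraction in \[0, 1\].
#' @param k,d0,v Shape parameters, see [wetland_shape()].
#' @return Wetland fraction in \[0, `f_max`\].
#' @examples
#' wetland_fraction(50, f_max = 0.3, k = 1, d0 = 50) # 0.15
#' @export
wetland_fraction <- function(deficit, f_max, k = 0.1, d0 = 85, v = 1) {
  if (any(deficit < 0)) abort_afw("`deficit` must be >= 0.", "invalid_argument")
  if (any(f_max < 0 | f_max > 1) || any(k <= 0) || any(d0 < 0) || any(v <= 0))
    abort_afw("Invalid wetland parameters.", "invalid_argument")
  f_max * (1 + v * exp(k * (deficit - d0)))^(-1 / v)
}

# join per-cell parameters onto a deficit series and evaluate the sigmoid
wetland_series <- function(deficit_tbl, params) {
  deficit_tbl |>
    dplyr::inner_join(
      dplyr::select(params, "cell", "f_max", "k", "d0", "v"), by = "cell") |>
    dplyr::mutate(wet_frac = wetland_fraction(
      .data$deficit, .data$f_max, .data$k, .data$d0, .data$v))
}

#' Monthly wetland fractions and annual maxima from a deficit series
#'
#' Applies the diagnostic per cell with per-cell parameters and reduces to the
#' annual maximum fraction, the quantity the observational products report.
#'
#' @param deficit_tbl Tibble `cell`, `year`, (`month`), `deficit`.
#' @param params Tibble with columns `cell`, `f_max`, `k`, `d0`, `v`.
#' @return A tibble `cell`, `year`, `annual_max_frac`.
#' @export
annual_max_wetland_fraction <- function(deficit_tbl, params) {
  wetland_series(deficit_tbl, params) |>
    dplyr::group_by(.data$cell, .data$year) |>
    dplyr::summarise(annual_max_frac = max(.data$wet_frac), .groups = "drop")
}

#' Annual maximum wetland area
#'
#' Converts annual maximum wetland fractions to areas (fraction times full
#' cell area, km^2).
#'
#' @param annual_frac Tibble `cell`, `year`, `annual_max_frac`.
#' @param domain A [make_grid_domain()] domain.
#' @return A tibble `cell`, `year`, `area_km2`.
#' @export
annual_max_wetland_area <- function(annual_frac, domain) {
  annual_frac |>
    dplyr::inner_join(dplyr::select(domain, "cell", "area_km2"), by = "cell") |>
    dplyr::mutate(area_km2 = .data$annual_max_frac * .data$area_km2) |>
    dplyr::select("cell", "year", "area_km2")
}

#' Static calibration against a long-term maximum wetland extent
#'
#' With the sigmoid shape held at its defaults, solves per cell for the single
#' scale parameter `f_max` so that the modeled long-term maximum — attained at
#' the minimum-deficit timestep — exactly reproduces the observed static
#' maximum extent. Cells observed at zero get `f_max = 0`. This mirrors
#' calibration against a static maximum-extent wetland map, which cannot
#' identify more than one parameter per cell.
#'
#' @param obs_static Tibble `cell`, `static_max_frac` in \[0, 1\].
#' @param deficit_tbl Tibble `cell`, ..., `deficit` over the calibration
#'   period.
#' @param shape A [wetland_shape()] with the fixed shape parameters.
#' @return A tibble of class `wetland_calibration`: `cell`, `f_max`, `k`,
#'   `d0`, `v`, `sse` (0 by construction), `converged`.
#' @export
calibrate_static <- function(obs_static, deficit_tbl, shape = wetland_shape()) {
  if (any(obs_static$static_max_frac < 0 | obs_static$static_max_frac > 1))
    abort_afw("Observed fractions must lie in [0, 1].", "invalid_argument")
  finite <- dplyr::filter(deficit_tbl, is.finite(.data$deficit))
  if (nrow(finite) == 0)
    abort_afw("No finite deficits to calibrate against.", "insufficient_data")
  dmin <- finite |>
    dplyr::group_by(.data$cell) |>
    dplyr::summarise(d_min = min(.data$deficit), .groups = "drop")
  missing <- setdiff(obs_static$cell, dmin$cell)
  if (length(missing))
    abort_afw(sprintf("No finite deficits for %d cell(s).", length(missing)),
              "insufficient_data")
  out <- obs_static |>
    dplyr::inner_join(dmin, by = "cell") |>
    dplyr::mutate(
      g_max = wetland_fraction(.data$d_min, 1, shape$k, shape$d0, shape$v),
      f_max = dplyr::if_else(.data$static_max_frac == 0, 0,
                             pmin(1, .data$static_max_frac / .data$g_max)),
      k = shape$k, d0 = shape$d0, v = shape$v,
      sse = 0, converged = TRUE
    ) |>
    dplyr::select("cell", "f_max", "k", "d0", "v", "sse", "converged")
  class(out) <- c("wetland_calibration", class(out))
  out
}

#' Dynamic calibration against annual maximum wetland areas
#'
#' Fits `(f_max, k, d0)` per cell (asymmetry `v` held fixed) by bounded
#' nonlinear least squares (Levenberg-Marquardt, \pkg{minpack.lm}) so the
#' modeled annual maxima match an observed annual-maximum series. The modeled
#' annual maximum is the sigmoid evaluated at each year's minimum deficit.
#' A small multi-start over `d0` and `k` initialisations guards against local
#' minima. Cells whose yearly minimum deficits are (near-)constant cannot
#' identify the shape and are flagged unconverged (degenerate), as are fits
#' that exhaust the iteration budget.
#'
#' @param obs_annual Tibble `cell`, `year`, `annual_max_frac`; at least 4
#'   years per cell.
#' @param deficit_tbl Tibble `cell`, `year`, ..., `deficit`.
#' @param shape A [wetland_shape()] giving `v` and the initial `k`, `d0`.
#' @param max_iter Iteration cap per start (default 200).
#' @return A tibble of class `wetland_calibration`: `cell`, `f_max`, `k`,
#'   `d0`, `v`, `sse`, `converged`, `n_years`. Non-convergence is reported in
#'   the `converged` column, never raised.
#' @export
calibrate_dynamic <- function(obs_annual, deficit_tbl,
                              shape = wetland_shape(), max_iter = 200) {
  dy <- deficit_tbl |>
    dplyr::group_by(.data$cell, .data$year) |>
    dplyr::summarise(d_min = min(.data$deficit), .groups = "drop")
  df <- dplyr::inner_join(obs_annual, dy, by = c("cell", "year"))

  fit_cell <- function(d) {
    n <- nrow(d)
    if (n < 4)
      return(tibble(f_max = NA_real_, k = NA_real_, d0 = NA_real_,
                    sse = NA_real_, converged = FALSE, n_years = n))
    obs <- d$annual_max_frac
    dmin <- d$d_min
    if (max(obs) == 0)
      return(tibble(f_max = 0, k = shape$k, d0 = shape$d0, sse = sum(obs^2),
                    converged = TRUE, n_years = n))
    degenerate <- stats::sd(dmin) < 1e-8
    lower <- c(f_max = 1e-8, k = 1e-4, d0 = 0)
    upper <- c(f_max = 1, k = 2, d0 = max(dmin) * 2 + shape$d0)
    resid_fn <- function(par)
      wetland_fraction(dmin, par[1], par[2], par[3], shape$v) - obs
    starts <- tidyr::expand_grid(
      k0 = unique(pmax(lower["k"], c(0.5, 1, 2) * shape$k)),
      d00 = unique(quantile(dmin, c(0.25, 0.5, 0.75), names = FALSE)))
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      par0 <- c(f_max = min(1, max(obs) *
                  (1 + shape$v * exp(starts$k0[i] * (min(dmin) - starts$d00[i])))^(1 / shape$v)),
                k = starts$k0[i], d0 = starts$d00[i])
      par0 <- pmin(pmax(par0, lower), upper)
      fit <- try(minpack.lm::nls.lm(
        par = par0, lower = lower, upper = upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = max_iter)),
        silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (is.null(best) || fit$deviance < best$deviance) best <- fit
    }
    if (is.null(best))
      return(tibble(f_max = NA_real_, k = NA_real_, d0 = NA_real_,
                    sse = NA_real_, converged = FALSE, n_years = n))
    tibble(
      f_max = best$par[["f_max"]], k = best$par[["k"]], d0 = best$par[["d0"]],
      sse = best$deviance,
      converged = !degenerate && best$info %in% 1:4,
      n_years = n
    )
  }

  out <- df |>
    dplyr::group_by(.data$cell) |>
    dplyr::group_modify(~ fit_cell(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(v = shape$v) |>
    dplyr::select("cell", "f_max", "k", "d0", "v", "sse", "converged",
                  "n_years")
  class(out) <- c("wetland_calibration", class(out))
  out
}

#' @export
tidy.wetland_calibration <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x)[c("cell", "f_max", "k", "d0", "v")],
                      -"cell", names_to = "term", values_to = "estimate")
}

#' @export
glance.wetland_calibration <- function(x, ...) {
  tibble(
    n_cells = nrow(x),
    n_converged = sum(x$converged, na.rm = TRUE),
    median_sse = median(x$sse, na.rm = TRUE),
    total_sse = sum(x$sse, na.rm = TRUE)
  )
}
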