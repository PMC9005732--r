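#' Build a near-term planting scenario
#'
#' Constructs a per-cell forest-fraction trajectory for the projection window
#' under one of four allocation rules:
#' * `"SA"` — the national target is allocated proportionally to each cell's
#'   historical planting (the plan continues the historical trajectory);
#' * `"SA_dry"`, `"SA_mesic"`, `"SA_wet"` — the full national target is
#'   planted only in the named aridity zone (PET/P > 2, 1-2, < 1),
#'   proportionally to each cell's remaining plantable area.
#'
#' Per-cell fractions never exceed `max_forest_frac` (capped, overflow
#' redistributed); total planted area equals the target to within 0.1%, or an
#' `infeasible_allocation` error reports the shortfall. Trajectories are
#' linear in time from the current forest map.
#'
#' @param kind One of `"SA"`, `"SA_dry"`, `"SA_mesic"`, `"SA_wet"`.
#' @param domain A [make_grid_domain()] domain.
#' @param zones Tibble `cell`, `zone` (see [climate_zone()]).
#' @param forest_now Tibble `cell`, `forest_frac`: the forest map at the start
#'   of the window.
#' @param national_target_km2 Total new forest area, km^2 (>= 0).
#' @param years Projection years (default 2017:2035).
#' @param hist_planted Optional tibble `cell`, `planted_km2` of historical
#'   planting; required for `kind = "SA"`.
#' @param max_forest_frac Per-cell forest ceiling (default 0.9).
#' @return A list of class `planting_scenario`: `name`, `national_target_km2`,
#'   `allocation` (tibble `cell`, `planted_km2`), `forest_traj` (tibble
#'   `cell`, `year`, `forest_frac`), `years`.
#' @export
build_scenario <- function(kind = c("SA", "SA_dry", "SA_mesic", "SA_wet"),
                           domain, zones, forest_now, national_target_km2,
                           years = 2017:2035, hist_planted = NULL,
                           max_forest_frac = 0.9) {
  kind <- match.arg(kind)
  if (national_target_km2 < 0)
    abort_afw("`national_target_km2` must be >= 0.", "invalid_argument")
  if (any(diff(years) != 1))
    abort_afw("`years` must be contiguous.", "invalid_argument")

  df <- domain |>
    dplyr::select("cell", "area_km2") |>
    dplyr::inner_join(zones, by = "cell") |>
    dplyr::inner_join(forest_now, by = "cell") |>
    dplyr::mutate(capacity = pmax(0, max_forest_frac - .data$forest_frac) *
                    .data$area_km2)

  if (kind == "SA") {
    if (is.null(hist_planted))
      abort_afw("`hist_planted` is required for kind = \"SA\".",
                "invalid_argument")
    df <- dplyr::left_join(df, hist_planted, by = "cell") |>
      dplyr::mutate(weight = dplyr::coalesce(.data$planted_km2, 0))
  } else {
    zone_name <- sub("SA_", "", kind)
    df <- dplyr::mutate(df,
      weight = dplyr::if_else(.data$zone == zone_name, .data$capacity, 0))
  }

  planted <- allocate_area(df$weight,
                           df$capacity * (df$weight > 0),
                           national_target_km2)
  dfrac <- planted / df$area_km2
  ramp <- seq(0, 1, length.out = length(years))

  traj <- tidyr::expand_grid(cell = df$cell, year = years) |>
    dplyr::left_join(
      tibble(cell = df$cell, f0 = df$forest_frac, dfrac = dfrac), by = "cell") |>
    dplyr::mutate(forest_frac = .data$f0 +
                    .data$dfrac * ramp[match(.data$year, years)]) |>
    dplyr::select("cell", "year", "forest_frac")

  structure(list(
    name = kind,
    national_target_km2 = national_target_km2,
    allocation = tibble(cell = df$cell, planted_km2 = planted),
    forest_traj = traj,
    years = years
  ), class = "planting_scenario")
}

#' @export
print.planting_scenario <- function(x, ...) {
  cat(sprintf("<planting_scenario %s: %.0f km2 over %d-%d, %d cells planted>\n",
              x$name, x$national_target_km2, min(x$years), max(x$years),
              sum(x$allocation$planted_km2 > 0)))
  invisible(x)
}

#' Recycle historical climate into a projection window
#'
#' Implements "constant climate": each projection year reuses one seeded draw
#' (with replacement) of the historical years, so the projection window sees
#' the historical climate statistics but no trend.
#'
#' @param climate Historical climate tibble (`cell`, `year`, `p`, `pet`,
#'   `phi`).
#' @param years Projection years.
#' @param seed Integer seed for the year resampling.
#' @return A climate tibble over `years`.
#' @export
recycle_climate <- function(climate, years, seed) {
  hist_years <- sort(unique(climate$year))
  withr::with_seed(seed, {
    pick <- sample(hist_years, length(years), replace = TRUE)
  })
  purrr::map2_dfr(years, pick, function(yy, hy) {
    climate |>
      dplyr::filter(.data$year == hy) |>
      dplyr::mutate(year = yy)
  })
}

#' Project wetland change under a planting scenario
#'
#' Runs the full surrogate chain for a scenario and its paired control:
#' bucket soil moisture under the scenario forest trajectory (S1) and under
#' constant forest (S0), the wetland diagnostic with calibrated parameters on
#' both, annual maximum wetland areas, and the attributed change S1 - S0.
#' The baseline area per cell is the control-run mean annual-maximum area
#' (the extent maintained if the start-of-window forest map persisted);
#' losses are reported relative to it via [loss_relative()].
#'
#' @param scenario A [build_scenario()] object.
#' @param climate Climate over the projection years (e.g.
#'   [recycle_climate()]).
#' @param domain The [make_grid_domain()] domain (for cell areas).
#' @param wetland_params A `wetland_calibration` (or truth) parameter table;
#'   cells without parameters are reported in `missing_cells`, not silently
#'   skipped.
#' @param budyko,bucket Parameter objects for the surrogate.
#' @return A list of class `wetland_projection`: `scenario`, `annual` (tibble
#'   `cell`, `year`, `area_s1`, `area_s0`, `delta_km2`), `cells` (per-cell
#'   baseline/final/loss table, see [loss_relative()]), `national_loss_km2`
#'   (net attributed loss, positive = loss), `missing_cells`.
#' @export
project_scenario <- function(scenario, climate, domain, wetland_params,
                             budyko = budyko_params(),
                             bucket = bucket_params()) {
  domain_cells <- sort(unique(scenario$forest_traj$cell))
  have <- wetland_params$cell[!is.na(wetland_params$f_max)]
  missing_cells <- setdiff(domain_cells, have)
  params <- dplyr::filter(wetland_params, .data$cell %in% have)

  f0 <- scenario$forest_traj |>
    dplyr::filter(.data$year == min(.data$year)) |>
    dplyr::select("cell", "forest_frac")
  control_traj <- tidyr::expand_grid(cell = f0$cell, year = scenario$years) |>
    dplyr::left_join(f0, by = "cell")

  run_chain <- function(traj) {
    bucket_soil_moisture(climate, traj, budyko, bucket) |>
      soil_moisture_deficit() |>
      annual_max_wetland_fraction(params) |>
      annual_max_wetland_area(domain)
  }
  a1 <- run_chain(scenario$forest_traj)
  a0 <- run_chain(control_traj)

  annual <- dplyr::inner_join(
    dplyr::rename(a1, area_s1 = "area_km2"),
    dplyr::rename(a0, area_s0 = "area_km2"),
    by = c("cell", "year")) |>
    dplyr::mutate(delta_km2 = .data$area_s1 - .data$area_s0)

  cells <- annual |>
    dplyr::group_by(.data$cell) |>
    dplyr::summarise(
      baseline_km2 = mean(.data$area_s0),
      delta_end_km2 = .data$delta_km2[which.max(.data$year)],
      .groups = "drop"
    ) |>
    dplyr::mutate(final_km2 = .data$baseline_km2 + .data$delta_end_km2) |>
    loss_relative()

  structure(list(
    scenario = scenario$name,
    national_target_km2 = scenario$national_target_km2,
    annual = annual,
    cells = cells,
    national_loss_km2 = -sum(cells$delta_end_km2),
    missing_cells = missing_cells
  ), class = "wetland_projection")
}

#' Wetland loss relative to a baseline extent
#'
#' Percentage loss per cell, `100 * (baseline - final) / baseline`, defined
#' only where the baseline extent is positive. Gains are never reported as
#' negative losses: cells whose final extent exceeds the baseline get
#' `loss_pct = 0` with the `gain` flag set.
#'
#' @param cells Tibble with columns `baseline_km2` and `final_km2` (other
#'   columns carried through), e.g. the `cells` table of a
#'   `wetland_projection`.
#' @return The input with `loss_pct` (missing where baseline is 0) and `gain`
#'   columns.
#' @export
loss_relative <- function(cells) {
  dplyr::mutate(cells,
    loss_pct = dplyr::if_else(
      .data$baseline_km2 > 0,
      pmax(0, 100 * (.data$baseline_km2 - .data$final_km2) /
             .data$baseline_km2),
      NA_real_),
    gain = .data$baseline_km2 > 0 & .data$final_km2 > .data$baseline_km2
  )
}

#' Histogram of wetland losses in the reporting bins
#'
#' Counts losses in the bins \[2,4), \[4,6), \[6,8), \[8,10) and >10 percent.
#' Losses below 2% are uncounted; a loss of exactly 10% falls in neither
#' \[8,10) nor the strict >10% bin and is uncounted (documented boundary
#' convention).
#'
#' @param loss_pct Numeric loss percentages (NA ignored).
#' @param edges Interior bin edges (default `c(2, 4, 6, 8, 10)`).
#' @return A tibble `bin`, `count` with a row per bin, plus attribute
#'   `n_uncounted`.
#' @export
loss_bins <- function(loss_pct, edges = c(2, 4, 6, 8, 10)) {
  v <- loss_pct[is.finite(loss_pct)]
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  labels <- c(sprintf("%g-%g%%", lo, hi), sprintf(">%g%%", edges[length(edges)]))
  counts <- c(
    purrr::map2_int(lo, hi, ~ sum(v >= .x & v < .y)),
    sum(v > edges[length(edges)])
  )
  out <- tibble(bin = factor(labels, levels = labels), count = counts)
  attr(out, "n_uncounted") <- length(v) - sum(counts)
  out
}

#' @export
print.wetland_projection <- function(x, ...) {
  cat(sprintf("<wetland_projection %s: net attributed loss %.2f km2 across %d cells>\n",
              x$scenario, x$national_loss_km2, nrow(x$cells)))
  invisible(x)
}

#' @export
tidy.wetland_projection <- function(x, ...) x$cells

#' @export
glance.wetland_projection <- function(x, ...) {
  tibble(
    scenario = x$scenario,
    national_target_km2 = x$national_target_km2,
    national_loss_km2 = x$national_loss_km2,
    n_cells = nrow(x$cells),
    n_loss_gt10 = sum(x$cells$loss_pct > 10, na.rm = TRUE),
    n_missing = length(x$missing_cells)
  )
}
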