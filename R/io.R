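#' Write / read gridded fields as coordinate-explicit CSV
#'
#' Gridded fields travel as long-format CSV with explicit `lat` and `lon`
#' coordinate columns (plus any time columns such as `year`, `month`), one
#' row per cell(-timestep). `read_grid()` validates the coordinate columns
#' and raises a `format_error` naming the missing dimension; a file without
#' time columns reads as a static map. The round trip is lossless to within
#' storage precision.
#'
#' @param field Tibble with a `cell` column, value columns, and optional
#'   `year`/`month` columns.
#' @param domain A [make_grid_domain()] domain supplying `lat`/`lon`.
#' @param path File path.
#' @return `write_grid()` returns `path` invisibly; `read_grid()` returns a
#'   tibble with `cell`, `lat`, `lon`, any time columns, and the values.
#' @export
write_grid <- function(field, domain, path) {
  out <- field |>
    dplyr::inner_join(dplyr::select(domain, "cell", "lat", "lon"),
                      by = "cell") |>
    dplyr::relocate("cell", "lat", "lon")
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  for (dim in c("lat", "lon")) {
    if (!dim %in% names(df))
      abort_afw(sprintf("Grid file lacks the '%s' coordinate column.", dim),
                "format_error")
  }
  df
}

#' Write / read a basin membership table as CSV
#'
#' @param basin_table Tibble `cell`, `basin_id`, `protection_level`.
#' @param path File path.
#' @return The path (write) or the tibble with `protection_level` restored
#'   as a factor (read).
#' @export
write_basin_table <- function(basin_table, path) {
  readr::write_csv(basin_table, path)
  invisible(path)
}

#' @rdname write_basin_table
#' @export
read_basin_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  lv <- c("national", "provincial", "municipal_county", "unprotected")
  if ("protection_level" %in% names(df))
    df$protection_level <- factor(df$protection_level, levels = lv)
  df
}

#' Default pipeline configuration
#'
#' All thresholds default to the analysis conventions (1% wetland-cell rule,
#' 10% rice exclusion, 5th-95th percentile outlier screen, loss bins
#' 2/4/6/8/10%); every random stage derives its seed from the single master
#' seed.
#'
#' @param seed Master seed.
#' @param ... Overrides for any element of the default list (`n_lat`,
#'   `n_lon`, `years`, `p_base`, `phi_range`, `interannual_cv`,
#'   `national_increase_km2`, `n_basins`, `calibration` (`"static"` or
#'   `"dynamic"`), `obs_noise_cv`, `wetland_threshold`, `rice_threshold`,
#'   `outlier_pct`, `loss_edges`, `scenario_target_km2`, `scenario_years`,
#'   `out_dir`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    n_lat = 10, n_lon = 20, lat0 = 30,
    years = 2000:2016,
    p_base = 800, phi_range = c(0.3, 3), interannual_cv = 0.15,
    national_increase_km2 = NULL,
    n_basins = 24,
    calibration = "static",
    obs_noise_cv = 0.05,
    wetland_threshold = 0.01,
    rice_threshold = 0.10,
    outlier_pct = c(5, 95),
    loss_edges = c(2, 4, 6, 8, 10),
    scenario_target_km2 = NULL,
    scenario_years = 2017:2035,
    out_dir = NULL
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad))
    abort_afw(paste("Unknown config fields:", paste(bad, collapse = ", ")),
              "invalid_argument")
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match [run_config()] fields.
#' @return A `run_config` list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Run the full analysis pipeline
#'
#' Chains every stage end to end on the synthetic study defined by the
#' configuration: input generation, the S1 bucket run, observation synthesis,
#' wetland-parameter calibration (static or dynamic), S1 - S0 factorial
#' attribution, sensitivity decomposition with outlier screening and zone box
#' statistics, Budyko runoff change at grid and basin scale, the four
#' near-term planting scenarios with loss histograms, and basin protection
#' statistics. Reruns with the same config are bit-identical; if `out_dir`
#' is set, key products are written as CSV and a manifest of md5 hashes is
#' returned.
#'
#' @param cfg A [run_config()] (or a YAML path for [read_config()]).
#' @return A list of class `pipeline_report`; see the elements it documents.
#' @export
run_pipeline <- function(cfg = run_config()) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  seed <- cfg$seed

  study <- gen_study(seed, n_lat = cfg$n_lat, n_lon = cfg$n_lon,
                     lat0 = cfg$lat0, years = cfg$years, p_base = cfg$p_base,
                     phi_range = cfg$phi_range,
                     interannual_cv = cfg$interannual_cv,
                     national_increase_km2 = cfg$national_increase_km2,
                     n_basins = cfg$n_basins)

  # observations synthesised from the S1 world, then calibration against them
  sm_s1 <- bucket_soil_moisture(study$climate, study$forest)
  obs <- gen_observed_wetlands(study$truth, sm_s1,
                               noise_cv = cfg$obs_noise_cv,
                               seed = stage_seed(seed, 6))
  deficit_s1 <- soil_moisture_deficit(sm_s1)
  params <- if (cfg$calibration == "static")
    calibrate_static(obs$static, deficit_s1)
  else
    calibrate_dynamic(obs$annual, deficit_s1)

  attr_run <- historical_attribution(
    study, params,
    wetland_threshold = cfg$wetland_threshold,
    rice_threshold = cfg$rice_threshold)

  sens <- sensitivity_ratios(attr_run$changes)
  included <- dplyr::filter(sens, .data$included)
  screened <- included |>
    dplyr::group_by(.data$zone) |>
    dplyr::group_modify(function(d, g) {
      kept <- drop_outliers(d$dawet_daforest,
                            cfg$outlier_pct[1], cfg$outlier_pct[2])
      d[d$dawet_daforest %in% kept$values, ]
    }) |>
    dplyr::ungroup()
  box <- zone_box_stats(screened, dawet_daforest)

  dq_grid <- grid_delta_runoff(study$climate, study$forest, summarise = TRUE)
  dq_basin <- basin_budyko_delta_q(study$climate, study$forest,
                                   study$basins, study$domain,
                                   summarise = TRUE)

  # basin-level cumulative changes and protection-group regression
  d_area <- attribution_diff(attr_run$annual_area_s1, attr_run$annual_area_s0,
                             area_km2)
  bas_wet <- aggregate_to_basins(d_area, study$basins, study$domain,
                                 area_km2, mode = "sum")
  f_start <- study$forest |>
    dplyr::filter(.data$year == min(.data$year)) |>
    dplyr::select("cell", f0 = "forest_frac")
  d_forest <- study$forest |>
    dplyr::inner_join(f_start, by = "cell") |>
    dplyr::inner_join(dplyr::select(study$domain, "cell", "area_km2"),
                      by = "cell") |>
    dplyr::mutate(d_af = (.data$forest_frac - .data$f0) * .data$area_km2) |>
    dplyr::select("cell", "year", "d_af")
  bas_for <- aggregate_to_basins(d_forest, study$basins, study$domain,
                                 d_af, mode = "sum")
  levels_tbl <- dplyr::distinct(study$basins, .data$basin_id,
                                .data$protection_level)
  reg <- bas_wet |>
    dplyr::inner_join(bas_for, by = c("basin_id", "year")) |>
    dplyr::inner_join(levels_tbl, by = "basin_id") |>
    dplyr::group_by(.data$protection_level, .data$year) |>
    dplyr::summarise(d_awet = sum(.data$area_km2), d_aforest = sum(.data$d_af),
                     .groups = "drop") |>
    dplyr::rename(group = "protection_level") |>
    group_regression()

  # near-term scenarios
  target <- cfg$scenario_target_km2 %||%
    (0.04 * domain_area(study$domain))
  f_now <- study$forest |>
    dplyr::filter(.data$year == max(.data$year)) |>
    dplyr::select("cell", "forest_frac")
  zones <- tibble(
    cell = study$domain$cell,
    zone = climate_zone((study$climate |>
      dplyr::group_by(cell) |>
      dplyr::summarise(phi = mean(.data$pet) / mean(.data$p)))$phi))
  hist_planted <- tibble(cell = study$domain$cell,
                         planted_km2 = attr(study$forest, "planted_km2"))
  clim_proj <- recycle_climate(study$climate, cfg$scenario_years,
                               stage_seed(seed, 7))
  projections <- purrr::map(
    setNames(nm = c("SA", "SA_dry", "SA_mesic", "SA_wet")),
    function(kind) {
      sc <- build_scenario(kind, study$domain, zones, f_now, target,
                           years = cfg$scenario_years,
                           hist_planted = hist_planted)
      project_scenario(sc, clim_proj, study$domain, params)
    })
  bins <- purrr::map(projections, ~ loss_bins(.x$cells$loss_pct,
                                              cfg$loss_edges))

  # basin losses under the SA projection, counted by protection level
  bas_loss <- purrr::map(projections, function(pr) {
    b <- pr$cells |>
      aggregate_to_basins(study$basins, study$domain, baseline_km2,
                          mode = "sum") |>
      dplyr::inner_join(
        aggregate_to_basins(pr$cells, study$basins, study$domain, final_km2,
                            mode = "sum"), by = "basin_id") |>
      loss_relative() |>
      dplyr::inner_join(levels_tbl, by = "basin_id")
    count_basins_exceeding(b)
  })

  report <- list(
    config = cfg,
    params = params,
    sensitivity = sens,
    zone_box = box,
    delta_q_grid = dq_grid,
    delta_q_basin = dq_basin,
    basin_regression = reg,
    projections = projections,
    loss_bins = bins,
    basin_loss_counts = bas_loss,
    national = tibble(
      scenario = names(projections),
      national_loss_km2 = purrr::map_dbl(projections, "national_loss_km2"))
  )

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      params = file.path(cfg$out_dir, "wetland_params.csv"),
      sensitivity = file.path(cfg$out_dir, "sensitivity.csv"),
      zone_box = file.path(cfg$out_dir, "zone_box_stats.csv"),
      national = file.path(cfg$out_dir, "national_loss.csv")
    )
    readr::write_csv(params, paths["params"])
    readr::write_csv(sens, paths["sensitivity"])
    readr::write_csv(box, paths["zone_box"])
    readr::write_csv(report$national, paths["national"])
    report$manifest <- tibble(
      file = basename(paths),
      md5 = unname(tools::md5sum(paths)),
      seed = seed
    )
  }
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  cells: %d  included in sensitivity: %d\n",
              nrow(x$sensitivity), sum(x$sensitivity$included)))
  cat("  national attributed loss by scenario (km2):\n")
  for (i in seq_len(nrow(x$national)))
    cat(sprintf("    %-8s %8.2f\n", x$national$scenario[i],
                x$national$national_loss_km2[i]))
  invisible(x)
}
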