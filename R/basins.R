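#' Aggregate a cell field to basins
#'
#' Exact aggregation of a per-cell (optionally per-year) field to basins,
#' either as a plain sum or as an area-weighted mean. In sum mode the basin
#' totals add up to the domain total by construction.
#'
#' @param field Tibble with `cell`, the value column, and optionally `year`.
#' @param basin_table Tibble `cell`, `basin_id` (and optionally
#'   `protection_level`, carried through).
#' @param domain A [make_grid_domain()] domain (for areas).
#' @param value Value column (tidy-eval).
#' @param mode `"sum"` or `"area_weighted_mean"`.
#' @return A tibble with `basin_id`, optional `year`, and the aggregated
#'   value column.
#' @export
aggregate_to_basins <- function(field, basin_table, domain, value,
                                mode = c("sum", "area_weighted_mean")) {
  mode <- match.arg(mode)
  value <- rlang::enquo(value)
  unknown <- setdiff(field$cell, basin_table$cell)
  if (length(unknown))
    abort_afw(sprintf("%d cell(s) missing from the basin table.",
                      length(unknown)), "invalid_argument")
  cell_area <- setNames(domain$area_km2, domain$cell)
  df <- field |>
    dplyr::inner_join(dplyr::select(basin_table, "cell", "basin_id"),
                      by = "cell") |>
    dplyr::mutate(.cell_area = cell_area[as.character(.data$cell)])
  keys <- intersect(c("basin_id", "year"), names(df))
  df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      dplyr::across(!!value, ~ if (mode == "sum") sum(.x)
                    else sum(.x * .data$.cell_area) / sum(.data$.cell_area)),
      .groups = "drop"
    )
}

#' Basin-scale Budyko runoff change
#'
#' Aggregates precipitation, PET and forest fraction to basins (area-weighted
#' means per year), then applies the Budyko forest-change runoff equation at
#' the basin level with the basin's climatological aridity.
#'
#' @inheritParams aggregate_to_basins
#' @param climate Tibble `cell`, `year`, `p`, `pet`.
#' @param forest Tibble `cell`, `year`, `forest_frac`.
#' @param params A [budyko_params()] object.
#' @param summarise If `TRUE`, one row per basin with the period-total
#'   `delta_q_total` and `delta_q_over_p`.
#' @return A tibble `basin_id`, `year`, `delta_q` (mm yr^-1), or the
#'   per-basin summary.
#' @export
basin_budyko_delta_q <- function(climate, forest, basin_table, domain,
                                 params = budyko_params(),
                                 summarise = FALSE) {
  agg <- function(f, v) aggregate_to_basins(f, basin_table, domain, {{ v }},
                                            mode = "area_weighted_mean")
  bas <- agg(dplyr::select(climate, "cell", "year", "p"), p) |>
    dplyr::inner_join(agg(dplyr::select(climate, "cell", "year", "pet"), pet),
                      by = c("basin_id", "year")) |>
    dplyr::inner_join(agg(forest, forest_frac), by = c("basin_id", "year")) |>
    dplyr::rename(cell = "basin_id")
  out <- grid_delta_runoff(
    dplyr::select(dplyr::mutate(bas, phi = .data$pet / .data$p),
                  "cell", "year", "p", "pet", "phi"),
    dplyr::select(bas, "cell", "year", "forest_frac"),
    params, summarise = summarise) |>
    dplyr::rename(basin_id = "cell")
  out
}

#' Per-group regression of wetland change on forest change
#'
#' For each protection group, the least-squares slope of cumulative wetland
#' area change on cumulative forest area change across years (with
#' intercept), the p-value on the slope, and a significance marker at the
#' 99% level (`"**"`). Groups with degenerate (constant) forest change get a
#' missing slope.
#'
#' @param df Tibble with columns `group`, `year`, `d_awet`, `d_aforest`
#'   (cumulative changes by year).
#' @return A tibble `group`, `slope`, `p_value`, `n`, `signif`.
#' @export
group_regression <- function(df) {
  fit_one <- function(d) {
    n <- nrow(d)
    if (n < 3 || stats::sd(d$d_aforest) == 0)
      return(tibble(slope = NA_real_, p_value = NA_real_, n = n))
    x <- d$d_aforest; y <- d$d_awet
    sxx <- sum((x - mean(x))^2)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    res <- y - mean(y) - slope * (x - mean(x))
    s2 <- sum(res^2) / (n - 2)
    p <- if (s2 == 0) 0 else 2 * pt(-abs(slope / sqrt(s2 / sxx)), df = n - 2)
    tibble(slope = slope, p_value = p, n = n)
  }
  df |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ fit_one(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(signif = dplyr::if_else(
      !is.na(.data$p_value) & .data$p_value < 0.01, "**", ""))
}

#' Count basins exceeding a wetland-loss threshold
#'
#' @param basin_loss Tibble `basin_id`, `loss_pct`, and optionally
#'   `protection_level`.
#' @param threshold Loss threshold in percent (default 10; strict >).
#' @return A list with `overall` (count) and, if protection levels are
#'   present, `by_level` (tibble `protection_level`, `n_exceeding`,
#'   `n_basins`).
#' @export
count_basins_exceeding <- function(basin_loss, threshold = 10) {
  if (threshold <= 0) abort_afw("`threshold` must be > 0.", "invalid_argument")
  exceed <- !is.na(basin_loss$loss_pct) & basin_loss$loss_pct > threshold
  out <- list(overall = sum(exceed))
  if ("protection_level" %in% names(basin_loss)) {
    out$by_level <- basin_loss |>
      dplyr::mutate(exceed = exceed) |>
      dplyr::group_by(.data$protection_level, .drop = FALSE) |>
      dplyr::summarise(n_exceeding = sum(.data$exceed),
                       n_basins = dplyr::n(), .groups = "drop")
  }
  out
}

#' Resolve a basin's protection level from its reserves
#'
#' When a basin contains several reserves the basin is labelled with the
#' highest protection level present (national > provincial >
#' municipal_county > unprotected).
#'
#' @param levels A character or factor vector of reserve levels in a basin.
#' @return The single highest level as a factor.
#' @export
highest_protection <- function(levels) {
  ord <- c("national", "provincial", "municipal_county", "unprotected")
  present <- ord[ord %in% as.character(levels)]
  factor(present[1], levels = ord)
}
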