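#' Generate synthetic gridded climate along an aridity gradient
#'
#' Emulates reanalysis-style annual forcing: mean aridity (PET/P) increases
#' monotonically from the western to the eastern column of the grid, spanning
#' `phi_range` so that all three climate zones (PET/P < 1, 1-2, > 2) are
#' represented when the range spans them. Interannual variability is
#' multiplicative lognormal noise with the stated coefficient of variation,
#' drawn independently for P and PET. Deterministic for a given seed.
#'
#' @param domain A [make_grid_domain()] domain.
#' @param seed Integer seed; same seed, same output.
#' @param phi_range Length-2 positive range of column-mean PET/P
#'   (default `c(0.3, 3)`).
#' @param p_base Mean annual precipitation, mm yr^-1 (default 800).
#' @param years Calendar years covered (default 2000:2016).
#' @param interannual_cv Coefficient of variation of the multiplicative
#'   interannual noise (default 0.15; 0 gives identical years).
#' @return A tibble with columns `cell`, `year`, `p`, `pet`, `phi` (= pet/p).
#' @export
gen_climate <- function(domain, seed, phi_range = c(0.3, 3), p_base = 800,
                        years = 2000:2016, interannual_cv = 0.15) {
  if (length(phi_range) != 2 || any(phi_range <= 0) ||
      phi_range[2] < phi_range[1])
    abort_afw("`phi_range` must be an increasing positive range.",
              "invalid_argument")
  if (p_base <= 0) abort_afw("`p_base` must be > 0.", "invalid_argument")

  n_lon <- attr(domain, "n_lon")
  phi_col <- if (n_lon == 1) mean(phi_range) else
    seq(phi_range[1], phi_range[2], length.out = n_lon)

  withr::with_seed(seed, {
    out <- tidyr::expand_grid(cell = domain$cell, year = years) |>
      dplyr::left_join(dplyr::select(domain, "cell", "col"), by = "cell") |>
      dplyr::mutate(
        p = p_base * noise_factors(dplyr::n(), interannual_cv),
        pet = phi_col[.data$col] * p_base *
          noise_factors(dplyr::n(), interannual_cv),
        phi = .data$pet / .data$p
      ) |>
      dplyr::select("cell", "year", "p", "pet", "phi")
  })
  out
}

# Proportional allocation of a national planted area to cells, respecting
# per-cell capacities: cap saturated cells and redistribute the remainder
# among unsaturated ones until the target is met (water filling).
allocate_area <- function(weights, capacity_km2, target_km2) {
  if (target_km2 == 0) return(rep(0, length(weights)))
  if (sum(capacity_km2) < target_km2 * (1 - 1e-9))
    abort_afw(
      sprintf("Requested area %.1f km2 exceeds plantable capacity %.1f km2 (shortfall %.1f km2).",
              target_km2, sum(capacity_km2), target_km2 - sum(capacity_km2)),
      "infeasible_allocation")
  planted <- rep(0, length(weights))
  remaining <- target_km2
  open <- capacity_km2 > 0 & weights > 0
  for (i in seq_len(length(weights) + 1)) {
    if (remaining <= target_km2 * 1e-12 || !any(open)) break
    share <- weights * open / sum(weights[open])
    add <- pmin(remaining * share, capacity_km2 - planted)
    planted <- planted + add
    remaining <- remaining - sum(add)
    open <- open & (capacity_km2 - planted > 1e-12)
  }
  if (remaining > target_km2 * 1e-3)
    abort_afw("Allocation failed to place the full target within capacity.",
              "infeasible_allocation")
  planted
}

#' Generate a monotone afforestation history
#'
#' Emulates inventory-based annual forest maps: each cell starts from a random
#' initial forest fraction and gains area linearly in time, with the national
#' total gain over the window equal to `national_increase_km2` (conserved to
#' within 0.1%). Gains are allocated proportionally to `spatial_weights`
#' (random by default), capped so no cell exceeds `max_forest_frac`, with the
#' overflow redistributed.
#'
#' @inheritParams gen_climate
#' @param national_increase_km2 Total forest-area gain over the window, km^2.
#' @param start_year,end_year Window bounds (defaults 2000 and 2016).
#' @param f0_range Range of initial forest fractions (default `c(0.05, 0.4)`).
#' @param spatial_weights Optional nonnegative per-cell allocation weights.
#' @param max_forest_frac Per-cell ceiling on forest fraction (default 0.9;
#'   the remainder is reserved non-plantable land).
#' @return A tibble with columns `cell`, `year`, `forest_frac`, plus
#'   attribute `planted_km2` (per-cell total planted area).
#' @export
gen_forest_history <- function(domain, seed, national_increase_km2,
                               start_year = 2000, end_year = 2016,
                               f0_range = c(0.05, 0.4),
                               spatial_weights = NULL,
                               max_forest_frac = 0.9) {
  if (national_increase_km2 < 0)
    abort_afw("`national_increase_km2` must be >= 0.", "invalid_argument")
  years <- start_year:end_year
  n <- nrow(domain)

  withr::with_seed(seed, {
    f0 <- runif(n, f0_range[1], f0_range[2])
    w <- spatial_weights %||% runif(n)
  })
  if (any(w < 0)) abort_afw("Weights must be nonnegative.", "invalid_argument")

  capacity <- pmax(0, max_forest_frac - f0) * domain$area_km2
  planted <- allocate_area(w, capacity, national_increase_km2)
  dfrac <- planted / domain$area_km2

  frac_t <- seq(0, 1, length.out = length(years))
  out <- tidyr::expand_grid(cell = domain$cell, year = years) |>
    dplyr::mutate(
      forest_frac = f0[.data$cell] +
        dfrac[.data$cell] * frac_t[match(.data$year, years)]
    )
  attr(out, "planted_km2") <- planted
  out
}

#' Generate a static rice-paddy fraction mask
#'
#' Each cell is rice-free with probability `1 - rice_prob`; otherwise its
#' static rice fraction is uniform on `rice_frac_range`. Used by the >10%
#' rice-coverage exclusion upstream of wetland trend analysis.
#'
#' @inheritParams gen_climate
#' @param rice_prob Probability a cell contains rice (default 0.15).
#' @param rice_frac_range Range of nonzero rice fractions
#'   (default `c(0.02, 0.4)`).
#' @return A tibble with columns `cell`, `rice_frac`.
#' @export
gen_rice_mask <- function(domain, seed, rice_prob = 0.15,
                          rice_frac_range = c(0.02, 0.4)) {
  if (rice_prob < 0 || rice_prob > 1)
    abort_afw("`rice_prob` must lie in [0, 1].", "invalid_argument")
  withr::with_seed(seed, {
    has_rice <- runif(nrow(domain)) < rice_prob
    frac <- ifelse(has_rice,
                   runif(nrow(domain), rice_frac_range[1], rice_frac_range[2]),
                   0)
  })
  tibble(cell = domain$cell, rice_frac = frac)
}

#' Generate contiguous basins with protection levels
#'
#' Partitions the grid into `n_basins` spatially contiguous basins by seeded
#' multi-source region growing (rook adjacency), then assigns each basin a
#' wetland-protection level sampled from `level_shares`.
#'
#' @inheritParams gen_climate
#' @param n_basins Number of basins (1 to the number of cells).
#' @param level_shares Named nonnegative shares over the protection levels
#'   `national`, `provincial`, `municipal_county`, `unprotected`.
#' @return A tibble with columns `cell`, `basin_id`, `protection_level`
#'   (factor).
#' @export
gen_basins <- function(domain, n_basins, seed,
                       level_shares = c(national = 0.15, provincial = 0.2,
                                        municipal_county = 0.25,
                                        unprotected = 0.4)) {
  n <- nrow(domain)
  if (n_basins < 1 || n_basins > n)
    abort_afw("`n_basins` must lie in [1, n_cells].", "invalid_argument")
  lv <- c("national", "provincial", "municipal_county", "unprotected")
  if (!all(names(level_shares) %in% lv) || any(level_shares < 0) ||
      sum(level_shares) <= 0)
    abort_afw("`level_shares` must be nonnegative shares over the four levels.",
              "invalid_argument")
  shares <- setNames(rep(0, 4), lv)
  shares[names(level_shares)] <- level_shares

  n_lat <- attr(domain, "n_lat"); n_lon <- attr(domain, "n_lon")
  neighbours <- function(i) {
    r <- domain$row[i]; co <- domain$col[i]
    cand <- rbind(c(r - 1, co), c(r + 1, co), c(r, co - 1), c(r, co + 1))
    ok <- cand[, 1] >= 1 & cand[, 1] <= n_lat & cand[, 2] >= 1 & cand[, 2] <= n_lon
    (cand[ok, 1, drop = TRUE] - 1) * n_lon + cand[ok, 2, drop = TRUE]
  }

  withr::with_seed(seed, {
    basin <- rep(NA_integer_, n)
    seeds <- sample.int(n, n_basins)
    basin[seeds] <- seq_len(n_basins)
    frontier <- seeds
    while (anyNA(basin)) {
      # random frontier cell with an unassigned neighbour claims it
      frontier <- frontier[vapply(frontier, function(i)
        anyNA(basin[neighbours(i)]), logical(1))]
      i <- frontier[sample.int(length(frontier), 1)]
      nb <- neighbours(i)
      nb <- nb[is.na(basin[nb])]
      j <- nb[sample.int(length(nb), 1)]
      basin[j] <- basin[i]
      frontier <- c(frontier, j)
    }
    prot <- sample(lv, n_basins, replace = TRUE, prob = shares / sum(shares))
  })

  tibble(cell = domain$cell, basin_id = basin,
         protection_level = factor(prot[basin], levels = lv))
}

#' Generate noisy "observed" wetland products from known truth
#'
#' Builds the two observation surrogates the calibration modes consume, from a
#' soil-moisture series and known per-cell diagnostic parameters: a static
#' long-term maximum extent map (the noiseless maximum of the diagnostic over
#' the whole series) and a dynamic annual-maximum series with multiplicative
#' lognormal noise of coefficient of variation `noise_cv`, clipped to
#' \[0, 1\]. Because the truth is known, calibration can be scored exactly.
#'
#' @param true_params Tibble `cell`, `f_max`, `k`, `d0`, `v`.
#' @param sm A [bucket_soil_moisture()] series (columns `cell`, `year`,
#'   `month`, `sm`, `sm_sat`).
#' @param noise_cv Coefficient of variation of the annual-max noise
#'   (default 0.05; 0 = noiseless).
#' @param seed Integer seed.
#' @return A list with tibbles `static` (`cell`, `static_max_frac`) and
#'   `annual` (`cell`, `year`, `annual_max_frac`).
#' @export
gen_observed_wetlands <- function(true_params, sm, noise_cv = 0.05, seed = 1) {
  deficit <- soil_moisture_deficit(sm)
  annual <- annual_max_wetland_fraction(deficit, true_params)
  static <- annual |>
    dplyr::group_by(.data$cell) |>
    dplyr::summarise(static_max_frac = max(.data$annual_max_frac),
                     .groups = "drop")
  withr::with_seed(seed, {
    annual_noisy <- annual |>
      dplyr::mutate(annual_max_frac = pmin(1, pmax(0,
        .data$annual_max_frac * noise_factors(dplyr::n(), noise_cv))))
  })
  list(static = static, annual = annual_noisy)
}
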