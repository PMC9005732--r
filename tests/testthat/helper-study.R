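# Shared fixtures, generated in code and memoised per test run.
.fixtures <- new.env(parent = emptyenv())

# the standard seeded study: 200 cells spanning all three climate zones
std_study <- function() {
  if (is.null(.fixtures$std)) .fixtures$std <- gen_study(42)
  .fixtures$std
}

# a small, fast study for unit tests
small_study <- function(seed = 7) {
  key <- paste0("small", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- gen_study(seed, n_lat = 4, n_lon = 10, n_basins = 6)
  .fixtures[[key]]
}

# hand-rolled climate/forest tables for pointwise checks
flat_climate <- function(cells, years, p, phi) {
  tidyr::expand_grid(cell = cells, year = years) |>
    dplyr::mutate(p = p, pet = phi * p, phi = phi)
}

flat_forest <- function(cells, years, frac) {
  tidyr::expand_grid(cell = cells, year = years) |>
    dplyr::mutate(forest_frac = frac)
}

# a 6-cell table exercising every exclusion path plus one clean cell:
# 1 no forest, 2 no forest change, 3 sub-threshold wetland, 4 rice-excluded,
# 5 passes the filters but with a wild ratio, 6 clean
six_cell_changes <- function() {
  ann <- tidyr::expand_grid(cell = 1:6, year = 2000:2004) |>
    dplyr::mutate(annual_max_frac = c(0.2, 0.2, 0.005, 0.2, 0.2, 0.2)[cell])
  rice <- tibble::tibble(cell = 1:6,
                         rice_frac = c(0, 0, 0, 0.15, 0, 0))
  mask <- rice_filter(wetland_cell_mask(ann), rice)
  tibble::tibble(
    cell = 1:6,
    d_awet = c(0, -0.5, -1, -1.2, 500, -1.4),
    d_aforest = c(0, 0, 90, 110, 100, 100),
    d_sm = c(0, -0.2, -0.4, -0.5, -0.01, -0.6),
    has_forest = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE)
  ) |>
    dplyr::inner_join(dplyr::select(mask, cell, wetland_cell), by = "cell")
}

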