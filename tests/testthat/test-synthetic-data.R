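test_that("climate generator is seeded, spans the gradient, and respects cv", {
  d <- make_grid_domain(3, 10, lat0 = 32)
  c1 <- gen_climate(d, seed = 5)
  c2 <- gen_climate(d, seed = 5)
  expect_identical(c1, c2)

  # column means of PET/P strictly increasing across the 10 columns
  col_means <- c1 |>
    dplyr::inner_join(dplyr::select(d, cell, col), by = "cell") |>
    dplyr::group_by(col) |>
    dplyr::summarise(phi = mean(phi)) |>
    dplyr::pull(phi)
  expect_true(all(diff(col_means) > 0))

  # zero interannual noise: every year identical
  c0 <- gen_climate(d, seed = 5, interannual_cv = 0)
  per_cell_sd <- c0 |>
    dplyr::group_by(cell) |>
    dplyr::summarise(s = sd(p) + sd(pet))
  expect_true(all(per_cell_sd$s == 0))

  expect_error(gen_climate(d, 1, phi_range = c(-1, 2)),
               class = "invalid_argument")
})

test_that("forest history is monotone, linear, and conserves the target", {
  d1 <- make_grid_domain(1, 1, lat0 = 36)

  # zero increase: constant trajectory
  f0 <- gen_forest_history(d1, seed = 3, national_increase_km2 = 0)
  expect_equal(length(unique(f0$forest_frac)), 1L)

  # 250 km2 over a ~2500 km2 cell raises the fraction by 0.10, linearly
  f <- gen_forest_history(d1, seed = 3, national_increase_km2 = 250)
  rise <- max(f$forest_frac) - min(f$forest_frac)
  expect_equal(rise, 250 / d1$area_km2, tolerance = 1e-12)
  expect_lt(abs(rise - 0.10) / 0.10, 0.05)
  expect_equal(unique(round(diff(f$forest_frac), 12)), round(rise / 16, 12))

  # conservation on a multi-cell domain, within 0.1%
  d <- make_grid_domain(4, 8, lat0 = 30)
  fh <- gen_forest_history(d, seed = 9, national_increase_km2 = 5000)
  dfrac <- fh |>
    dplyr::group_by(cell) |>
    dplyr::summarise(df = max(forest_frac) - min(forest_frac))
  total <- sum(dfrac$df * d$area_km2)
  expect_lt(abs(total - 5000) / 5000, 0.001)
  expect_true(all(fh |>
    dplyr::group_by(cell) |>
    dplyr::summarise(mono = all(diff(forest_frac) >= 0)) |>
    dplyr::pull(mono)))

  # asking for more than the plantable area fails loudly
  expect_error(
    gen_forest_history(d1, seed = 3, national_increase_km2 = 1e7),
    class = "infeasible_allocation")
})

test_that("rice mask is seeded and bounded", {
  d <- make_grid_domain(5, 5, lat0 = 30)
  expect_true(all(gen_rice_mask(d, 1, rice_prob = 0)$rice_frac == 0))
  r1 <- gen_rice_mask(d, 8)
  expect_identical(r1, gen_rice_mask(d, 8))
  nz <- r1$rice_frac[r1$rice_frac > 0]
  expect_true(all(nz >= 0.02 & nz <= 0.4))
})

test_that("basins partition the domain into contiguous regions", {
  d <- make_grid_domain(5, 8, lat0 = 30)
  b <- gen_basins(d, n_basins = 6, seed = 4)
  # partition: every cell in exactly one basin; areas sum to the domain
  expect_equal(sort(b$cell), d$cell)
  basin_area <- d |>
    dplyr::inner_join(b, by = "cell") |>
    dplyr::group_by(basin_id) |>
    dplyr::summarise(a = sum(area_km2))
  expect_equal(sum(basin_area$a), domain_area(d), tolerance = 1e-12)

  # contiguity: each basin is one rook-connected component
  grid <- matrix(b$basin_id, nrow = 5, byrow = TRUE) # row-major cells -> row x col
  for (id in unique(b$basin_id)) {
    cells <- which(grid == id, arr.ind = TRUE)
    seen <- 1L
    frontier <- 1L
    repeat {
      adj <- which(apply(cells, 1, function(rc)
        any(abs(rc[1] - cells[frontier, 1]) + abs(rc[2] - cells[frontier, 2]) == 1)))
      new <- setdiff(adj, seen)
      if (!length(new)) break
      seen <- c(seen, new)
      frontier <- new
    }
    expect_equal(length(seen), nrow(cells))
  }

  # degenerate cases
  b1 <- gen_basins(d, n_basins = nrow(d), seed = 1)
  expect_equal(length(unique(b1$basin_id)), nrow(d))
  bu <- gen_basins(d, 5, seed = 2, level_shares = c(unprotected = 1))
  expect_true(all(bu$protection_level == "unprotected"))
  expect_error(gen_basins(d, 0, seed = 1), class = "invalid_argument")
})

test_that("bucket dries out without rain and closes its budget", {
  cells <- 1:2
  years <- 2000:2004
  dry_clim <- flat_climate(cells, years, p = 1e-9, phi = 1)
  sm <- bucket_soil_moisture(dry_clim, flat_forest(cells, years, 0.2))
  per_cell <- sm |>
    dplyr::group_by(cell) |>
    dplyr::summarise(mono = all(diff(sm) <= 1e-12), final = dplyr::last(sm))
  expect_true(all(per_cell$mono))
  expect_true(all(per_cell$final < 1))

  # budget identity on unclamped steps, machine tolerance
  st <- small_study()
  run <- bucket_soil_moisture(st$climate, st$forest)
  open <- dplyr::filter(run, !clamped)
  resid <- with(open, (sm - sm_start) - (p_month - et - q))
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("more forest means drier soil at fixed climate", {
  cells <- 1:2
  years <- 2000:2016
  clim <- flat_climate(cells, years, p = 800, phi = 2)
  forest <- dplyr::bind_rows(
    flat_forest(1, years, 0.1),
    flat_forest(2, years, 0.5))
  sm <- bucket_soil_moisture(clim, forest)
  means <- sm |>
    dplyr::group_by(cell) |>
    dplyr::summarise(m = mean(sm))
  expect_lt(means$m[means$cell == 2], means$m[means$cell == 1])
})

test_that("observed-wetland products honour their noise contract", {
  st <- small_study()
  sm <- bucket_soil_moisture(st$climate, st$forest)

  noiseless <- gen_observed_wetlands(st$truth, sm, noise_cv = 0, seed = 1)
  recomputed <- annual_max_wetland_fraction(soil_moisture_deficit(sm),
                                            st$truth)
  expect_equal(noiseless$annual$annual_max_frac, recomputed$annual_max_frac,
               tolerance = 1e-12)

  # static max dominates every noiseless annual max
  joined <- dplyr::inner_join(noiseless$annual, noiseless$static, by = "cell")
  expect_true(all(joined$annual_max_frac <= joined$static_max_frac + 1e-12))

  noisy1 <- gen_observed_wetlands(st$truth, sm, noise_cv = 0.05, seed = 33)
  noisy2 <- gen_observed_wetlands(st$truth, sm, noise_cv = 0.05, seed = 33)
  expect_identical(noisy1, noisy2)
  expect_true(all(noisy1$annual$annual_max_frac >= 0 &
                    noisy1$annual$annual_max_frac <= 1))
})
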