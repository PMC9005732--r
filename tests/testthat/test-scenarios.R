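three_zone_domain <- function() {
  d <- make_grid_domain(1, 3, lat0 = 33)
  zones <- tibble::tibble(cell = 1:3,
                          zone = factor(c("wet", "mesic", "dry"),
                                        c("wet", "mesic", "dry")))
  f_now <- tibble::tibble(cell = 1:3, forest_frac = 0.3)
  list(domain = d, zones = zones, f_now = f_now)
}

test_that("zone scenarios plant only in their zone and conserve the target", {
  z <- three_zone_domain()
  sc <- build_scenario("SA_dry", z$domain, z$zones, z$f_now, 300)
  expect_equal(sc$allocation$planted_km2[z$zones$zone == "dry"], 300)
  expect_equal(sc$allocation$planted_km2[z$zones$zone != "dry"], c(0, 0))

  hp <- tibble::tibble(cell = 1:3, planted_km2 = c(10, 30, 60))
  for (kind in c("SA", "SA_dry", "SA_mesic", "SA_wet")) {
    sck <- build_scenario(kind, z$domain, z$zones, z$f_now, 300,
                          hist_planted = hp)
    expect_lt(abs(sum(sck$allocation$planted_km2) - 300) / 300, 0.001)
    expect_true(all(sck$forest_traj$forest_frac <= 0.9 + 1e-12))
    # linear ramp
    one <- dplyr::filter(sck$forest_traj, cell == which.max(sck$allocation$planted_km2))
    expect_equal(length(unique(round(diff(one$forest_frac), 12))), 1L)
  }

  # zero target: constant trajectories
  sc0 <- build_scenario("SA_wet", z$domain, z$zones, z$f_now, 0)
  expect_equal(unique(sc0$forest_traj$forest_frac), 0.3)

  # a zone cannot absorb more than its plantable area
  expect_error(
    build_scenario("SA_dry", z$domain, z$zones, z$f_now, 1e7),
    class = "infeasible_allocation")
})

test_that("SA allocation follows historical planting weights", {
  z <- three_zone_domain()
  hp <- tibble::tibble(cell = 1:3, planted_km2 = c(0, 100, 300))
  sc <- build_scenario("SA", z$domain, z$zones, z$f_now, 400,
                       hist_planted = hp)
  expect_equal(sc$allocation$planted_km2, c(0, 100, 300), tolerance = 1e-9)
})

test_that("projection with zero planting is identical to the control", {
  st <- small_study(3)
  zones <- st$climate |>
    dplyr::group_by(cell) |>
    dplyr::summarise(phi = mean(pet) / mean(p)) |>
    dplyr::mutate(zone = climate_zone(phi))
  f_now <- st$forest |>
    dplyr::filter(year == max(year)) |>
    dplyr::select(cell, forest_frac)
  clim <- recycle_climate(st$climate, 2017:2035, seed = 5)

  sc0 <- build_scenario("SA_dry", st$domain, zones, f_now, 0)
  pr0 <- project_scenario(sc0, clim, st$domain, st$truth)
  expect_true(all(pr0$annual$delta_km2 == 0))
  expect_equal(pr0$national_loss_km2, 0)
  expect_true(all(pr0$cells$loss_pct == 0))

  # monotonicity: more planting in one dry cell cannot lessen its loss
  dry_cell <- zones$cell[zones$zone == "dry"][1]
  plant_one <- function(km2) {
    traj <- tidyr::expand_grid(cell = f_now$cell, year = 2017:2035) |>
      dplyr::left_join(f_now, by = "cell") |>
      dplyr::group_by(cell) |>
      dplyr::mutate(forest_frac = forest_frac +
        (cell == dry_cell) * (km2 / st$domain$area_km2[dry_cell]) *
          seq(0, 1, length.out = 19)) |>
      dplyr::ungroup()
    sc <- sc0
    sc$forest_traj <- traj
    project_scenario(sc, clim, st$domain, st$truth)$cells |>
      dplyr::filter(cell == dry_cell) |>
      dplyr::pull(loss_pct)
  }
  expect_gte(plant_one(500), plant_one(250))
})

test_that("relative loss reports percentages and flags gains", {
  cells <- tibble::tibble(baseline_km2 = c(100, 50, 40, 0),
                          final_km2 = c(88, 50, 44, 5))
  out <- loss_relative(cells)
  expect_equal(out$loss_pct, c(12, 0, 0, NA))
  expect_equal(out$gain, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("loss bins count the reporting intervals with strict edges", {
  b <- loss_bins(c(1, 3, 12))
  expect_equal(b$count, c(1, 0, 0, 0, 1))
  expect_equal(attr(b, "n_uncounted"), 1)

  expect_true(all(loss_bins(numeric(0))$count == 0))

  # exactly 10 falls between [8,10) and the strict >10% bin
  b10 <- loss_bins(c(10, 10.0001, 9.999))
  expect_equal(b10$count, c(0, 0, 0, 1, 1))
  expect_equal(attr(b10, "n_uncounted"), 1)
})
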