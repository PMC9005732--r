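# deficit fixture: 16 years x 12 months whose yearly minimum deficits sweep
# the sigmoid limb, so all three parameters are identifiable
limb_deficits <- function(d_min_by_year = seq(30, 150, length.out = 16)) {
  tidyr::expand_grid(cell = 1L, year = seq_along(d_min_by_year),
                     month = 1:12) |>
    dplyr::mutate(deficit = d_min_by_year[year] + 5 * (month != 6))
}

test_that("soil-moisture deficit is the gap to saturation", {
  sm <- tibble::tibble(cell = 1, year = 2000, month = 1:3,
                       sm = c(300, 0, 250), sm_sat = 300)
  expect_equal(soil_moisture_deficit(sm)$deficit, c(0, 300, 50))
  bad <- dplyr::mutate(sm, sm = c(301, 0, 250))
  expect_error(soil_moisture_deficit(bad), class = "invariant_violation")
})

test_that("the diagnostic sigmoid hits its midpoint, bounds and asymptote", {
  expect_equal(wetland_fraction(50, f_max = 0.3, k = 1, d0 = 50, v = 1), 0.15)
  expect_lt(wetland_fraction(1e4, f_max = 0.9, k = 0.1, d0 = 85), 1e-6)

  # bounded in [0, f_max] and monotone nonincreasing: randomized sweeps
  withr::with_seed(1, {
    for (i in 1:20) {
      f_max <- runif(1); k <- runif(1, 0.01, 1); d0 <- runif(1, 0, 200)
      v <- runif(1, 0.3, 3)
      d <- sort(runif(50, 0, 400))
      f <- wetland_fraction(d, f_max, k, d0, v)
      expect_true(all(f >= 0 & f <= f_max))
      expect_true(all(diff(f) <= 1e-15))
    }
  })
  expect_error(wetland_fraction(-1, 0.3), class = "invalid_argument")
})

test_that("static calibration inverts the sigmoid and is idempotent", {
  expect_equal(
    calibrate_static(tibble::tibble(cell = 1L, static_max_frac = 0),
                     limb_deficits())$f_max, 0)

  # when the minimum deficit sits exactly at d0 (v = 1), f_max = 2 * obs
  shape <- wetland_shape(k = 0.1, d0 = 85, v = 1)
  at_mid <- tidyr::expand_grid(cell = 1L, year = 1:3, month = 1:12) |>
    dplyr::mutate(deficit = 85 + 10 * (month != 6))
  cal <- calibrate_static(tibble::tibble(cell = 1L, static_max_frac = 0.2),
                          at_mid, shape)
  expect_equal(cal$f_max, 0.4, tolerance = 1e-12)

  # the calibrated model reproduces the observation at the min-deficit step,
  # and recalibrating against the model's own maximum returns identical params
  dfx <- limb_deficits()
  cal2 <- calibrate_static(tibble::tibble(cell = 1L, static_max_frac = 0.27),
                           dfx, shape)
  modeled_max <- max(wetland_series(dfx, cal2)$wet_frac)
  expect_equal(modeled_max, 0.27, tolerance = 1e-12)
  cal3 <- calibrate_static(
    tibble::tibble(cell = 1L, static_max_frac = modeled_max), dfx, shape)
  expect_equal(cal2$f_max, cal3$f_max, tolerance = 1e-12)

  expect_error(
    calibrate_static(tibble::tibble(cell = 1L, static_max_frac = 0.2),
                     dplyr::mutate(limb_deficits(), deficit = NA_real_)),
    class = "insufficient_data")
})

test_that("dynamic calibration recovers known parameters from clean data", {
  truth <- tibble::tibble(cell = 1L, f_max = 0.3, k = 0.1, d0 = 85, v = 1)
  dfx <- limb_deficits()
  obs <- annual_max_wetland_fraction(dfx, truth)
  fit <- calibrate_dynamic(obs, dfx)
  expect_true(fit$converged)
  expect_lt(fit$sse, 1e-10)
  expect_lt(abs(fit$f_max - 0.3) / 0.3, 0.01)

  # constant deficits cannot identify the shape: flagged, not raised
  flat <- dplyr::mutate(limb_deficits(), deficit = 100)
  obs_flat <- annual_max_wetland_fraction(flat, truth)
  fit_flat <- calibrate_dynamic(obs_flat, flat)
  expect_false(fit_flat$converged)

  # fewer years than parameters: missing result
  short <- dplyr::filter(dfx, year <= 3)
  fit_short <- calibrate_dynamic(annual_max_wetland_fraction(short, truth),
                                 short)
  expect_false(fit_short$converged)
  expect_true(is.na(fit_short$f_max))
})

test_that("tidy and glance summarise a calibration", {
  truth <- tibble::tibble(cell = 1L, f_max = 0.3, k = 0.1, d0 = 85, v = 1)
  dfx <- limb_deficits()
  fit <- calibrate_dynamic(annual_max_wetland_fraction(dfx, truth), dfx)
  td <- tidy(fit)
  expect_named(td, c("cell", "term", "estimate"))
  expect_equal(nrow(td), 4)
  gl <- glance(fit)
  expect_equal(gl$n_cells, 1)
  expect_equal(gl$n_converged, 1)
})

test_that("annual maximum areas scale with fraction trends and cell area", {
  d <- make_grid_domain(1, 1, lat0 = 36) # ~2500 km2
  years <- 2000:2016
  frac <- tibble::tibble(cell = 1L, year = years,
                         annual_max_frac = 0.05 + 4e-4 * (years - 2000))
  area <- annual_max_wetland_area(frac, d)
  tr <- linear_trend(area$area_km2, area$year)
  expect_equal(tr$slope, 4e-4 * d$area_km2, tolerance = 1e-9)
  expect_lt(abs(tr$slope - 1) / 1, 0.05) # ~1 km2 per year on a ~2500 km2 cell

  expect_true(all(annual_max_wetland_area(
    dplyr::mutate(frac, annual_max_frac = 0), d)$area_km2 == 0))

  d2 <- dplyr::mutate(d, area_km2 = 2 * area_km2)
  expect_equal(annual_max_wetland_area(frac, d2)$area_km2,
               2 * area$area_km2, tolerance = 1e-12)
})
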