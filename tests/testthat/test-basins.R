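test_that("basin aggregation is exact in both modes", {
  d <- make_grid_domain(2, 2, lat0 = 40)
  bt <- tibble::tibble(cell = 1:4, basin_id = c(1, 1, 2, 2))
  field <- tibble::tibble(cell = 1:4, v = c(1, 3, 5, 7))

  sums <- aggregate_to_basins(field, bt, d, v, mode = "sum")
  expect_equal(sum(sums$v), sum(field$v), tolerance = 1e-12)

  # cells 1 and 2 share a latitude row, so equal areas: mean of 1 and 3 is 2
  m <- aggregate_to_basins(field, bt, d, v, mode = "area_weighted_mean")
  expect_equal(dplyr::filter(m, basin_id == 1)$v, 2, tolerance = 1e-12)

  # single-cell basins: aggregation is the identity
  bt1 <- tibble::tibble(cell = 1:4, basin_id = 1:4)
  id <- aggregate_to_basins(field, bt1, d, v, mode = "sum")
  expect_equal(id$v[order(id$basin_id)], field$v)

  expect_error(
    aggregate_to_basins(dplyr::mutate(field, cell = cell + 10), bt, d, v),
    class = "invalid_argument")
})

test_that("basin-scale Budyko runoff change degrades gracefully", {
  years <- 2000:2010
  clim <- flat_climate(1:4, years, p = 900, phi = 1.2)
  d <- make_grid_domain(2, 2, lat0 = 40)
  one_basin <- tibble::tibble(cell = 1:4, basin_id = 1)

  # uniform domain in a single basin equals the per-cell value
  ramp <- tidyr::expand_grid(cell = 1:4, year = years) |>
    dplyr::mutate(forest_frac = 0.1 + 0.01 * (year - 2000))
  bas <- basin_budyko_delta_q(clim, ramp, one_basin, d, summarise = TRUE)
  grid <- grid_delta_runoff(clim, ramp, summarise = TRUE)
  expect_equal(bas$delta_q_total, grid$delta_q_total[1], tolerance = 1e-9)

  # no forest change: zero
  still <- basin_budyko_delta_q(clim, flat_forest(1:4, years, 0.4),
                                one_basin, d, summarise = TRUE)
  expect_equal(still$delta_q_total, 0)

  # two cells, uniform forest change, aridities on the monotone limb of the
  # response curve: the basin value lies between the cell values
  d2 <- make_grid_domain(1, 2, lat0 = 40)
  clim2 <- dplyr::bind_rows(flat_climate(1, years, 900, 1.5),
                            flat_climate(2, years, 900, 2.5))
  ramp2 <- tidyr::expand_grid(cell = 1:2, year = years) |>
    dplyr::mutate(forest_frac = 0.1 + 0.01 * (year - 2000))
  bas2 <- basin_budyko_delta_q(clim2, ramp2,
                               tibble::tibble(cell = 1:2, basin_id = 1),
                               d2, summarise = TRUE)
  cells2 <- grid_delta_runoff(clim2, ramp2, summarise = TRUE)
  expect_lte(abs(bas2$delta_q_total), max(abs(cells2$delta_q_total)) + 1e-12)
  expect_gte(abs(bas2$delta_q_total), min(abs(cells2$delta_q_total)) - 1e-12)
})

test_that("group regressions recover slopes and flag degenerate groups", {
  years <- 2000:2016
  x <- cumsum(runif(17, 10, 30))
  perfect <- tibble::tibble(group = "national", year = years,
                            d_aforest = x, d_awet = -0.01 * x)
  fit <- group_regression(perfect)
  expect_equal(fit$slope, -0.01, tolerance = 1e-12)
  expect_lt(fit$p_value, 1e-10)
  expect_equal(fit$signif, "**")

  flat <- dplyr::mutate(perfect, d_aforest = 5)
  expect_true(is.na(group_regression(flat)$slope))

  withr::with_seed(21, {
    noisy <- tibble::tibble(group = "provincial", year = years,
                            d_aforest = x,
                            d_awet = -0.01 * x + rnorm(17, 0, 0.05))
    fitn <- group_regression(noisy)
    expect_lt(abs(fitn$slope - (-0.01)) / 0.01, 0.1)
  })
})

test_that("threshold exceedance counts split cleanly by protection level", {
  bl <- tibble::tibble(
    basin_id = 1:5,
    loss_pct = c(12, 5, 11, NA, 30),
    protection_level = factor(
      c("national", "national", "provincial", "unprotected", "unprotected"),
      c("national", "provincial", "municipal_county", "unprotected")))
  cnt <- count_basins_exceeding(bl)
  expect_equal(cnt$overall, 3)
  expect_equal(sum(cnt$by_level$n_exceeding), cnt$overall)
  expect_equal(
    cnt$by_level$n_exceeding[cnt$by_level$protection_level == "national"], 1)

  expect_equal(count_basins_exceeding(bl[0, ])$overall, 0)
  # order invariance
  expect_equal(count_basins_exceeding(bl[sample(5), ])$overall, 3)
  expect_error(count_basins_exceeding(bl, threshold = 0),
               class = "invalid_argument")
})

test_that("multi-reserve basins take the highest protection level", {
  expect_equal(as.character(highest_protection(c("municipal_county",
                                                 "national"))), "national")
  expect_equal(as.character(highest_protection("unprotected")), "unprotected")
})
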