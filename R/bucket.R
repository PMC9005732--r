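#' Bucket soil-moisture surrogate parameters
#'
#' Parameters of the monthly single-bucket water balance used as the package's
#' soil-moisture surrogate: storage capacity `sm_sat` (mm), linear drainage
#' coefficient `drainage` (fraction of storage per month), initial storage as
#' a fraction of capacity, and an optional sinusoidal seasonal redistribution
#' of the annual P and PET totals (amplitude 0 = flat 1/12 split, the
#' default).
#'
#' @param sm_sat Storage capacity, mm (default 300).
#' @param drainage Drainage coefficient, month^-1, in (0, 1) (default 0.1).
#' @param sm0_frac Initial storage / capacity (default 0.5).
#' @param seasonal_amplitude Amplitude of the sinusoidal monthly weighting,
#'   in \[0, 1\) (default 0 = flat split).
#' @return A list of class `bucket_params`.
#' @export
bucket_params <- function(sm_sat = 300, drainage = 0.1, sm0_frac = 0.5,
                          seasonal_amplitude = 0) {
  if (sm_sat <= 0 || drainage <= 0 || drainage >= 1 ||
      sm0_frac < 0 || sm0_frac > 1 ||
      seasonal_amplitude < 0 || seasonal_amplitude >= 1)
    abort_afw("Invalid bucket parameters.", "invalid_argument")
  structure(list(sm_sat = sm_sat, drainage = drainage, sm0_frac = sm0_frac,
                 seasonal_amplitude = seasonal_amplitude),
            class = "bucket_params")
}

#' Monthly bucket soil-moisture surrogate
#'
#' A deliberately simple, analytic land-surface surrogate: each cell is a
#' single bucket stepped monthly as
#' \deqn{SM_{t+1} = \mathrm{clamp}(SM_t + P_t - ET_t - Q_t,\ 0,\ SM_{sat})}
#' with \eqn{ET_t = (ET/P)_{Budyko} \cdot P_t \cdot SM_t/SM_{sat}} — the
#' annual Budyko evaporative fraction at the cell's climatological aridity and
#' the cell-year's effective (forest-mixed) `w`, distributed over months and
#' throttled by wetness — and linear drainage \eqn{Q_t = d \cdot SM_t}.
#' Raising forest fraction raises the effective `w`, hence ET, hence lowers
#' equilibrium soil moisture: the monotone forest-to-drying dependence the
#' downstream attribution machinery is built to detect. The water budget
#' closes exactly (\eqn{\Delta SM = P - ET - Q}) on every step where clamping
#' is inactive.
#'
#' @param climate Tibble `cell`, `year`, `p`, `pet` (see [gen_climate()]).
#' @param forest Tibble `cell`, `year`, `forest_frac`; must share cells and
#'   years with `climate`.
#' @param budyko A [budyko_params()] object.
#' @param bucket A [bucket_params()] object.
#' @return A tibble with one row per cell-month: `cell`, `year`, `month`,
#'   `sm_start`, `sm` (end of month), `sm_sat`, `p_month`, `et`, `q`,
#'   `clamped`.
#' @export
bucket_soil_moisture <- function(climate, forest, budyko = budyko_params(),
                                 bucket = bucket_params()) {
  cells <- sort(unique(climate$cell))
  years <- sort(unique(climate$year))
  if (!setequal(cells, unique(forest$cell)) ||
      !setequal(years, unique(forest$year)))
    abort_afw("`climate` and `forest` must share cells and years.",
              "shape_mismatch")

  n_c <- length(cells); n_y <- length(years)
  clim <- dplyr::arrange(climate, .data$year, .data$cell)
  fore <- dplyr::arrange(forest, .data$year, .data$cell)
  p_mat <- matrix(clim$p, n_c, n_y)    # cells x years
  pet_mat <- matrix(clim$pet, n_c, n_y)
  f_mat <- matrix(fore$forest_frac, n_c, n_y)

  phi_clim <- rowMeans(pet_mat) / rowMeans(p_mat)
  # evaporative fraction per cell-year from the mixed coefficient
  et_frac <- matrix(
    et_ratio(rep(phi_clim, n_y), effective_w(as.vector(f_mat), budyko)),
    n_c, n_y)

  m_w <- (1 + bucket$seasonal_amplitude * sin(2 * pi * (0:11) / 12)) / 12
  m_w <- m_w / sum(m_w)

  sm <- rep(bucket$sm0_frac * bucket$sm_sat, n_c)
  n_step <- 12 * n_y
  out_sm0 <- out_sm <- out_p <- out_et <- out_q <- matrix(0, n_c, n_step)
  out_cl <- matrix(FALSE, n_c, n_step)
  for (s in seq_len(n_step)) {
    y <- (s - 1) %/% 12 + 1
    m <- (s - 1) %% 12 + 1
    p_m <- p_mat[, y] * m_w[m]
    et <- et_frac[, y] * p_m * sm / bucket$sm_sat
    q <- bucket$drainage * sm
    raw <- sm + p_m - et - q
    new <- pmin(pmax(raw, 0), bucket$sm_sat)
    out_sm0[, s] <- sm; out_sm[, s] <- new
    out_p[, s] <- p_m; out_et[, s] <- et; out_q[, s] <- q
    out_cl[, s] <- raw != new
    sm <- new
  }

  tidyr::expand_grid(step = seq_len(n_step), cell = cells) |>
    dplyr::mutate(
      year = years[(.data$step - 1) %/% 12 + 1],
      month = (.data$step - 1) %% 12 + 1,
      sm_start = as.vector(out_sm0),
      sm = as.vector(out_sm),
      sm_sat = bucket$sm_sat,
      p_month = as.vector(out_p),
      et = as.vector(out_et),
      q = as.vector(out_q),
      clamped = as.vector(out_cl)
    ) |>
    dplyr::arrange(.data$cell, .data$year, .data$month) |>
    dplyr::select("cell", "year", "month", "sm_start", "sm", "sm_sat",
                  "p_month", "et", "q", "clamped")
}
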