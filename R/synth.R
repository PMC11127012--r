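#' Synthetic weekly estuarine panel generator
#'
#' Seeded generator that emulates the statistical structure the analysis
#' assumes: ~52 weekly observations per year over ~50 years, bimodal
#' chlorophyll seasonality (winter-spring and summer-fall peaks), long-term
#' declines in chlorophyll and most nutrients, warming temperature,
#' log-scale overdispersion, and the characteristic missingness patterns of
#' a long shore-based monitoring program (random point gaps, biweekly
#' sampling stretches, and multi-year block gaps).
#'
#' Chlorophyll is generated on the log scale:
#' `log chl = level + trend * t + bimodal seasonal(week) + sum beta_i z(driver_i, lag_i) + AR(1) noise`,
#' then exponentiated, so values are strictly positive and multiplicative
#' noise spans orders of magnitude as real pigment data do. Drivers are
#' generated first and chlorophyll depends on them, giving a known causal
#' direction for predictive-causality power tests.
#'
#' @name synthetic_data
NULL

#' Configuration for the synthetic panel
#'
#' Defaults describe a 50-year (1970-2019) weekly record of a bimodal
#' temperate estuary: seasonal log-scale bumps centered at weeks 8 and 32,
#' a -0.012 / yr log-linear chlorophyll decline (~45% over 50 years),
#' declining nitrogen nutrients, 0.025 degC / yr warming, AR(1) residuals,
#' 10% random point gaps, biweekly sampling over 1999-2001, and whole-year
#' block gaps for 1995-1998 and 2012.
#'
#' @param n_years number of years.
#' @param start_year first calendar year.
#' @param chl_log_mean mean of log chlorophyll (log mg chl m^-3).
#' @param seasonal_centers,seasonal_widths,seasonal_heights two Gaussian
#'   bumps on the week-of-year axis (log scale): center weeks, SD widths in
#'   weeks, heights in log units.
#' @param chl_trend_per_year log-scale linear trend of chlorophyll.
#' @param ar1_coefficient,noise_sd AR(1) residual structure of log chl.
#' @param exog_effects named list of `list(lag =, beta =)` giving true
#'   coefficients linking standardized drivers to log chl.
#' @param temp_warming_per_year temperature trend (degC / yr).
#' @param nutrient_trends named per-year log-scale trends for the nutrients.
#' @param missingness list: `point_rate` (Bernoulli gap probability),
#'   `biweekly_years` (years sampled every other week), `block_years`
#'   (whole missing years).
#' @param seed integer RNG seed; the generator is deterministic given it.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_years = 50L,
                         start_year = 1970L,
                         chl_log_mean = 1.1,
                         seasonal_centers = c(8, 32),
                         seasonal_widths = c(3, 5),
                         seasonal_heights = c(1.3, 0.8),
                         chl_trend_per_year = -0.012,
                         ar1_coefficient = 0.5,
                         noise_sd = 0.45,
                         exog_effects = list(
                           no32 = list(lag = 1L, beta = -0.25),
                           temp = list(lag = 0L, beta = -0.10)
                         ),
                         temp_warming_per_year = 0.025,
                         nutrient_trends = c(no32 = -0.006, nh4 = -0.005,
                                             po4 = -0.003, sio4 = 0.000),
                         missingness = list(
                           point_rate = 0.10,
                           biweekly_years = 1999:2001,
                           block_years = c(1995:1998, 2012)
                         ),
                         seed = 1L) {
  stopifnot(n_years >= 1, noise_sd > 0,
            abs(ar1_coefficient) < 1,
            length(seasonal_centers) == 2L,
            all(seasonal_widths > 0),
            missingness$point_rate >= 0, missingness$point_rate <= 1)
  structure(as.list(environment()), class = "synth_config")
}

# circular Gaussian bump on the 52-week axis
.bump <- function(week, center, width, height) {
  d <- pmin(abs(week - center), 52 - abs(week - center))
  height * exp(-0.5 * (d / width)^2)
}

.ar1 <- function(n, phi, sd) {
  as.numeric(stats::arima.sim(n = n, list(ar = phi), sd = sd))
}

#' Generate a synthetic panel plus ground truth
#'
#' @param config a [synth_config()].
#' @return list with elements `panel` (a complete [env_panel()]) and
#'   `truth` (class `synth_truth`: noise-free latent log-chl path, trend and
#'   seasonal components, the exogenous contribution, and the true
#'   coefficients). Apply [apply_missingness()] to obtain the observable
#'   panel; `truth$chl` keeps the full values for recovery tests.
#' @export
generate_panel <- function(config = synth_config()) {
  cf <- config
  set.seed(cf$seed)
  n <- cf$n_years * 52L
  week <- rep(1:52, cf$n_years)
  tyr <- (seq_len(n) - 1) / 52
  year <- cf$start_year + (seq_len(n) - 1) %/% 52L

  # --- drivers first (known causal direction) ---
  temp <- 11 + cf$temp_warming_per_year * tyr +
    9 * cos(2 * pi * (week - 31) / 52) + .ar1(n, 0.6, 0.8)
  salinity <- 30 + 0.6 * cos(2 * pi * (week - 45) / 52) + .ar1(n, 0.7, 0.5)
  secchi <- pmax(0.5, 3 + 0.6 * sin(2 * pi * (week - 20) / 52) + .ar1(n, 0.5, 0.4))
  light <- pmax(1, 40 + 22 * cos(2 * pi * (week - 26) / 52) - 0.08 * tyr +
                  .ar1(n, 0.4, 4))
  precip <- stats::rgamma(n, shape = 1.6, scale = 15)
  strat <- pmax(0, 1.2 + 1.0 * cos(2 * pi * (week - 30) / 52) + .ar1(n, 0.5, 0.35))

  nut <- function(base_log, trend, phase, amp, phi = 0.85, sd = 0.25) {
    exp(base_log + trend * tyr + amp * cos(2 * pi * (week - phase) / 52) +
          .ar1(n, phi, sd))
  }
  no32 <- nut(log(4),   cf$nutrient_trends[["no32"]], 2, 0.8)
  nh4  <- nut(log(2.5), cf$nutrient_trends[["nh4"]],  50, 0.5)
  po4  <- nut(log(1),   cf$nutrient_trends[["po4"]],  48, 0.4)
  sio4 <- nut(log(8),   cf$nutrient_trends[["sio4"]], 4, 0.7)

  gsi <- data.frame(year = cf$start_year + 0:(cf$n_years - 1L),
                    gsi = .ar1(cf$n_years, 0.5, 1))

  drivers <- list(temp = temp, salinity = salinity, secchi = secchi,
                  light = light, precip = precip, strat = strat,
                  no32 = no32, nh4 = nh4, po4 = po4, sio4 = sio4)

  # --- chlorophyll depends on the drivers ---
  trend_comp <- cf$chl_log_mean + cf$chl_trend_per_year * tyr
  seas_comp <- .bump(week, cf$seasonal_centers[1], cf$seasonal_widths[1],
                     cf$seasonal_heights[1]) +
               .bump(week, cf$seasonal_centers[2], cf$seasonal_widths[2],
                     cf$seasonal_heights[2])
  exog_comp <- numeric(n)
  betas <- numeric(0)
  for (v in names(cf$exog_effects)) {
    ef <- cf$exog_effects[[v]]
    z <- as.numeric(scale(drivers[[v]]))
    lagged <- c(rep(z[1], ef$lag), z[seq_len(n - ef$lag)])
    exog_comp <- exog_comp + ef$beta * lagged
    betas[paste0(v, if (ef$lag > 0) paste0("_lag", ef$lag) else "")] <- ef$beta
  }
  noise <- .ar1(n, cf$ar1_coefficient, cf$noise_sd)
  log_chl_latent <- trend_comp + seas_comp + exog_comp
  chl <- exp(log_chl_latent + noise)

  mk <- function(v, name, unit) weekly_series(v, cf$start_year, 1L, name, unit)
  panel <- env_panel(list(
    chl = mk(chl, "chl", "mg chl m-3"),
    temp = mk(temp, "temp", "degC"),
    salinity = mk(salinity, "salinity", "psu"),
    secchi = mk(secchi, "secchi", "m"),
    light = mk(light, "light", "E m-2 wk-1"),
    precip = mk(precip, "precip", "mm wk-1"),
    strat = mk(strat, "strat", "kg m-3"),
    no32 = mk(no32, "no32", "uM"),
    nh4 = mk(nh4, "nh4", "uM"),
    po4 = mk(po4, "po4", "uM"),
    sio4 = mk(sio4, "sio4", "uM")
  ), annual = gsi)

  truth <- structure(list(
    log_chl_latent = log_chl_latent,
    trend = trend_comp,
    seasonal = seas_comp,
    exog = exog_comp,
    betas = betas,
    chl = chl,
    year = year, week = week
  ), class = "synth_truth")

  list(panel = panel, truth = truth)
}

#' Mask a complete panel with the configured missingness patterns
#'
#' Applies, in order: whole-year block gaps, biweekly sampling stretches
#' (every second week missing), and Bernoulli point gaps. Observed values
#' are never altered. The masking RNG is seeded by `config$seed + 1` so the
#' same config yields the same panel and mask.
#'
#' @param panel a complete `env_panel`.
#' @param config a [synth_config()].
#' @param variables which series to mask (default: all).
#' @return the masked `env_panel`.
#' @export
apply_missingness <- function(panel, config, variables = names(panel$series)) {
  cf <- config$missingness
  set.seed(config$seed + 1L)
  g <- series_grid(panel$series[[1]])
  if (length(cf$block_years) &&
      !all(cf$block_years %in% g$year)) {
    stop("block gap span outside panel grid")
  }
  drop <- rep(FALSE, nrow(g))
  drop[g$year %in% cf$block_years] <- TRUE
  bi <- g$year %in% cf$biweekly_years & g$week %% 2L == 0L
  drop[bi] <- TRUE
  for (v in variables) {
    point <- stats::runif(nrow(g)) < cf$point_rate
    m <- panel$series[[v]]$mask & !(drop | point)
    vals <- panel$series[[v]]$values
    vals[!m] <- NA_real_
    panel$series[[v]] <- weekly_series(
      vals, panel$series[[v]]$start[["year"]], panel$series[[v]]$start[["week"]],
      name = panel$series[[v]]$name, unit = panel$series[[v]]$unit, mask = m)
  }
  panel
}
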