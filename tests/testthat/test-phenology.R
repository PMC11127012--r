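test_that("bloom threshold is 1.05 x the annual median and order-invariant", {
  expect_equal(bloom_threshold(1:52), 1.05 * 26.5)
  expect_equal(bloom_threshold(sample(1:52)), 1.05 * 26.5)
  expect_equal(bloom_threshold(rep(3, 52)), 3.15)
  expect_error(bloom_threshold(rep(NA_real_, 52)), "all-missing")
  expect_error(bloom_threshold(1:10), "at least 26")
})

test_that("rectangular pulses are detected exactly", {
  y <- rep(1, 52); y[10:14] <- 10
  ev <- detect_blooms(y, 2000)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start_week, 10L)
  expect_equal(ev$end_week, 14L)
  expect_equal(ev$duration_weeks, 5L)
  expect_equal(ev$peak_week, 10L)         # ties resolve to the earliest week
  expect_equal(ev$season, "winter_spring")

  y2 <- rep(1, 52); y2[5:7] <- 8; y2[30:33] <- 6
  ev2 <- detect_blooms(y2, 2000)
  expect_equal(ev2$season, c("winter_spring", "summer_fall"))
  expect_equal(seasonal_metrics(ev2, 2000)$annual_count, 2L)

  expect_equal(nrow(detect_blooms(rep(4, 52), 2000)), 0L)   # constant year
})

test_that("detected events are exactly the maximal above-threshold runs", {
  set.seed(6)
  for (i in 1:20) {
    y <- rlnorm(52, 0, 1)
    ev <- detect_blooms(y, 1990)
    thr <- bloom_threshold(y)
    in_bloom <- rep(FALSE, 52)
    for (r in seq_len(nrow(ev))) in_bloom[ev$start_week[r]:ev$end_week[r]] <- TRUE
    expect_identical(in_bloom, y > thr)                    # union = exceedances
    if (nrow(ev) > 1) {
      expect_true(all(ev$start_week[-1] > ev$end_week[-nrow(ev)] + 1))  # maximal
    }
    # oracle: run count by direct scan
    runs <- rle(y > thr)
    expect_equal(nrow(ev), sum(runs$values))
  }
})

test_that("phenology metrics are invariant to rescaling the year", {
  set.seed(7)
  y <- rlnorm(52, 1, 0.8)
  for (c_ in c(0.01, 1, 250)) {
    expect_equal(detect_blooms(c_ * y, 2000)[, c("start_week", "end_week",
                                                 "peak_week", "season")],
                 detect_blooms(y, 2000)[, c("start_week", "end_week",
                                            "peak_week", "season")])
  }
})

test_that("seasonal metrics summarize events per window", {
  y <- rep(1, 52); y[6:9] <- c(3, 5, 9, 4)
  rec <- seasonal_metrics(detect_blooms(y, 2001), 2001)
  expect_equal(rec$winter_spring_start, 6L)
  expect_equal(rec$winter_spring_peak, 8L)
  expect_equal(rec$winter_spring_duration, 4L)
  expect_equal(rec$winter_spring_count, 1L)
  expect_true(is.na(rec$summer_fall_start))
  expect_equal(rec$summer_fall_count, 0L)
})

test_that("ensemble phenology pools members and sees timing drift", {
  # identical members: zero across-member SD
  y <- rep(rep(1, 52), 3); y[c(10:12, 62:64, 114:116)] <- 9
  ens <- structure(list(values = matrix(y, 156, 4), mask = rep(TRUE, 156),
                        grid = data.frame(year = rep(2000:2002, each = 52),
                                          week = rep(1:52, 3))),
                   class = "imputation_ensemble")
  ph <- phenology_over_ensemble(ens)
  expect_true(all(ph$summary$winter_spring_start_sd == 0, na.rm = TRUE))
  expect_equal(ph$summary$winter_spring_start_median, rep(10, 3))

  # winter bloom drifting earlier by 0.07 wk/yr is recovered as negative trend;
  # the broad annual cycle keeps the winter baseline below the annual median,
  # as in a real bimodal estuary
  hits <- 0L
  for (s in 1:10) {
    set.seed(400 + s)
    n_yr <- 40
    vals <- unlist(lapply(seq_len(n_yr), function(j) {
      center <- 12 - 0.07 * (j - 1)
      w <- 1:52
      exp(0.5 + 0.8 * cos(2 * pi * (w - 26) / 52) +
          1.5 * exp(-0.5 * ((w - center) / 2.5)^2) + rnorm(52, 0, 0.3))
    }))
    ph2 <- annual_phenology(vals, years = 1980:(1980 + n_yr - 1))
    tr <- trend_rate_days_per_decade(ph2$year, ph2$winter_spring_start)
    if (tr$rate < 0) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("imputation leaves bloom timing essentially unchanged", {
  cfg <- synth_config(n_years = 25, seed = 12,
                      missingness = list(point_rate = 0.1,
                                         biweekly_years = integer(0),
                                         block_years = integer(0)))
  gen <- generate_panel(cfg)
  masked <- apply_missingness(gen$panel, cfg)
  imp <- impute_panel(masked, M = 15, seed = 3)
  ph_true <- annual_phenology(gen$panel$series$chl)
  ph_imp <- phenology_over_ensemble(imp$ensemble)
  merged <- merge(ph_true[, c("year", "winter_spring_start")],
                  ph_imp$summary[, c("year", "winter_spring_start_median")])
  ok <- abs(merged$winter_spring_start -
            merged$winter_spring_start_median) <= 1
  expect_gte(mean(ok, na.rm = TRUE), 0.9)
})

test_that("Poisson GLM matches a direct likelihood-maximization oracle", {
  set.seed(9)
  X <- data.frame(year = 1:30, z = rnorm(30))
  lam <- exp(2 - 0.02 * X$year + 0.1 * X$z)
  y <- rpois(30, lam)
  fit <- poisson_glm(y, X)
  oracle <- poisson_ml_oracle(y, X)
  expect_equal(fit$coef$estimate, unname(oracle), tolerance = 1e-6)
  expect_error(poisson_glm(c(1.5, 2), data.frame(a = 1:2)), "integer")
})

test_that("Poisson year-slope is recovered and null slopes stay null", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(500 + s)
    yr <- 1970:2019
    y <- rpois(50, exp(2 - 0.01 * (yr - 1970)))
    fit <- poisson_glm(y, data.frame(year = yr - 1970))
    est <- fit$coef[fit$coef$term == "year", ]
    if (abs(est$estimate - (-0.01)) <= 2 * est$se) hits <- hits + 1L
  }
  expect_gte(hits, 18L)

  fit0 <- poisson_glm(rep(7L, 40), data.frame(year = 1:40))
  z <- fit0$coef$z[fit0$coef$term == "year"]
  expect_lt(abs(z), 2)
})

test_that("weekly slopes convert exactly to days per decade", {
  yrs <- 2000:2019
  wk <- 20 - 0.07 * (yrs - 2000)
  tr <- trend_rate_days_per_decade(yrs, wk)
  expect_equal(tr$rate, -4.9, tolerance = 1e-10)
  expect_equal(tr$se, 0, tolerance = 1e-8)
  tr0 <- trend_rate_days_per_decade(yrs, rep(8, 20))
  expect_equal(tr0$rate, 0)
})
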