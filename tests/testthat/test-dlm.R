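# Known-variance local level spec used by several oracle checks
ll_spec <- function(v, w, m0 = 0, c0 = 1e6) {
  dlm_spec(slope = FALSE, harmonics = 0, obs_variance = v,
           W = matrix(w, 1, 1), prior_mean = m0, prior_cov = matrix(c0, 1, 1))
}

test_that("filter reduces to the data in the diffuse single-observation limit", {
  mom <- kalman_filter(ll_spec(1, 0.1), 7.3)
  expect_equal(mom$m[1, 1], 7.3, tolerance = 1e-5)
})

test_that("filtered means equal a hand-coded scalar Kalman recursion", {
  y <- c(2.1, 1.4, 3.0, 2.2, 2.8)
  mom <- kalman_filter(ll_spec(0.5, 0.2, m0 = 1, c0 = 4), y)
  oracle <- local_level_filter_oracle(y, v = 0.5, w = 0.2, m0 = 1, c0 = 4)
  expect_equal(mom$m[1, ], oracle$m, tolerance = 1e-10)
  expect_equal(mom$C[1, 1, ], oracle$C, tolerance = 1e-10)
})

test_that("one-step forecasts converge to a constant series", {
  mom <- kalman_filter(ll_spec(0.01, 0), rep(5, 30))
  expect_equal(mom$f[30], 5, tolerance = 1e-3)
})

test_that("smoothed moments equal brute-force joint-Gaussian conditioning", {
  set.seed(11)
  for (case in 1:4) {
    T_ <- sample(5:10, 1)
    y <- rnorm(T_, 3, 1)
    if (case >= 3) y[sample(T_, 2)] <- NA       # interior gaps
    spec <- if (case %% 2 == 1) {
      ll_spec(0.4, 0.15, m0 = 2, c0 = 3)
    } else {
      dlm_spec(slope = TRUE, harmonics = 1, period = 4, obs_variance = 0.4,
               W = diag(c(0.1, 0.01, 0.05, 0.05)),
               prior_mean = c(2, 0, 0, 0), prior_cov = diag(2, 4))
    }
    mom <- kalman_smooth(kalman_filter(spec, y))
    oracle <- dlm_conditioning_oracle(spec$F, spec$G, spec$W,
                                      spec$obs_variance, spec$prior_mean,
                                      spec$prior_cov, y)
    expect_equal(mom$sm, oracle$mean, tolerance = 1e-8)
    proj_var <- vapply(seq_len(T_), function(t)
      sum(spec$F * (mom$sC[, , t] %*% spec$F)), numeric(1))
    expect_equal(proj_var, oracle$var_proj, tolerance = 1e-8)
  }
})

test_that("smoother boundary and interpolation identities hold", {
  set.seed(2)
  y <- rnorm(12, 5)
  mom <- kalman_smooth(kalman_filter(ll_spec(0.3, 0.1), y))
  expect_equal(mom$sm[, 12], mom$m[, 12])       # last smoothed == last filtered
  y2 <- c(4.8, 5.1, NA, 5.5, 5.4)
  m2 <- kalman_smooth(kalman_filter(ll_spec(0.3, 0.1), y2))
  gap <- m2$sm[1, 3]
  expect_true(gap > min(m2$sm[1, c(2, 4)]) && gap < max(m2$sm[1, c(2, 4)]))
})

test_that("adding an observation never increases posterior variance there", {
  y <- c(1.2, 0.8, NA, 1.1, 0.9)
  v_with_gap <- kalman_smooth(kalman_filter(ll_spec(0.3, 0.1), y))$sC[1, 1, 3]
  y[3] <- 1.0
  v_obs <- kalman_smooth(kalman_filter(ll_spec(0.3, 0.1), y))$sC[1, 1, 3]
  expect_lt(v_obs, v_with_gap)
})

test_that("log-likelihood depends only on data and spec, not time labels", {
  vals <- rlnorm(60, 1, 0.4)
  s1 <- weekly_series(vals, 1970, name = "chl")
  s2 <- weekly_series(vals, 2001, start_week = 17, name = "chl")
  spec <- dlm_spec(harmonics = 2, transform = "log")
  expect_identical(kalman_filter(spec, s1)$loglik,
                   kalman_filter(spec, s2)$loglik)
})

test_that("all-missing input errors", {
  expect_error(kalman_filter(ll_spec(1, 1), rep(NA_real_, 5)), "all-missing")
})

test_that("FFBS honors observed weeks, the seed, and the smoothed mean", {
  set.seed(8)
  y <- 5 + sin(2 * pi * (1:80) / 26) + rnorm(80, 0, 0.3)
  y[c(20:25, 60)] <- NA
  spec <- dlm_spec(harmonics = 2, period = 26)
  e1 <- ffbs_sample(spec, y, M = 50, seed = 3)
  e2 <- ffbs_sample(spec, y, M = 50, seed = 3)
  expect_identical(e1$values, e2$values)
  obs <- which(!is.na(y))
  expect_true(all(e1$values[obs, ] == y[obs]))
  miss <- which(is.na(y))
  expect_true(all(apply(e1$values[miss, , drop = FALSE], 1, sd) > 0))

  # ensemble mean at gaps approaches the smoothed mean (M = 1000, 3 MC SE)
  e3 <- ffbs_sample(spec, y, M = 1000, seed = 5)
  mom <- kalman_smooth(kalman_filter(spec, y))
  sm_mean <- drop(crossprod(spec$F, mom$sm))
  for (t in miss) {
    mc_se <- sd(e3$values[t, ]) / sqrt(1000)
    expect_lt(abs(mean(e3$values[t, ]) - sm_mean[t]), 3 * mc_se + 1e-9)
  }
})

test_that("decomposition separates trend from seasonal structure", {
  t_ <- 1:312
  pure_seas <- 10 + 2 * sin(2 * pi * t_ / 52)
  spec <- dlm_spec(obs_variance = 1e-4, discount_trend = 1, discount_seasonal = 1)
  d <- dlm_decompose(spec, pure_seas)
  expect_gt(var(d$seasonal) / var(pure_seas), 0.99)
  expect_lt(sd(d$trend[60:312]), 0.1)

  ramp <- seq(1, 10, length.out = 312)
  d2 <- dlm_decompose(spec, ramp)
  expect_gt(cor(d2$trend[60:312], ramp[60:312]), 0.999)
  expect_lt(sd(d2$seasonal[60:312]), 0.05)
})

test_that("recovered long-term trend tracks the generator truth", {
  g <- generate_panel(synth_config(seed = 1))
  d <- dlm_decompose(dlm_spec(transform = "log", discount_trend = 0.999),
                     g$panel$series$chl)
  expect_gt(cor(d$trend, g$truth$trend), 0.9)
  expect_equal(nrow(d$seasonal_annual_mean), 50L)
})

test_that("impute_panel completes drivers below their marginal noise level", {
  gen <- tiny_panel(seed = 4, n_years = 10)
  cfg <- synth_config(n_years = 10, seed = 4,
                      missingness = list(point_rate = 0.15,
                                         biweekly_years = integer(0),
                                         block_years = integer(0)))
  masked <- apply_missingness(gen$panel, cfg)
  imp <- impute_panel(masked, M = 5, seed = 2)
  expect_true(all(!is.na(imp$panel$series$temp$values)))
  miss <- !masked$series$temp$mask
  rmse <- sqrt(mean((imp$panel$series$temp$values[miss] -
                     gen$panel$series$temp$values[miss])^2))
  expect_lt(rmse, sd(gen$panel$series$temp$values))
  # ensemble members agree with data at observed weeks
  obsw <- masked$series$chl$mask
  expect_equal(imp$ensemble$values[obsw, ],
               matrix(masked$series$chl$values[obsw], sum(obsw), 5),
               tolerance = 1e-12)
})

test_that("a panel with no gaps imputes to itself", {
  gen <- tiny_panel(seed = 6, n_years = 4)
  imp <- impute_panel(gen$panel, M = 3, seed = 1)
  expect_equal(imp$ensemble$values,
               matrix(gen$panel$series$chl$values, 208, 3))
  expect_equal(imp$panel$series$no32$values, gen$panel$series$no32$values)
})
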