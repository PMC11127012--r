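mk_series <- function(vals, start_year = 1970) {
  weekly_series(vals, start_year, name = "chl")
}

test_that("annual summaries aggregate complete years correctly", {
  s <- mk_series(c(rep(2, 52), rep(c(1, 3), 26)))
  a <- annual_summaries(s)
  expect_equal(a$cumulative, c(104, 104))
  expect_equal(a$mean, c(2, 2))
  expect_equal(a$cv[1], 0)
  expect_equal(a$cumulative, 52 * a$mean)
  expect_equal(a$sd[2], sd(rep(c(1, 3), 26)))
  # partial years are excluded
  s2 <- mk_series(rep(5, 60))
  expect_message(a2 <- annual_summaries(s2), "partial")
  expect_equal(nrow(a2), 1L)
})

test_that("annual CV is scale invariant", {
  set.seed(1)
  v <- rlnorm(104, 1, 0.7)
  a1 <- annual_summaries(mk_series(v))
  a2 <- annual_summaries(mk_series(17 * v))
  expect_equal(a1$cv, a2$cv, tolerance = 1e-12)
})

test_that("decade comparison reproduces the closed-form Welch t", {
  summ <- data.frame(year = c(1971:1973, 1981:1983),
                     cumulative = c(1, 2, 3, 4, 5, 6))
  d <- decade_compare(summ, decade_spec("first", 1971, 1973),
                      decade_spec("last", 1981, 1983))
  # closed form: means 2 and 5, each var 1, n 3 -> t = -3/sqrt(2/3) = -3.674
  expect_equal(d$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(d$percent_change, 150)
  same <- decade_compare(rbind(summ, summ), decade_spec("a", 1971, 1973),
                         decade_spec("a2", 1971, 1973))
  expect_equal(same$t, 0)
  expect_equal(same$percent_change, 0)
  expect_error(decade_compare(summ, decade_spec("x", 1971, 1971),
                              decade_spec("y", 1981, 1983)), "2 years")
})

test_that("log-linear trend fits are exact on exponential inputs", {
  yrs <- 1970:1999
  f <- loglinear_trend(exp(-0.02 * yrs + 51.75), yrs)
  expect_equal(f$slope, -0.02, tolerance = 1e-10)
  expect_equal(f$intercept, 51.75, tolerance = 1e-7)
  expect_equal(f$r_squared, 1, tolerance = 1e-8)

  f0 <- loglinear_trend(rep(3, 30), yrs)
  expect_equal(f0$slope, 0)
  expect_equal(f0$r_squared, 0)

  # scaling values shifts only the intercept
  set.seed(2)
  v <- rlnorm(30, 2, 0.5)
  fa <- loglinear_trend(v, yrs); fb <- loglinear_trend(5 * v, yrs)
  expect_equal(fa$slope, fb$slope, tolerance = 1e-12)
  expect_equal(fb$intercept - fa$intercept, log(5), tolerance = 1e-10)
  expect_equal(fa$r_squared, fb$r_squared, tolerance = 1e-12)
  expect_error(loglinear_trend(c(1, -1, 2), 1971:1973), "1972")
})

test_that("OLS inside loglinear_trend equals the normal equations", {
  set.seed(3)
  yrs <- 1980:1999
  v <- rlnorm(20, 1, 0.4)
  f <- loglinear_trend(v, yrs)
  X <- cbind(1, yrs)
  beta <- solve(t(X) %*% X, t(X) %*% log(v))
  expect_equal(c(f$intercept, f$slope), drop(beta), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("decadal climatology averages weeks within decades", {
  set.seed(4)
  v <- rlnorm(52 * 20, 1, 0.5)
  s <- mk_series(v, 1970)
  decs <- list(decade_spec("d1", 1970, 1979), decade_spec("d2", 1980, 1989))
  cl <- decadal_climatology(s, decs)
  expect_equal(dim(cl), c(52L, 2L))
  expect_equal(mean(cl[, "d1"]), mean(v[1:520]))     # profile mean = grand mean
  one <- decadal_climatology(s, list(decade_spec("y", 1970, 1970)))
  expect_equal(unname(one[, 1]), v[1:52])            # single-year decade

  g <- generate_panel(synth_config(n_years = 20, seed = 8))
  cl2 <- decadal_climatology(g$panel$series$chl,
                             list(decade_spec("a", 1970, 1979),
                                  decade_spec("b", 1980, 1989)))
  for (j in 1:2) {
    prof <- cl2[, j]
    expect_gt(which.max(prof[1:20]), 3)   # winter-spring peak, interior
    expect_gt(max(prof[22:45]), max(prof[17:21]))  # second mode present
  }
})

test_that("AD statistic reproduces the reference implementation on a fixture", {
  set.seed(42)
  s1 <- round(rnorm(12), 4); s2 <- round(rnorm(15, 0.5), 4)
  s3 <- round(c(rnorm(8), 1, 1, 1), 4)
  r <- ad_ksample(list(s1, s2, s3))
  # frozen from scipy.stats.anderson_ksamp (midrank variant), same data
  expect_equal(r$T, 0.47030430335343554, tolerance = 1e-8)
  expect_equal(r$p, 0.2458, tolerance = 0.02)
})

test_that("AD separates shifted samples and accepts exchangeable ones", {
  set.seed(5)
  a <- rnorm(50); b <- rnorm(50, 3)
  expect_lt(ad_ksample(list(a, b), method = "asymptotic")$p, 0.001)
  expect_lt(ad_ksample(list(a, b), method = "permutation", n_perm = 2000,
                       seed = 1)$p, 0.001)
  same <- rnorm(30)
  expect_gte(ad_ksample(list(same, same), method = "permutation",
                        n_perm = 500, seed = 2)$p, 0.9)
  ident <- rep(2.5, 20)
  expect_equal(ad_ksample(list(ident, ident))$p, 1)
})

test_that("AD is invariant under joint monotone transforms", {
  set.seed(6)
  x <- list(rlnorm(40), rlnorm(40, 0.5), rlnorm(40, -0.3))
  r1 <- ad_ksample(x)
  r2 <- ad_ksample(lapply(x, log))
  r3 <- ad_ksample(lapply(x, function(v) v^3))
  expect_equal(r1$A2, r2$A2, tolerance = 1e-12)
  expect_equal(r1$A2, r3$A2, tolerance = 1e-12)
})

test_that("pairwise decade matrix is symmetric and flags the matching pair", {
  set.seed(7)
  base <- rlnorm(52, 1, 0.6)
  v <- c(base + 0, base + 3, rlnorm(52, 2.2, 0.3))   # decades 1 and 2 share shape
  s <- mk_series(v, 2000)
  decs <- list(decade_spec("p", 2000, 2000), decade_spec("q", 2001, 2001),
               decade_spec("r", 2002, 2002))
  pt <- pairwise_decade_tests(s, decs, method = "asymptotic")
  expect_equal(pt$p, t(pt$p))
  expect_true(all(pt$p >= 0 & pt$p <= 1, na.rm = TRUE))
})
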