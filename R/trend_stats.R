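#' Long-term trend statistics
#'
#' Annual aggregation of weekly chlorophyll, decadal comparisons (Welch t),
#' log-linear trend fits, decadal weekly climatologies, and the
#' Scholz-Stephens k-sample Anderson-Darling test with midrank tie
#' handling.
#'
#' @name trend_stats
NULL

#' Annual summaries of a complete weekly series
#'
#' Per complete (52-week) year: cumulative value, mean, sample SD, CV (%),
#' max, min. Partial years are excluded with a message.
#'
#' @param series a complete `weekly_series`.
#' @return data.frame `year, cumulative, mean, sd, cv, max, min`.
#' @export
annual_summaries <- function(series) {
  g <- series_grid(series)
  vals <- series$values
  rows <- lapply(split(seq_len(nrow(g)), g$year), function(idx) {
    yr <- g$year[idx[1]]
    if (length(idx) < 52L || anyNA(vals[idx])) {
      message(sprintf("excluding partial year %d", yr))
      return(NULL)
    }
    v <- vals[idx]
    data.frame(year = yr, cumulative = sum(v), mean = mean(v),
               sd = stats::sd(v), cv = 100 * stats::sd(v) / mean(v),
               max = max(v), min = min(v))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Compare a per-year field between two decades
#'
#' Welch two-sample t-test (the default; `var.equal = TRUE` gives the
#' pooled variant) on the per-year values of `field`, plus the percent
#' change of the last-decade mean relative to the first.
#'
#' @param summaries output of [annual_summaries()] (any per-year
#'   data.frame with a `year` column works).
#' @param first,last [decade_spec()]s.
#' @param field column to compare (e.g. `"cumulative"`, `"cv"`, `"max"`).
#' @param var.equal pooled-variance t-test instead of Welch.
#' @return list `t, df, p, percent_change, mean_first, mean_last`.
#' @export
decade_compare <- function(summaries, first, last, field = "cumulative",
                           var.equal = FALSE) {
  pick <- function(d) {
    v <- summaries[[field]][summaries$year >= d$first_year &
                            summaries$year <= d$last_year]
    if (length(v) < 2) stop("need at least 2 years per decade")
    v
  }
  v1 <- pick(first); v2 <- pick(last)
  tt <- stats::t.test(v1, v2, var.equal = var.equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       percent_change = 100 * (mean(v2) - mean(v1)) / mean(v1),
       mean_first = mean(v1), mean_last = mean(v2))
}

#' Log-linear trend of yearly values
#'
#' OLS of `ln(value)` on calendar year. Scaling all values by c > 0 shifts
#' only the intercept (by ln c); slope, R-squared and p are scale-free.
#'
#' @param values positive yearly values.
#' @param years calendar years.
#' @return list `slope, intercept, r_squared, p, transform`.
#' @export
loglinear_trend <- function(values, years) {
  stopifnot(length(values) == length(years))
  if (any(values <= 0)) {
    stop(sprintf("nonpositive value in year %d", years[which(values <= 0)[1]]))
  }
  lv <- log(values)
  if (stats::var(lv) < 1e-12) {           # constant input: flat fit by definition
    return(list(slope = 0, intercept = mean(lv), r_squared = 0,
                p = NA_real_, transform = "log"))
  }
  fit <- stats::lm(lv ~ years)
  sm <- suppressWarnings(summary(fit))    # exact fits trip a benign lm warning
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p = if (sm$sigma > 0) sm$coefficients[2, 4] else 0,
       transform = "log")
}

#' Decadal weekly climatologies
#'
#' @param series complete `weekly_series`.
#' @param decades list of [decade_spec()]s.
#' @return 52 x n_decades matrix of week-of-year means, columns named by
#'   decade label.
#' @export
decadal_climatology <- function(series, decades) {
  g <- series_grid(series)
  lab <- assign_decades(g$year, decades)
  out <- sapply(decades, function(d) {
    idx <- which(lab == d$label)
    as.numeric(tapply(series$values[idx], g$week[idx], mean))
  })
  colnames(out) <- vapply(decades, function(d) d$label, character(1))
  rownames(out) <- 1:52
  out
}

# ---- k-sample Anderson-Darling (Scholz & Stephens), midrank tie version ----

.ad_statistic <- function(samples) {
  k <- length(samples)
  n <- lengths(samples)
  N <- sum(n)
  z <- sort(unlist(samples, use.names = FALSE))
  zu <- unique(z)
  L <- length(zu)
  lj <- tabulate(match(z, zu), nbins = L)
  Bj <- cumsum(lj) - lj / 2
  inner <- 0
  for (i in seq_len(k)) {
    fij <- tabulate(match(samples[[i]], zu), nbins = L)
    Mij <- cumsum(fij) - fij / 2
    denom <- Bj * (N - Bj) - N * lj / 4
    term <- (lj / N) * (N * Mij - n[i] * Bj)^2 / denom
    term[denom <= 0] <- 0           # degenerate cells (e.g. single distinct value)
    inner <- inner + sum(term) / n[i]
  }
  (N - 1) / N * inner
}

.ad_variance <- function(n) {
  k <- length(n); N <- sum(n)
  H <- sum(1 / n)
  h <- sum(1 / seq_len(N - 1))
  i <- seq_len(N - 2)
  # g = sum_{i=1}^{N-2} sum_{j=i+1}^{N-1} 1/((N-i) j)
  csum <- cumsum(1 / seq_len(N - 1))
  g <- sum((csum[N - 1] - csum[i]) / (N - i))
  a <- (4 * g - 6) * (k - 1) + (10 - 6 * g) * H
  b <- (2 * g - 4) * k^2 + 8 * h * k + (2 * g - 14 * h - 4) * H - 8 * h + 4 * g - 6
  cc <- (6 * h + 2 * g - 2) * k^2 + (4 * h - 4 * g + 6) * k + (2 * h - 6) * H + 4 * h
  d <- (2 * h + 6) * k^2 - 4 * h * k
  (a * N^3 + b * N^2 + cc * N + d) / ((N - 1) * (N - 2) * (N - 3))
}

# cache of standardized limit-law draws, per k
.ad_cache <- new.env(parent = emptyenv())

# The asymptotic null law of A2 is sum_j chisq_{k-1} / (j (j+1)); the
# standardized statistic converges to the standardization of that sum.
# Tabulated once per k by a large fixed-seed draw (truncation j <= 200 with
# a mean correction for the tail), kept sorted for ecdf lookup.
.ad_limit_draws <- function(k, n_draws = 2e5, J = 200L) {
  key <- as.character(k)
  if (!is.null(.ad_cache[[key]])) return(.ad_cache[[key]])
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(794613L + k)
  S <- numeric(n_draws)
  for (j in seq_len(J)) {
    S <- S + stats::rchisq(n_draws, df = k - 1) / (j * (j + 1))
  }
  S <- S + (k - 1) / (J + 1)                       # tail mean
  sigma_inf <- sqrt(2 * (k - 1) * (pi^2 / 3 - 3))
  draws <- sort((S - (k - 1)) / sigma_inf)
  .ad_cache[[key]] <- draws
  draws
}

#' k-sample Anderson-Darling test
#'
#' Rank-based test that k samples share one continuous distribution
#' (Scholz-Stephens statistic, midrank tie adjustment). The standardized
#' statistic `T = (A2 - (k-1)) / sigma_N` is referred either to the
#' asymptotic null law (a weighted chi-square sum, tabulated internally) or
#' to a seeded permutation distribution.
#'
#' @param samples list of k numeric vectors (k >= 2, each n >= 5).
#' @param method `"asymptotic"` or `"permutation"`.
#' @param n_perm number of permutations (>= 2000 recommended).
#' @param seed permutation seed.
#' @return object of class `ad_result`: `k`, `n`, `A2`, `T` (standardized),
#'   `sigma`, `p`, `method`.
#' @export
ad_ksample <- function(samples, method = c("asymptotic", "permutation"),
                       n_perm = 2000L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(length(samples) >= 2, all(lengths(samples) >= 5))
  samples <- lapply(samples, as.numeric)
  n <- lengths(samples)
  if (length(unique(unlist(samples))) == 1L) {
    return(structure(list(k = length(samples), n = n, A2 = 0, T = NA_real_,
                          sigma = NA_real_, p = 1, method = method),
                     class = "ad_result"))
  }
  A2 <- .ad_statistic(samples)
  sigma <- sqrt(.ad_variance(n))
  Tstat <- (A2 - (length(samples) - 1)) / sigma
  if (method == "asymptotic") {
    draws <- .ad_limit_draws(length(samples))
    p <- mean(draws > Tstat)
    p <- min(max(p, 1 / length(draws)), 1)
  } else {
    set.seed(seed)
    pool <- unlist(samples, use.names = FALSE)
    idx_end <- cumsum(n); idx_start <- idx_end - n + 1
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample(pool)
      ps <- lapply(seq_along(n), function(i) perm[idx_start[i]:idx_end[i]])
      if (.ad_statistic(ps) >= A2 - 1e-12) cnt <- cnt + 1L
    }
    p <- (cnt + 1) / (n_perm + 1)
  }
  structure(list(k = length(samples), n = n, A2 = A2, T = Tstat,
                 sigma = sigma, p = p, method = method),
            class = "ad_result")
}

#' @export
print.ad_result <- function(x, ...) {
  cat(sprintf("<ad_result> k=%d A2=%.3f T=%.3f p=%.4g (%s)\n",
              x$k, x$A2, x$T, x$p, x$method))
  invisible(x)
}

#' Pairwise decade comparisons of weekly distributions
#'
#' Runs [ad_ksample()] (k = 2) on the pooled weekly values of every pair of
#' decades; p-values are reported without multiplicity correction.
#'
#' @param series complete `weekly_series`.
#' @param decades list of [decade_spec()]s.
#' @param ... passed to [ad_ksample()].
#' @return list: `p` (symmetric matrix of p-values), `results` (list of
#'   `ad_result` keyed "label1|label2").
#' @export
pairwise_decade_tests <- function(series, decades, ...) {
  g <- series_grid(series)
  lab <- assign_decades(g$year, decades)
  labels <- vapply(decades, function(d) d$label, character(1))
  vals <- lapply(labels, function(l) series$values[which(lab == l)])
  names(vals) <- labels
  k <- length(labels)
  P <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  diag(P) <- 1
  results <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    r <- ad_ksample(list(vals[[i]], vals[[j]]), ...)
    P[i, j] <- P[j, i] <- r$p
    results[[paste(labels[i], labels[j], sep = "|")]] <- r
  }
  list(p = P, results = results)
}
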