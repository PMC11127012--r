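#' Threshold-based bloom phenology
#'
#' A bloom is a maximal run of consecutive weeks with chlorophyll strictly
#' above a year-specific threshold, 1.05 x the year's weekly median (the
#' ">5% of the annual median" convention). Events are labelled by the
#' seasonal window containing their start week: winter-spring (weeks 1-16)
#' or summer-fall (weeks 22-38); events starting elsewhere count toward the
#' annual frequency only. Because the threshold scales with the median,
#' every phenology metric is invariant to rescaling a year's chlorophyll.
#'
#' @name phenology
NULL

#' Seasonal window bookkeeping
#'
#' @param winter_spring,summer_fall inclusive week ranges `c(first, last)`.
#' @export
season_windows <- function(winter_spring = c(1L, 16L),
                           summer_fall = c(22L, 38L)) {
  stopifnot(winter_spring[1] >= 1, summer_fall[2] <= 52,
            winter_spring[2] < summer_fall[1])
  structure(list(winter_spring = as.integer(winter_spring),
                 summer_fall = as.integer(summer_fall)),
            class = "season_windows")
}

.season_of <- function(week, windows) {
  ifelse(week >= windows$winter_spring[1] & week <= windows$winter_spring[2],
         "winter_spring",
         ifelse(week >= windows$summer_fall[1] & week <= windows$summer_fall[2],
                "summer_fall", "other"))
}

#' Year-specific bloom threshold
#'
#' @param values a year's weekly chlorophyll (complete, >= 26 values).
#' @param factor threshold multiplier on the annual median (default 1.05).
#' @export
bloom_threshold <- function(values, factor = 1.05) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("all-missing year")
  if (length(values) < 26) stop("need at least 26 weekly values")
  factor * stats::median(values)
}

#' Detect bloom events in one year
#'
#' @param values complete weekly chlorophyll for the year (week 1 first).
#' @param year calendar year label.
#' @param windows a [season_windows()].
#' @param factor threshold multiplier.
#' @return data.frame of events: `year, start_week, end_week,
#'   duration_weeks, peak_week, peak_value, season` (zero rows if no week
#'   exceeds the threshold). Peak ties resolve to the earliest week.
#' @export
detect_blooms <- function(values, year, windows = season_windows(),
                          factor = 1.05) {
  thr <- bloom_threshold(values, factor)
  above <- values > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (length(keep) == 0) {
    return(data.frame(year = integer(0), start_week = integer(0),
                      end_week = integer(0), duration_weeks = integer(0),
                      peak_week = integer(0), peak_value = numeric(0),
                      season = character(0)))
  }
  rows <- lapply(keep, function(i) {
    s <- starts[i]; e <- ends[i]
    pk <- s + which.max(values[s:e]) - 1L
    data.frame(year = year, start_week = s, end_week = e,
               duration_weeks = e - s + 1L, peak_week = pk,
               peak_value = values[pk], season = .season_of(s, windows))
  })
  do.call(rbind, rows)
}

#' Per-season phenology metrics for one year
#'
#' For each window: start = start week of the earliest event starting in
#' it; peak = week of the maximum chlorophyll among that window's events;
#' duration = duration of the event containing that peak; count = number of
#' events starting in the window. Seasons with no event get `NA` metrics
#' and count 0.
#'
#' @param events output of [detect_blooms()] for the year.
#' @param year calendar year label.
#' @return one-row data.frame (a phenology record).
#' @export
seasonal_metrics <- function(events, year) {
  rec <- list(year = year)
  for (season in c("winter_spring", "summer_fall")) {
    ev <- events[events$season == season, , drop = FALSE]
    if (nrow(ev) == 0) {
      rec[paste0(season, c("_start", "_peak", "_duration"))] <- NA_real_
      rec[[paste0(season, "_count")]] <- 0L
    } else {
      top <- ev[which.max(ev$peak_value), ]
      rec[[paste0(season, "_start")]] <- min(ev$start_week)
      rec[[paste0(season, "_peak")]] <- top$peak_week
      rec[[paste0(season, "_duration")]] <- top$duration_weeks
      rec[[paste0(season, "_count")]] <- nrow(ev)
    }
  }
  rec$annual_count <- nrow(events)
  as.data.frame(rec)
}

#' Annual phenology table for a complete series
#'
#' @param series complete `weekly_series` (or numeric of length 52 * years)
#'   of chlorophyll.
#' @param years calendar years (needed when `series` is numeric).
#' @inheritParams detect_blooms
#' @return data.frame, one phenology record per complete year.
#' @export
annual_phenology <- function(series, years = NULL,
                             windows = season_windows(), factor = 1.05) {
  if (inherits(series, "weekly_series")) {
    g <- series_grid(series)
    vals <- series$values
  } else {
    vals <- as.numeric(series)
    stopifnot(length(vals) %% 52 == 0, !is.null(years))
    g <- data.frame(year = rep(years, each = 52), week = rep(1:52, length(years)))
  }
  out <- lapply(split(seq_len(nrow(g)), g$year), function(idx) {
    if (length(idx) < 52L) return(NULL)     # partial years excluded
    yv <- vals[idx]
    if (anyNA(yv)) return(NULL)
    seasonal_metrics(detect_blooms(yv, g$year[idx[1]], windows, factor),
                     g$year[idx[1]])
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Phenology across an imputation ensemble
#'
#' Computes the annual phenology table for every ensemble member and pools
#' per-year metrics as the across-member median and SD.
#'
#' @param ensemble an `imputation_ensemble` (with a grid).
#' @inheritParams detect_blooms
#' @return list: `members` (long data.frame with a `member` column) and
#'   `summary` (per-year median and SD of each metric).
#' @export
phenology_over_ensemble <- function(ensemble, windows = season_windows(),
                                    factor = 1.05) {
  stopifnot(!is.null(ensemble$grid))
  g <- ensemble$grid
  years <- unique(g$year[duplicated(g$year) | TRUE])
  members <- lapply(seq_len(ncol(ensemble$values)), function(j) {
    ph <- annual_phenology(ensemble$values[, j],
                           years = sort(unique(g$year)),
                           windows = windows, factor = factor)
    ph$member <- j
    ph
  })
  long <- do.call(rbind, members)
  metrics <- setdiff(names(long), c("year", "member"))
  agg <- function(fun) {
    a <- stats::aggregate(long[metrics], by = long["year"], FUN = fun,
                          na.rm = TRUE)
    a[metrics] <- lapply(a[metrics], function(v) ifelse(is.nan(v), NA, v))
    a
  }
  med <- agg(stats::median)
  sdv <- agg(stats::sd)
  names(med)[-1] <- paste0(names(med)[-1], "_median")
  names(sdv)[-1] <- paste0(names(sdv)[-1], "_sd")
  list(members = long, summary = merge(med, sdv, by = "year"))
}

#' Poisson GLM for phenology trends
#'
#' Log-link Poisson regression of a week-number (or count) response on
#' environmental covariates, fit by iteratively reweighted least squares;
#' Wald p-values and residual deviance are reported.
#'
#' @param response nonnegative integer response (week numbers or counts).
#' @param covariates data.frame of complete covariates (e.g. year,
#'   nutrients, salinity, Secchi, stratification, a climate index).
#' @return list: `coef` data.frame (`term, estimate, se, z, p`), `deviance`,
#'   `converged`.
#' @export
poisson_glm <- function(response, covariates) {
  if (any(is.na(response)) || any(response < 0) ||
      any(response != round(response))) {
    stop("response must be nonnegative integers")
  }
  df <- data.frame(.y = response, covariates)
  fit <- stats::glm(.y ~ ., data = df, family = stats::poisson())
  cf <- summary(fit)$coefficients
  list(coef = data.frame(term = rownames(cf), estimate = cf[, 1],
                         se = cf[, 2], z = cf[, 3], p = cf[, 4],
                         row.names = NULL),
       deviance = fit$deviance, converged = fit$converged)
}

#' Convert a weekly timing trend to days per decade
#'
#' OLS slope of week-of-year on calendar year, converted as
#' `days/decade = slope[weeks/yr] * 7 * 10`; the SE converts identically.
#' Negative rates mean the event advances (occurs earlier).
#'
#' @param years calendar years.
#' @param weeks yearly timing values (week numbers); `NA`s dropped.
#' @return list `rate`, `se`, `p` (days per decade).
#' @export
trend_rate_days_per_decade <- function(years, weeks) {
  ok <- !is.na(weeks) & !is.na(years)
  if (sum(ok) < 10) stop("need at least 10 yearly values")
  fit <- stats::lm(weeks[ok] ~ years[ok])
  sm <- suppressWarnings(summary(fit))$coefficients
  list(rate = sm[2, 1] * 70, se = sm[2, 2] * 70, p = sm[2, 4])
}
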