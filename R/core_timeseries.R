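#' Weekly time-series containers and calendar conventions
#'
#' The analysis lives on a contiguous 52-week-per-year grid. Calendar dates
#' are binned by day of year, `week = min(ceiling(yday / 7), 52)`, so days
#' 365/366 fold into week 52. A period-53 year would break the seasonal
#' difference used downstream, hence the cap.
#'
#' @name core_timeseries
NULL

# Variables whose observed values must be nonnegative (concentrations).
.nonneg_vars <- c("chl", "no32", "nh4", "po4", "sio4")

#' Map calendar dates to (year, week) grid coordinates
#'
#' @param dates a `Date` vector (or strings coercible via `as.Date`).
#' @return a data.frame with integer columns `year` and `week` (1..52).
#' @export
week_of_date <- function(dates) {
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("unparseable dates")
  yday <- as.integer(format(dates, "%j"))
  data.frame(
    year = as.integer(format(dates, "%Y")),
    week = pmin(as.integer(ceiling(yday / 7)), 52L)
  )
}

# serial week number since an arbitrary origin; strict total order on (year, week)
.week_serial <- function(year, week) year * 52L + (week - 1L)

.serial_week <- function(serial) {
  data.frame(year = serial %/% 52L, week = serial %% 52L + 1L)
}

#' Construct a weekly series on a contiguous grid
#'
#' @param values numeric vector; `NA` marks missing weeks.
#' @param start_year,start_week grid coordinates of `values[1]`.
#' @param name variable identifier.
#' @param unit unit string, metadata only.
#' @param mask optional logical observed flag (defaults to `!is.na(values)`).
#' @return an object of class `weekly_series`.
#' @export
weekly_series <- function(values, start_year, start_week = 1L,
                          name = "value", unit = "", mask = NULL) {
  values <- as.numeric(values)
  if (is.null(mask)) mask <- !is.na(values)
  stopifnot(length(values) == length(mask), is.logical(mask))
  if (start_week < 1L || start_week > 52L) stop("start_week must be in 1..52")
  obs <- values[mask]
  if (any(!is.finite(obs))) stop("observed values must be finite")
  if (name %in% .nonneg_vars && any(obs < 0)) {
    stop(sprintf("observed '%s' values must be nonnegative", name))
  }
  values[!mask] <- NA_real_
  structure(
    list(name = name, unit = unit,
         start = c(year = as.integer(start_year), week = as.integer(start_week)),
         values = values, mask = mask),
    class = "weekly_series"
  )
}

#' @export
length.weekly_series <- function(x) length(x$values)

#' Grid coordinates of every position in a weekly series
#' @param series a `weekly_series`.
#' @return data.frame with columns `year`, `week`.
#' @export
series_grid <- function(series) {
  s0 <- .week_serial(series$start[["year"]], series$start[["week"]])
  .serial_week(s0 + seq_along(series$values) - 1L)
}

#' @export
print.weekly_series <- function(x, ...) {
  g <- series_grid(x)
  cat(sprintf("<weekly_series> %s [%s]: %d weeks (%d-W%02d .. %d-W%02d), %d observed\n",
              x$name, x$unit, length(x$values),
              g$year[1], g$week[1], g$year[nrow(g)], g$week[nrow(g)],
              sum(x$mask)))
  invisible(x)
}

#' Bin dated records onto the weekly grid
#'
#' Multiple records falling in one week are averaged; weeks with no record
#' are masked missing; the grid is contiguous from the first to the last
#' observed week.
#'
#' @param dates dates of the records.
#' @param values numeric values, same length.
#' @inheritParams weekly_series
#' @return a `weekly_series`.
#' @export
align_to_weekly_grid <- function(dates, values, name = "value", unit = "") {
  if (length(dates) == 0L) stop("no records")
  stopifnot(length(dates) == length(values))
  if (any(!is.finite(values))) stop("values must be finite")
  wk <- week_of_date(dates)
  serial <- .week_serial(wk$year, wk$week)
  means <- tapply(values, serial, mean)
  s <- as.integer(names(means))
  grid <- seq(min(s), max(s))
  v <- rep(NA_real_, length(grid))
  v[match(s, grid)] <- as.numeric(means)
  first <- .serial_week(grid[1])
  weekly_series(v, first$year, first$week, name = name, unit = unit)
}

#' Aligned panel of weekly series plus annual covariates
#'
#' @param series named list of `weekly_series` sharing one grid.
#' @param annual optional data.frame of per-year covariates with a `year`
#'   column (e.g. a Gulf Stream Index).
#' @return an object of class `env_panel`.
#' @export
env_panel <- function(series, annual = NULL) {
  stopifnot(is.list(series), length(series) >= 1L)
  nms <- vapply(series, function(s) s$name, character(1))
  if (is.null(names(series))) names(series) <- nms
  if (anyDuplicated(names(series))) stop("variable names must be unique")
  ref <- series[[1]]
  for (s in series) {
    if (!identical(s$start, ref$start) || length(s$values) != length(ref$values)) {
      stop(sprintf("series '%s' does not share the panel grid", s$name))
    }
  }
  if (!is.null(annual)) {
    stopifnot(is.data.frame(annual), "year" %in% names(annual))
  }
  structure(list(series = series, annual = annual), class = "env_panel")
}

#' @export
print.env_panel <- function(x, ...) {
  cat(sprintf("<env_panel> %d series x %d weeks: %s\n",
              length(x$series), length(x$series[[1]]$values),
              paste(names(x$series), collapse = ", ")))
  invisible(x)
}

#' Write / read a panel as CSV
#'
#' Layout: header `year,week,<var1>,<var2>,...`; empty cells are missing.
#' Annual covariates go to a second CSV with header `year,<cov>,...`.
#' The round trip is lossless for values, masks, names; units are stored in
#' a `# unit:` comment line.
#'
#' @param panel an `env_panel`.
#' @param path CSV path for the weekly table.
#' @param annual_path optional CSV path for annual covariates.
#' @export
write_panel <- function(panel, path, annual_path = NULL) {
  g <- series_grid(panel$series[[1]])
  df <- cbind(g, as.data.frame(lapply(panel$series, function(s) s$values)))
  units <- vapply(panel$series, function(s) s$unit, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# unit: %s", paste(units, collapse = ",")), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(panel$annual) && !is.null(annual_path)) {
    utils::write.csv(panel$annual, annual_path, row.names = FALSE,
                     quote = FALSE, na = "")
  }
  invisible(path)
}

#' @rdname write_panel
#' @return `read_panel` returns an `env_panel`.
#' @export
read_panel <- function(path, annual_path = NULL) {
  first <- readLines(path, n = 1L)
  units <- NULL
  if (startsWith(first, "# unit:")) {
    units <- strsplit(sub("^# unit: ?", "", first), ",")[[1]]
  }
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("year", "week") %in% names(df))) {
    stop("panel CSV must have 'year' and 'week' columns")
  }
  serial <- .week_serial(df$year, df$week)
  if (anyDuplicated(serial)) {
    d <- df[which(duplicated(serial))[1], ]
    stop(sprintf("duplicate (year, week) row: (%d, %d)", d$year, d$week))
  }
  o <- order(serial)
  df <- df[o, ]; serial <- serial[o]
  if (!all(diff(serial) == 1L)) stop("non-contiguous grid")
  vars <- setdiff(names(df), c("year", "week"))
  if (is.null(units)) units <- rep("", length(vars))
  series <- lapply(seq_along(vars), function(i) {
    weekly_series(df[[vars[i]]], df$year[1], df$week[1],
                  name = vars[i], unit = units[i])
  })
  names(series) <- vars
  annual <- if (!is.null(annual_path)) utils::read.csv(annual_path) else NULL
  env_panel(series, annual)
}

#' Restrict a series or panel to whole years
#'
#' The slice covers weeks `(first_year, 1) .. (last_year, 52)` and errors if
#' that range is not inside the object's span.
#'
#' @param x a `weekly_series` or `env_panel`.
#' @param first_year,last_year inclusive year range.
#' @export
slice_years <- function(x, first_year, last_year) UseMethod("slice_years")

#' @export
slice_years.weekly_series <- function(x, first_year, last_year) {
  stopifnot(last_year >= first_year)
  s0 <- .week_serial(x$start[["year"]], x$start[["week"]])
  want <- .week_serial(as.integer(first_year), 1L):.week_serial(as.integer(last_year), 52L)
  idx <- want - s0 + 1L
  if (idx[1] < 1L || idx[length(idx)] > length(x$values)) {
    stop("requested year range outside series span")
  }
  weekly_series(x$values[idx], first_year, 1L, name = x$name, unit = x$unit,
                mask = x$mask[idx])
}

#' @export
slice_years.env_panel <- function(x, first_year, last_year) {
  series <- lapply(x$series, slice_years, first_year, last_year)
  annual <- x$annual
  if (!is.null(annual)) {
    annual <- annual[annual$year >= first_year & annual$year <= last_year, ,
                     drop = FALSE]
  }
  env_panel(series, annual)
}

#' Decade bookkeeping
#'
#' A decade spec is just a labelled year range; spans need not be 10 years
#' (the study's last "decade" is the 11-year 2009-2019 span, kept as
#' printed).
#'
#' @param label short label, e.g. "first".
#' @param first_year,last_year inclusive range.
#' @export
decade_spec <- function(label, first_year, last_year) {
  stopifnot(last_year >= first_year)
  structure(list(label = label, first_year = as.integer(first_year),
                 last_year = as.integer(last_year)), class = "decade_spec")
}

#' @param years integer vector of years to label.
#' @param decades list of `decade_spec`s; must not overlap.
#' @return character labels, `NA` for years in no decade.
#' @rdname decade_spec
#' @export
assign_decades <- function(years, decades) {
  labels <- rep(NA_character_, length(years))
  for (d in decades) {
    hit <- years >= d$first_year & years <= d$last_year
    if (any(hit & !is.na(labels))) stop("overlapping decade specs")
    labels[hit] <- d$label
  }
  labels
}
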