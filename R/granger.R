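#' Bivariate Granger-causality screening
#'
#' `x` Granger-causes `y` if past `x` improves prediction of `y` beyond
#' past `y` alone. The test regresses `y_t` on its own lags 1..L
#' (restricted) and adds `x` lags 1..L (unrestricted); the F statistic on
#' the x-lag block is the test. L is chosen by AIC of the restricted
#' autoregression (so lag selection never peeks at `x` and the F test
#' stays calibrated), or fixed. Both series are mean-centered; the test is
#' directional and is reported without multiplicity adjustment.
#'
#' @name granger
NULL

#' Granger test of x -> y
#'
#' @param x candidate cause (complete numeric series).
#' @param y effect series, same length.
#' @param max_lag largest lag order considered.
#' @param lag_rule `"aic"` (choose L by AIC of the restricted model over
#'   1..max_lag) or `"fixed"` (use `max_lag`).
#' @return object of class `granger_result`: list with `F`, `p`, `lag`,
#'   `n_effective`, and the two residual sums of squares.
#' @export
granger_test <- function(x, y, max_lag = 4L, lag_rule = c("aic", "fixed")) {
  lag_rule <- match.arg(lag_rule)
  stopifnot(length(x) == length(y), max_lag >= 1)
  if (anyNA(x) || anyNA(y)) stop("series must be complete")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance series")
  n <- length(y)
  if (n <= 3 * max_lag) stop("insufficient length for requested max_lag")
  x <- x - mean(x); y <- y - mean(y)

  rss <- function(resp, Z) {
    r <- stats::lm.fit(Z, resp)$residuals
    sum(r^2)
  }
  pick_lag <- function() {
    aics <- vapply(seq_len(max_lag), function(L) {
      E <- stats::embed(y, L + 1)
      m <- nrow(E)
      m * log(rss(E[, 1], cbind(1, E[, -1, drop = FALSE])) / m) + 2 * L
    }, numeric(1))
    which.min(aics)
  }
  L <- if (lag_rule == "aic") pick_lag() else max_lag
  Ey <- stats::embed(y, L + 1)
  Ex <- stats::embed(x, L + 1)[, -1, drop = FALSE]
  resp <- Ey[, 1]
  Zr <- cbind(1, Ey[, -1, drop = FALSE])   # intercept absorbs trim-window means
  Zu <- cbind(Zr, Ex)
  m <- length(resp)
  rss0 <- rss(resp, Zr)
  rss1 <- rss(resp, Zu)
  df2 <- m - ncol(Zu)
  Fstat <- ((rss0 - rss1) / L) / (rss1 / df2)
  p <- stats::pf(Fstat, L, df2, lower.tail = FALSE)
  structure(list(F = Fstat, p = p, lag = L, n_effective = m,
                 rss_restricted = rss0, rss_unrestricted = rss1),
            class = "granger_result")
}

#' @export
print.granger_result <- function(x, ...) {
  cat(sprintf("<granger_result> L=%d F=%.3f p=%.4g (n=%d)\n",
              x$lag, x$F, x$p, x$n_effective))
  invisible(x)
}

#' Screen driver -> effect pairs across a panel
#'
#' Long-term screening runs on annual means of the completed series,
#' first-differenced to reduce spurious trend correlation (the default);
#' `resolution = "weekly"` tests the weekly series directly.
#'
#' @param panel a complete `env_panel`.
#' @param effect name of the effect variable.
#' @param causes character vector of candidate causes.
#' @param resolution `"annual"` or `"weekly"`.
#' @param difference first-difference the (annual) series before testing.
#' @param max_lag default 4 at annual resolution, 8 at weekly.
#' @param lag_rule passed to [granger_test()].
#' @return data.frame `cause, effect, lag, F, p, n`.
#' @export
granger_screen <- function(panel, effect = "chl", causes,
                           resolution = c("annual", "weekly"),
                           difference = TRUE, max_lag = NULL,
                           lag_rule = "aic") {
  resolution <- match.arg(resolution)
  if (!effect %in% names(panel$series)) {
    stop(sprintf("effect '%s' not in panel", effect))
  }
  missing_causes <- setdiff(causes, names(panel$series))
  if (length(missing_causes)) {
    stop(sprintf("cause(s) not in panel: %s", paste(missing_causes, collapse = ", ")))
  }
  if (is.null(max_lag)) max_lag <- if (resolution == "annual") 4L else 8L
  prep <- function(v) {
    s <- panel$series[[v]]
    vals <- s$values
    if (anyNA(vals)) stop(sprintf("series '%s' is not complete", v))
    if (resolution == "annual") {
      g <- series_grid(s)
      vals <- as.numeric(tapply(vals, g$year, mean))
    }
    if (difference && resolution == "annual") vals <- diff(vals)
    vals
  }
  ye <- prep(effect)
  rows <- lapply(causes, function(cv) {
    r <- granger_test(prep(cv), ye, max_lag = max_lag, lag_rule = lag_rule)
    data.frame(cause = cv, effect = effect, lag = r$lag, F = r$F, p = r$p,
               n = r$n_effective)
  })
  do.call(rbind, rows)
}
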