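#' Seasonal ARIMA with lagged exogenous drivers, fit across an imputation
#' ensemble
#'
#' The regression-with-SARIMA-errors form: seasonal differencing (D per the
#' order) is applied jointly to the response and the regressors by the
#' state-space likelihood, so exogenous coefficients are reported on the
#' undifferenced scale. Fitting each ensemble member and pooling
#' coefficient estimates (MC mean, MC SD, significance frequency at
#' p < 0.05) propagates imputation uncertainty into the regression
#' conclusions.
#'
#' @name sarimax_mc
NULL

#' SARIMA order specification
#'
#' @param p,d,q nonseasonal AR / differencing / MA orders.
#' @param P,D,Q seasonal orders.
#' @param s seasonal period (weeks). Default `(2,0,1)x(0,1,1)_52`.
#' @export
sarimax_order <- function(p = 2L, d = 0L, q = 1L, P = 0L, D = 1L, Q = 1L,
                          s = 52L) {
  ord <- c(p = p, d = d, q = q, P = P, D = D, Q = Q, s = s)
  stopifnot(all(ord >= 0), s >= 2)
  structure(as.list(ord), class = "sarimax_order")
}

#' Exogenous regressor specification
#'
#' A set of (variable, lag-in-weeks) pairs. `default_exog_spec()` is the
#' final driver set of the analysis: ammonium lags 0-2, silicate lags 0-1,
#' nitrate+nitrite lags 0-3, Secchi depth lag 0, temperature lag 0,
#' salinity lags 0-2 (14 columns).
#'
#' @param variables character vector of variable names.
#' @param lags integer vector of lags (same length).
#' @export
exog_spec <- function(variables, lags) {
  stopifnot(length(variables) == length(lags), all(lags >= 0))
  df <- data.frame(variable = variables, lag = as.integer(lags))
  if (anyDuplicated(df)) stop("duplicate (variable, lag) pair")
  structure(df, class = c("exog_spec", "data.frame"))
}

#' @rdname exog_spec
#' @export
default_exog_spec <- function() {
  exog_spec(
    c(rep("nh4", 3), rep("sio4", 2), rep("no32", 4), "secchi", "temp",
      rep("salinity", 3)),
    c(0:2, 0:1, 0:3, 0, 0, 0:2)
  )
}

.exog_name <- function(variable, lag) {
  ifelse(lag > 0, paste0(variable, "_lag", lag), variable)
}

#' Build the lagged design matrix
#'
#' Each (variable, lag) pair becomes a column shifted `lag` weeks back; the
#' first `max(lag)` weeks are trimmed from the response window so every row
#' is complete.
#'
#' @param panel a complete `env_panel` (or named list / data.frame of equal
#'   length numeric vectors).
#' @param spec an [exog_spec()].
#' @return list: `X` (matrix), `response_idx` (rows of the original grid
#'   the response window covers), `max_lag`.
#' @export
build_design <- function(panel, spec) {
  get_var <- function(v) {
    if (inherits(panel, "env_panel")) {
      if (!v %in% names(panel$series)) stop(sprintf("variable '%s' absent", v))
      panel$series[[v]]$values
    } else {
      if (!v %in% names(panel)) stop(sprintf("variable '%s' absent", v))
      as.numeric(panel[[v]])
    }
  }
  n <- length(get_var(spec$variable[1]))
  max_lag <- max(spec$lag)
  rows <- (max_lag + 1L):n
  X <- vapply(seq_len(nrow(spec)), function(i) {
    v <- get_var(spec$variable[i]); l <- spec$lag[i]
    v[rows - l]
  }, numeric(length(rows)))
  colnames(X) <- .exog_name(spec$variable, spec$lag)
  list(X = X, response_idx = rows, max_lag = max_lag)
}

#' Fit a SARIMAX model by state-space maximum likelihood
#'
#' Exogenous columns are standardized internally (a numerical-stability
#' measure) and coefficients are reported back on input units. The default
#' estimation path warm-starts exact maximum likelihood from
#' conditional-sum-of-squares estimates; `method = "css"` keeps the fast
#' CSS estimates, which are adequate for pooled summaries but bias the
#' seasonal MA coefficient toward zero.
#'
#' @param y numeric response.
#' @param X regressor matrix (or `NULL`).
#' @param order a [sarimax_order()].
#' @param method `"ml"` (CSS-warm-started exact ML) or `"css"`.
#' @param reltol optimizer tolerance for the ML stage.
#' @return object of class `sarimax_fit`: `coef` data.frame (`parameter`,
#'   `estimate`, `se`, `z`, `p`), `loglik`, `aic`, `sigma2`, `converged`.
#' @export
fit_sarimax <- function(y, X = NULL, order = sarimax_order(),
                        method = c("ml", "css"), reltol = 1e-6) {
  method <- match.arg(method)
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    qrX <- qr(cbind(1, X))
    if (qrX$rank < ncol(X) + 1) {
      keep <- qrX$pivot[seq_len(qrX$rank)] - 1L
      bad <- setdiff(seq_len(ncol(X)), keep)
      stop(sprintf("singular design; collinear column(s): %s",
                   paste(colnames(X)[bad], collapse = ", ")))
    }
    mu <- colMeans(X); sdev <- apply(X, 2, stats::sd)
    if (any(sdev == 0)) stop(sprintf("zero-variance column(s): %s",
      paste(colnames(X)[sdev == 0], collapse = ", ")))
    Xs <- scale(X, center = mu, scale = sdev)
  } else Xs <- NULL
  ord <- unlist(order[c("p", "d", "q")])
  seas <- list(order = unlist(order[c("P", "D", "Q")]), period = order$s)
  n_par <- order$p + order$q + order$P + order$Q +
    (if (is.null(Xs)) 0L else ncol(Xs)) +
    (order$d + order$D == 0)              # intercept when no differencing
  stopifnot(length(y) > order$s * (order$D + 1) + n_par)

  fit_css <- tryCatch(
    stats::arima(y, order = ord, seasonal = seas, xreg = Xs, method = "CSS"),
    error = function(e) NULL, warning = function(w) NULL)
  fit <- NULL; converged <- TRUE
  if (method == "ml") {
    init <- if (!is.null(fit_css)) stats::coef(fit_css) else NULL
    fit <- tryCatch(
      stats::arima(y, order = ord, seasonal = seas, xreg = Xs, method = "ML",
                   transform.pars = FALSE, init = init,
                   optim.control = list(reltol = reltol)),
      error = function(e) NULL)
    if (is.null(fit)) {       # retry from scratch with default init
      fit <- tryCatch(
        stats::arima(y, order = ord, seasonal = seas, xreg = Xs,
                     method = "ML", optim.control = list(reltol = reltol)),
        error = function(e) NULL)
    }
  } else {
    fit <- fit_css
  }
  if (is.null(fit)) {
    return(structure(list(coef = NULL, loglik = NA_real_, aic = NA_real_,
                          sigma2 = NA_real_, converged = FALSE,
                          order = order, method = method),
                     class = "sarimax_fit"))
  }
  est <- stats::coef(fit)
  vc <- tryCatch(fit$var.coef, error = function(e) NULL)
  se <- if (!is.null(vc)) sqrt(pmax(diag(vc), 0)) else rep(NA_real_, length(est))
  se <- se[match(names(est), names(est))]
  if (any(!is.finite(se))) converged <- FALSE
  # back-transform regression coefficients to input units
  if (!is.null(Xs)) {
    xi <- match(colnames(Xs), names(est))
    ii <- match("intercept", names(est))
    if (!is.na(ii) && !is.null(vc)) {
      # intercept on raw scale: a - sum(b_std * mu / sd); delta-method SE
      est[ii] <- est[ii] - sum(est[xi] * mu / sdev)
      dvec <- numeric(length(est))
      dvec[ii] <- 1
      dvec[xi] <- -mu / sdev
      se[ii] <- sqrt(max(drop(t(dvec) %*% vc %*% dvec), 0))
    }
    est[xi] <- est[xi] / sdev
    se[xi] <- se[xi] / sdev
    names(est)[xi] <- colnames(X)
  }
  arma_n <- c(AR = order$p, MA = order$q, SAR = order$P, SMA = order$Q)
  arma_names <- unlist(lapply(names(arma_n), function(k) {
    if (arma_n[[k]] > 0) paste0(k, seq_len(arma_n[[k]]))
  }))
  nm <- names(est)
  nm[seq_along(arma_names)] <- arma_names
  if ("intercept" %in% names(est)) nm[names(est) == "intercept"] <- "intercept"
  z <- est / se
  coef_df <- data.frame(parameter = nm, estimate = unname(est),
                        se = unname(se), z = unname(z),
                        p = unname(2 * stats::pnorm(-abs(z))))
  structure(list(coef = coef_df, loglik = fit$loglik,
                 aic = if (method == "ml") stats::AIC(fit) else NA_real_,
                 sigma2 = fit$sigma2, converged = converged,
                 order = order, method = method, arima = fit),
            class = "sarimax_fit")
}

#' @export
print.sarimax_fit <- function(x, ...) {
  cat(sprintf("<sarimax_fit> (%d,%d,%d)x(%d,%d,%d)_%d %s loglik=%.2f%s\n",
              x$order$p, x$order$d, x$order$q, x$order$P, x$order$D,
              x$order$Q, x$order$s, x$method, x$loglik,
              if (x$converged) "" else " [not converged]"))
  if (!is.null(x$coef)) print(x$coef, digits = 3)
  invisible(x)
}

#' Monte-Carlo SARIMAX over an imputation ensemble
#'
#' Fits the model to every ensemble member, drops non-converged fits (with
#' a message), and pools per-parameter MC mean, MC SD and the count of
#' members with two-sided Wald p < 0.05 (scaled to the reported M).
#'
#' @param ensemble an `imputation_ensemble` (response variable, data scale).
#' @param panel completed `env_panel` holding the drivers.
#' @param order a [sarimax_order()].
#' @param exog an [exog_spec()].
#' @param method estimation method passed to [fit_sarimax()].
#' @param report_m scale significance counts to this M (default: members
#'   used).
#' @return object of class `mc_summary`: data.frame `summary` with columns
#'   `parameter, mc_mean, mc_sd, sig_freq`, plus `M`, `n_dropped`.
#' @export
run_mc <- function(ensemble, panel, order = sarimax_order(),
                   exog = default_exog_spec(), method = "ml",
                   report_m = NULL) {
  M <- ncol(ensemble$values)
  stopifnot(M >= 2)
  des <- build_design(panel, exog)
  fits <- vector("list", M)
  for (j in seq_len(M)) {
    yj <- ensemble$values[des$response_idx, j]
    fits[[j]] <- fit_sarimax(yj, des$X, order, method = method)
  }
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  n_dropped <- sum(!ok)
  if (n_dropped > 0.2 * M) {
    stop(sprintf("%d/%d SARIMAX fits failed to converge; revise the model spec",
                 n_dropped, M))
  }
  if (n_dropped > 0) message(sprintf("dropped %d non-converged fit(s)", n_dropped))
  fits <- fits[ok]
  est <- sapply(fits, function(f) f$coef$estimate)
  sig <- sapply(fits, function(f) f$coef$p < 0.05)
  pars <- fits[[1]]$coef$parameter
  m_used <- length(fits)
  if (is.null(report_m)) report_m <- m_used
  out <- data.frame(parameter = pars,
                    mc_mean = rowMeans(est),
                    mc_sd = apply(est, 1, stats::sd),
                    sig_freq = round(rowSums(sig) / m_used * report_m))
  structure(list(summary = out, M = m_used, report_m = report_m,
                 n_dropped = n_dropped, order = order, exog = exog,
                 method = method),
            class = "mc_summary")
}

#' @export
print.mc_summary <- function(x, ...) {
  cat(sprintf("<mc_summary> %d fits (%d dropped), sig counts out of %d\n",
              x$M, x$n_dropped, x$report_m))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Simulate from a SARIMAX process
#'
#' Simulates the regression-with-SARIMA-errors model: an ARMA process with
#' the expanded (nonseasonal x seasonal) polynomials is drawn, seasonally
#' integrated `D` times and ordinarily integrated `d` times, and the
#' regression signal `X beta` is added.
#'
#' @param n series length.
#' @param order a [sarimax_order()].
#' @param ar,ma,sar,sma coefficient vectors matching the order.
#' @param X,beta optional regressors and coefficients.
#' @param sd innovation SD.
#' @param seed integer seed.
#' @return numeric vector of length `n`.
#' @export
simulate_sarimax <- function(n, order = sarimax_order(),
                             ar = numeric(0), ma = numeric(0),
                             sar = numeric(0), sma = numeric(0),
                             X = NULL, beta = NULL, sd = 1, seed = 1L) {
  set.seed(seed)
  s <- order$s
  expand <- function(nonseas, seas) {
    a <- c(1, nonseas)
    b <- c(1, numeric(0))
    if (length(seas)) {
      b <- numeric(1 + s * length(seas))
      b[1] <- 1
      b[1 + s * seq_along(seas)] <- seas
    }
    p <- stats::convolve(a, rev(b), type = "open")
    p[-1]
  }
  phi <- -expand(-ar, -sar)     # AR polynomial has negated signs
  theta <- expand(ma, sma)
  mod <- list()
  if (length(phi)) mod$ar <- phi
  if (length(theta)) mod$ma <- theta
  w <- as.numeric(stats::arima.sim(model = mod, n = n, sd = sd))
  for (i in seq_len(order$D)) {
    y <- numeric(n)
    y[seq_len(s)] <- stats::rnorm(s, 0, sd)
    for (t in (s + 1):n) y[t] <- y[t - s] + w[t]
    w <- y
  }
  for (i in seq_len(order$d)) w <- cumsum(w)
  if (!is.null(X)) w <- w + drop(as.matrix(X) %*% beta)
  w
}

#' Rank candidate model specifications by AIC
#'
#' Candidates are fit (exact ML) to a single reference series — typically
#' the ensemble-mean series — and ranked by AIC; ties break toward fewer
#' parameters.
#'
#' @param candidates list of `list(order =, exog =)`; `exog` may be `NULL`.
#' @param y reference response series.
#' @param panel completed panel (only needed when a candidate has exog).
#' @return data.frame ranked by AIC with columns `candidate`, `aic`,
#'   `n_par`, `converged`.
#' @export
select_model <- function(candidates, y, panel = NULL) {
  stopifnot(length(candidates) >= 1)
  rows <- lapply(seq_along(candidates), function(i) {
    cand <- candidates[[i]]
    X <- NULL; idx <- seq_along(y)
    if (!is.null(cand$exog)) {
      des <- build_design(panel, cand$exog)
      X <- des$X; idx <- des$response_idx
    }
    f <- tryCatch(fit_sarimax(y[idx], X, cand$order, method = "ml"),
                  error = function(e) NULL)
    ord <- cand$order
    lab <- sprintf("(%d,%d,%d)x(%d,%d,%d)_%d%s", ord$p, ord$d, ord$q,
                   ord$P, ord$D, ord$Q, ord$s,
                   if (is.null(X)) "" else sprintf("+%dxreg", ncol(X)))
    npar <- ord$p + ord$q + ord$P + ord$Q + if (is.null(X)) 0 else ncol(X)
    data.frame(candidate = lab, index = i,
               aic = if (is.null(f) || !f$converged) NA_real_ else f$aic,
               n_par = npar,
               converged = !is.null(f) && f$converged)
  })
  res <- do.call(rbind, rows)
  if (all(is.na(res$aic))) stop("all candidates failed")
  res[order(res$aic, res$n_par, na.last = TRUE), ]
}
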