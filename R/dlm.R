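#' Bayesian dynamic linear models for weekly gap filling
#'
#' A Gaussian state-space model `y_t = F' theta_t + v_t`,
#' `theta_t = G theta_{t-1} + w_t`, built from a local linear trend block
#' (level + slope) and a trigonometric seasonal block (harmonics of period
#' 52). Evolution covariances are set by block discount factors; the
#' observation variance is either known or learned by conjugate
#' normal-inverse-gamma updating (Student-t one-step forecasts). Missing
#' weeks propagate through the evolution only, which is what makes the
#' model an interpolator: the smoother and the forward-filtering
#' backward-sampling (FFBS) draw give, respectively, point reconstructions
#' and exact joint posterior samples of the state path, from which
#' posterior-predictive values at the gaps follow.
#'
#' @name dlm_impute
NULL

#' Specify a dynamic linear model
#'
#' @param level,slope include a local level / local linear trend block.
#' @param harmonics number of seasonal harmonics `h` in `0..period/2`.
#' @param period seasonal period in weeks.
#' @param discount_trend,discount_seasonal block discount factors in (0, 1];
#'   1 means a static block.
#' @param obs_variance known observation variance, or `NULL` to learn it by
#'   conjugate updating.
#' @param W explicit evolution covariance matrix (overrides discounts);
#'   requires a known `obs_variance`.
#' @param prior_mean,prior_cov prior state moments. When `NULL` (default)
#'   they are set from the data at filter time: level prior at the observed
#'   median, covariance `diag(4 * var(observed))`. A very diffuse explicit
#'   prior interacts badly with discounting (the unidentified state
#'   directions are re-inflated faster than the data contract them), so the
#'   weakly informative data-scaled default is recommended.
#' @param prior_df,prior_scale inverse-gamma prior for the unknown
#'   observation variance (degrees of freedom and point estimate);
#'   `prior_scale = NULL` defaults to a quarter of the observed variance.
#' @param transform `"raw"` or `"log"`; with `"log"` the series is modelled
#'   on the natural-log scale and all predictive output is exponentiated
#'   back. Appropriate for strictly positive, right-skewed variables.
#' @return an object of class `dlm_spec`.
#' @export
dlm_spec <- function(level = TRUE, slope = TRUE, harmonics = 3L, period = 52L,
                     discount_trend = 0.98, discount_seasonal = 0.98,
                     obs_variance = NULL, W = NULL,
                     prior_mean = NULL, prior_cov = NULL,
                     prior_df = 1, prior_scale = NULL,
                     transform = c("raw", "log")) {
  transform <- match.arg(transform)
  stopifnot(level || harmonics > 0, harmonics >= 0,
            harmonics <= period / 2,
            discount_trend > 0, discount_trend <= 1,
            discount_seasonal > 0, discount_seasonal <= 1)
  if (slope && !level) stop("slope requires level")
  if (!is.null(W) && is.null(obs_variance)) {
    stop("explicit W requires a known obs_variance")
  }

  Fv <- numeric(0); blocks <- list(); Gb <- list()
  if (level) {
    if (slope) {
      Gb <- c(Gb, list(matrix(c(1, 0, 1, 1), 2, 2)))
      Fv <- c(Fv, 1, 0)
    } else {
      Gb <- c(Gb, list(matrix(1, 1, 1)))
      Fv <- c(Fv, 1)
    }
    blocks <- c(blocks, list(list(idx = seq_along(Fv), delta = discount_trend)))
  }
  if (harmonics > 0) {
    s0 <- length(Fv)
    for (j in seq_len(harmonics)) {
      w <- 2 * pi * j / period
      if (abs(w - pi) < 1e-12) {          # Nyquist harmonic is 1-dimensional
        Gb <- c(Gb, list(matrix(-1, 1, 1)))
        Fv <- c(Fv, 1)
      } else {
        Gb <- c(Gb, list(matrix(c(cos(w), -sin(w), sin(w), cos(w)), 2, 2)))
        Fv <- c(Fv, 1, 0)
      }
    }
    blocks <- c(blocks, list(list(idx = (s0 + 1):length(Fv),
                                  delta = discount_seasonal)))
  }
  d <- length(Fv)
  G <- matrix(0, d, d)
  at <- 1L
  for (B in Gb) {
    k <- nrow(B)
    G[at:(at + k - 1L), at:(at + k - 1L)] <- B
    at <- at + k
  }
  if (!is.null(prior_mean)) stopifnot(length(prior_mean) == d)
  if (!is.null(prior_cov)) stopifnot(all(dim(prior_cov) == d))
  if (!is.null(W)) stopifnot(all(dim(W) == d))
  level_idx <- if (level) 1L else integer(0)
  seas_idx <- if (harmonics > 0) {
    which(Fv == 1)[-seq_len(as.integer(level))]
  } else integer(0)
  structure(list(F = Fv, G = G, blocks = blocks, W = W,
                 obs_variance = obs_variance,
                 prior_mean = prior_mean, prior_cov = prior_cov,
                 prior_df = prior_df, prior_scale = prior_scale,
                 transform = transform, period = period,
                 harmonics = harmonics, level_idx = level_idx,
                 seas_idx = seas_idx, d = d),
            class = "dlm_spec")
}

.dlm_y <- function(spec, series) {
  y <- if (inherits(series, "weekly_series")) series$values else as.numeric(series)
  if (spec$transform == "log") {
    if (any(y[!is.na(y)] <= 0)) stop("log transform requires positive values")
    y <- log(y)
  }
  y
}

#' Kalman filter for a `dlm_spec`
#'
#' Standard conjugate DLM forward recursion. Missing weeks update through
#' the evolution only. With unknown observation variance the one-step
#' forecast distribution is Student-t and the returned covariance arrays
#' are retrospectively rescaled to the final variance estimate, so the
#' smoother and FFBS condition on everything the filter learned.
#'
#' @param spec a [dlm_spec()].
#' @param series a `weekly_series` or numeric vector (`NA` = missing).
#' @return an object of class `dlm_moments` with filtered means `m` (d x T),
#'   covariances `C` (d x d x T), one-step forecasts `f`, `q`, prior moments
#'   `a`, `R`, the observation-variance path `S`, its degrees of freedom
#'   `n`, the plug-in variance `v_hat`, and the predictive log-likelihood
#'   of the observed points.
#' @export
kalman_filter <- function(spec, series) {
  y <- .dlm_y(spec, series)
  T_ <- length(y)
  obs <- !is.na(y)
  if (!any(obs)) stop("all-missing series")
  d <- spec$d; G <- spec$G; Fv <- spec$F
  known_v <- !is.null(spec$obs_variance)

  m <- matrix(0, d, T_); C <- array(0, c(d, d, T_))
  a <- matrix(0, d, T_); R <- array(0, c(d, d, T_))
  f <- numeric(T_); q <- numeric(T_)
  Spath <- numeric(T_); npath <- numeric(T_)
  loglik <- 0

  yo <- y[obs]
  vy <- stats::var(yo)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  m_prev <- spec$prior_mean
  if (is.null(m_prev)) {
    m_prev <- numeric(d)
    if (length(spec$level_idx)) m_prev[spec$level_idx] <- stats::median(yo)
  }
  C_prev <- if (is.null(spec$prior_cov)) diag(4 * vy, d) else spec$prior_cov
  S0 <- if (is.null(spec$prior_scale)) vy / 4 else spec$prior_scale
  S_prev <- if (known_v) spec$obs_variance else S0
  n_prev <- spec$prior_df

  for (t in seq_len(T_)) {
    a_t <- G %*% m_prev
    P <- G %*% C_prev %*% t(G)
    P <- (P + t(P)) / 2
    if (!is.null(spec$W)) {
      R_t <- P + spec$W
    } else {
      R_t <- P
      for (b in spec$blocks) {
        R_t[b$idx, b$idx] <- P[b$idx, b$idx] / b$delta
      }
    }
    RF <- R_t %*% Fv
    f_t <- sum(Fv * a_t)
    q_t <- sum(Fv * RF) + S_prev
    if (obs[t]) {
      e <- y[t] - f_t
      A <- RF / q_t
      m_t <- a_t + A * e
      if (known_v) {
        C_t <- R_t - tcrossprod(A) * q_t
        loglik <- loglik + stats::dnorm(e, 0, sqrt(q_t), log = TRUE)
        S_t <- S_prev; n_t <- n_prev
      } else {
        n_t <- n_prev + 1
        S_t <- S_prev + (S_prev / n_t) * (e^2 / q_t - 1)
        C_t <- (S_t / S_prev) * (R_t - tcrossprod(A) * q_t)
        # Student-t one-step forecast density with df n_prev, scale q_t
        loglik <- loglik + lgamma((n_prev + 1) / 2) - lgamma(n_prev / 2) -
          0.5 * log(n_prev * pi * q_t) -
          ((n_prev + 1) / 2) * log1p(e^2 / (n_prev * q_t))
      }
    } else {
      m_t <- a_t; C_t <- R_t; S_t <- S_prev; n_t <- n_prev
    }
    C_t <- (C_t + t(C_t)) / 2
    m[, t] <- m_t; C[, , t] <- C_t
    a[, t] <- a_t; R[, , t] <- R_t
    f[t] <- f_t; q[t] <- q_t
    Spath[t] <- S_t; npath[t] <- n_t
    m_prev <- m_t; C_prev <- C_t; S_prev <- S_t; n_prev <- n_t
  }

  v_hat <- Spath[T_]
  if (!known_v) {
    # retrospective rescaling to the final variance estimate
    S_lag <- c(S0, Spath[-T_])
    for (t in seq_len(T_)) {
      C[, , t] <- C[, , t] * (v_hat / Spath[t])
      R[, , t] <- R[, , t] * (v_hat / S_lag[t])
    }
  }

  structure(list(spec = spec, y = y, obs = obs,
                 m = m, C = C, a = a, R = R, f = f, q = q,
                 S = Spath, n = npath, v_hat = v_hat, loglik = loglik),
            class = "dlm_moments")
}

# backward gain B_t = C_t G' R_{t+1}^{-1}, shared by smoother and FFBS
.backward_gains <- function(mom) {
  G <- mom$spec$G
  T_ <- length(mom$f)
  B <- vector("list", T_)
  for (t in seq_len(T_ - 1)) {
    Rn <- mom$R[, , t + 1]
    B[[t]] <- t(solve(Rn, G %*% mom$C[, , t]))
  }
  B
}

#' Kalman smoother
#'
#' Backward recursion over the filtered moments; the smoothed mean at each
#' week conditions on the whole series.
#'
#' @param mom result of [kalman_filter()].
#' @return `mom` with elements `sm` (d x T smoothed means) and `sC`
#'   (smoothed covariances) added.
#' @export
kalman_smooth <- function(mom) {
  stopifnot(inherits(mom, "dlm_moments"))
  T_ <- length(mom$f); d <- mom$spec$d
  sm <- matrix(0, d, T_); sC <- array(0, c(d, d, T_))
  sm[, T_] <- mom$m[, T_]; sC[, , T_] <- mom$C[, , T_]
  B <- .backward_gains(mom)
  for (t in rev(seq_len(T_ - 1))) {
    sm[, t] <- mom$m[, t] + B[[t]] %*% (sm[, t + 1] - mom$a[, t + 1])
    V <- mom$C[, , t] + B[[t]] %*% (sC[, , t + 1] - mom$R[, , t + 1]) %*% t(B[[t]])
    sC[, , t] <- (V + t(V)) / 2
  }
  mom$sm <- sm; mom$sC <- sC
  mom
}

#' Smoothed predictive intervals on the data scale
#'
#' @param mom smoothed `dlm_moments` (from [kalman_smooth()]).
#' @param level central interval probability.
#' @return data.frame with `fit`, `lwr`, `upr` per week, back-transformed
#'   if the spec uses a log transform.
#' @export
predictive_intervals <- function(mom, level = 0.95) {
  if (is.null(mom$sm)) mom <- kalman_smooth(mom)
  Fv <- mom$spec$F
  mu <- drop(crossprod(Fv, mom$sm))
  vr <- apply(mom$sC, 3, function(Ct) sum(Fv * (Ct %*% Fv))) + mom$v_hat
  df <- mom$n[length(mom$n)]
  z <- if (is.null(mom$spec$obs_variance)) stats::qt((1 + level) / 2, df) else
    stats::qnorm((1 + level) / 2)
  out <- data.frame(fit = mu, lwr = mu - z * sqrt(vr), upr = mu + z * sqrt(vr))
  if (mom$spec$transform == "log") out[] <- lapply(out, exp)
  out
}

#' Forward-filtering backward-sampling imputation ensemble
#'
#' Draws `M` joint posterior state paths and emits, at missing weeks,
#' posterior-predictive observations (state draw plus observation noise);
#' observed weeks are kept verbatim — imputation only fills gaps.
#'
#' @param spec a [dlm_spec()].
#' @param series `weekly_series` or numeric with `NA` gaps.
#' @param M ensemble size (the analysis default is 100).
#' @param seed integer seed; the ensemble is deterministic given it.
#' @return an object of class `imputation_ensemble`: list with `values`
#'   (T x M matrix, data scale), `mask`, `seed`, `spec`.
#' @export
ffbs_sample <- function(spec, series, M = 100L, seed = 1L) {
  stopifnot(M >= 1)
  set.seed(seed)
  mom <- kalman_filter(spec, series)
  T_ <- length(mom$f); d <- spec$d
  B <- .backward_gains(mom)
  # sampling covariances H_t = C_t - B_t R_{t+1} B_t', shared across members
  L <- vector("list", T_)
  ch <- function(V) {
    V <- (V + t(V)) / 2
    ev <- eigen(V, symmetric = TRUE)
    val <- pmax(ev$values, 0)
    ev$vectors %*% (sqrt(val) * t(ev$vectors))
  }
  L[[T_]] <- ch(mom$C[, , T_])
  for (t in seq_len(T_ - 1)) {
    L[[t]] <- ch(mom$C[, , t] - B[[t]] %*% mom$R[, , t + 1] %*% t(B[[t]]))
  }
  Theta <- matrix(0, d, M)                     # states at t, all members
  Yrep <- matrix(rep(mom$y, M), T_, M)
  Theta <- mom$m[, T_] + L[[T_]] %*% matrix(stats::rnorm(d * M), d, M)
  sdv <- sqrt(mom$v_hat)
  emit <- function(t, Theta) {
    if (!mom$obs[t]) {
      Yrep[t, ] <<- drop(crossprod(spec$F, Theta)) + stats::rnorm(M, 0, sdv)
    }
  }
  emit(T_, Theta)
  for (t in rev(seq_len(T_ - 1))) {
    h <- mom$m[, t] + B[[t]] %*% (Theta - mom$a[, t + 1])
    Theta <- h + L[[t]] %*% matrix(stats::rnorm(d * M), d, M)
    emit(t, Theta)
  }
  if (spec$transform == "log") Yrep <- exp(Yrep)
  grid <- if (inherits(series, "weekly_series")) series_grid(series) else NULL
  structure(list(values = Yrep, mask = mom$obs, seed = seed, spec = spec,
                 grid = grid),
            class = "imputation_ensemble")
}

#' @export
print.imputation_ensemble <- function(x, ...) {
  cat(sprintf("<imputation_ensemble> %d weeks x %d members, %d imputed weeks\n",
              nrow(x$values), ncol(x$values), sum(!x$mask)))
  invisible(x)
}

#' Trend / seasonal decomposition of a smoothed DLM fit
#'
#' @param spec a [dlm_spec()] with both a trend and a seasonal block.
#' @param series the data.
#' @return list: `trend` (smoothed level), `seasonal` (smoothed seasonal
#'   signal), `fitted` (their sum), all on the transform scale, and
#'   `seasonal_annual_mean` (data.frame `year`, `mean`) when the series
#'   carries a grid.
#' @export
dlm_decompose <- function(spec, series) {
  if (length(spec$level_idx) == 0 || length(spec$seas_idx) == 0) {
    stop("decomposition needs both a trend and a seasonal block")
  }
  mom <- kalman_smooth(kalman_filter(spec, series))
  trend <- mom$sm[spec$level_idx, ]
  seasonal <- colSums(mom$sm[spec$seas_idx, , drop = FALSE])
  out <- list(trend = trend, seasonal = seasonal, fitted = trend + seasonal,
              moments = mom)
  if (inherits(series, "weekly_series")) {
    g <- series_grid(series)
    out$seasonal_annual_mean <- data.frame(
      year = sort(unique(g$year)),
      mean = as.numeric(tapply(seasonal, g$year, mean)))
  }
  out
}

# default per-variable spec: log scale for strictly positive concentrations
.default_var_spec <- function(name, ...) {
  logvars <- c("chl", .nonneg_vars)
  dlm_spec(transform = if (name %in% logvars) "log" else "raw", ...)
}

#' Impute a whole panel
#'
#' The target variable (chlorophyll) gets a full FFBS posterior-predictive
#' ensemble; every other variable is completed with its smoothed posterior
#' mean. Variables with fewer than 104 observed weeks trigger a warning
#' (the diffuse prior then dominates early).
#'
#' @param panel an `env_panel` with gaps.
#' @param target variable to ensemble-impute (default `"chl"`).
#' @param M ensemble size.
#' @param seed integer seed.
#' @param specs optional named list of [dlm_spec()]s per variable.
#' @return list: `ensemble` (the target's `imputation_ensemble`), `panel`
#'   (the completed panel; the target column holds the ensemble mean), and
#'   `imputed` (named list of logical imputed-week flags).
#' @export
impute_panel <- function(panel, target = "chl", M = 100L, seed = 1L,
                         specs = NULL) {
  stopifnot(target %in% names(panel$series))
  imputed <- list()
  out_series <- panel$series
  ens <- NULL
  for (v in names(panel$series)) {
    s <- panel$series[[v]]
    spec <- if (!is.null(specs[[v]])) specs[[v]] else .default_var_spec(v)
    if (sum(s$mask) < 104L) {
      warning(sprintf("variable '%s' has <104 observed weeks; diffuse prior dominates", v))
    }
    if (v == target) {
      ens <- ffbs_sample(spec, s, M = M, seed = seed)
      filled <- rowMeans(ens$values)
    } else if (all(s$mask)) {
      imputed[[v]] <- rep(FALSE, length(s$values))
      next
    } else {
      mom <- kalman_smooth(kalman_filter(spec, s))
      fit <- drop(crossprod(spec$F, mom$sm))
      if (spec$transform == "log") fit <- exp(fit)
      filled <- ifelse(s$mask, s$values, fit)
    }
    imputed[[v]] <- !s$mask
    out_series[[v]] <- weekly_series(filled, s$start[["year"]], s$start[["week"]],
                                     name = s$name, unit = s$unit)
  }
  list(ensemble = ens,
       panel = env_panel(out_series, panel$annual),
       imputed = imputed)
}
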