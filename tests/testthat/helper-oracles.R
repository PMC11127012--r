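# Independent oracles used across the suite. These never call the code
# paths they check.

# Joint-Gaussian conditioning oracle for a known-variance DLM: builds the
# full prior over stacked states from (m0, C0, G, W), conditions on the
# observed y, and returns exact posterior (smoothed) state means and the
# marginal covariances per week.
dlm_conditioning_oracle <- function(Fv, G, W, V, m0, C0, y) {
  d <- length(Fv); T_ <- length(y)
  obs <- which(!is.na(y))
  # prior mean of stacked states
  mu <- matrix(0, d, T_)
  mu[, 1] <- G %*% m0
  for (t in 2:max(T_, 2)) if (t <= T_) mu[, t] <- G %*% mu[, t - 1]
  # prior covariance blocks: S[ , , s, t] = Cov(theta_s, theta_t)
  Sig <- array(0, c(d, d, T_, T_))
  Sig[, , 1, 1] <- G %*% C0 %*% t(G) + W
  for (t in 2:max(T_, 2)) {
    if (t > T_) break
    Sig[, , t, t] <- G %*% Sig[, , t - 1, t - 1] %*% t(G) + W
  }
  for (s in 1:T_) for (t in s:T_) {
    if (t > s) Sig[, , s, t] <- Sig[, , s, s] %*% t(.mpow(G, t - s))
    Sig[, , t, s] <- t(Sig[, , s, t])
  }
  # stack
  big_mu <- as.numeric(mu)
  bigS <- matrix(0, d * T_, d * T_)
  for (s in 1:T_) for (t in 1:T_) {
    bigS[((s - 1) * d + 1):(s * d), ((t - 1) * d + 1):(t * d)] <- Sig[, , s, t]
  }
  H <- matrix(0, length(obs), d * T_)
  for (i in seq_along(obs)) {
    H[i, ((obs[i] - 1) * d + 1):(obs[i] * d)] <- Fv
  }
  yo <- y[obs]
  Syy <- H %*% bigS %*% t(H) + diag(V, length(obs))
  Sxy <- bigS %*% t(H)
  post_mu <- big_mu + Sxy %*% solve(Syy, yo - H %*% big_mu)
  post_S <- bigS - Sxy %*% solve(Syy, t(Sxy))
  list(mean = matrix(post_mu, d, T_),
       var_proj = vapply(1:T_, function(t) {
         idx <- ((t - 1) * d + 1):(t * d)
         sum(Fv * (post_S[idx, idx] %*% Fv))
       }, numeric(1)))
}

.mpow <- function(A, k) {
  R <- diag(nrow(A))
  for (i in seq_len(k)) R <- R %*% A
  R
}

# hand-coded scalar Kalman recursion for the local level model
local_level_filter_oracle <- function(y, v, w, m0, c0) {
  m <- numeric(length(y)); cc <- numeric(length(y))
  mp <- m0; cp <- c0
  for (t in seq_along(y)) {
    a <- mp; r <- cp + w
    if (is.na(y[t])) { mp <- a; cp <- r } else {
      q <- r + v
      k <- r / q
      mp <- a + k * (y[t] - a)
      cp <- r - k * r
    }
    m[t] <- mp; cc[t] <- cp
  }
  list(m = m, C = cc)
}

# direct Poisson log-likelihood maximization (BFGS), independent of glm
poisson_ml_oracle <- function(y, X) {
  X1 <- cbind(1, as.matrix(X))
  nll <- function(b) {
    eta <- drop(X1 %*% b)
    -sum(y * eta - exp(eta))
  }
  gr <- function(b) {
    eta <- drop(X1 %*% b)
    -drop(crossprod(X1, y - exp(eta)))
  }
  fit <- optim(numeric(ncol(X1)), nll, gr, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
  fit$par
}

# explicit two-regression Granger F via lm() on data frames
granger_f_oracle <- function(x, y, L) {
  x <- x - mean(x); y <- y - mean(y)
  n <- length(y)
  df <- data.frame(y0 = y[(L + 1):n])
  for (l in 1:L) {
    df[[paste0("yl", l)]] <- y[(L + 1 - l):(n - l)]
    df[[paste0("xl", l)]] <- x[(L + 1 - l):(n - l)]
  }
  f0 <- lm(stats::reformulate(paste0("yl", 1:L), "y0"), df)
  f1 <- lm(stats::reformulate(c(paste0("yl", 1:L), paste0("xl", 1:L)), "y0"), df)
  rss0 <- sum(resid(f0)^2); rss1 <- sum(resid(f1)^2)
  m <- nrow(df)
  ((rss0 - rss1) / L) / (rss1 / (m - 2 * L - 1))
}

# small complete panel for fast tests
tiny_panel <- function(seed = 1, n_years = 6) {
  cfg <- synth_config(n_years = n_years, seed = seed,
                      missingness = list(point_rate = 0,
                                         biweekly_years = integer(0),
                                         block_years = integer(0)))
  generate_panel(cfg)
}
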