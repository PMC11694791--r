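# Independent oracles and fixture builders shared across the suite.

# Brute-force Lomb-Scargle oracle: per-period least-squares sine+cosine fit
# via the 2x2 normal equations, power = variance reduction over 2*sigma^2.
ls_oracle <- function(t, y, periods) {
  yc <- y - mean(y)
  s2 <- sum(yc^2) / (length(y) - 1)
  vapply(periods, function(p) {
    w <- 2 * pi / p
    X <- cbind(cos(w * t), sin(w * t))
    b <- solve(crossprod(X), crossprod(X, yc))
    (sum(yc^2) - sum((yc - X %*% b)^2)) / (2 * s2)
  }, numeric(1))
}

# Sinusoid-rate count record: counts = round(base * (1 + amp*sin(2*pi*t/P)))
# plus optional Gaussian jitter, clamped at zero.
sine_record <- function(period_h, days, bin_minutes = 5, base = 50,
                        amp = 1, noise_sd = 0, seed = NULL,
                        channel = "wheel") {
  n <- as.integer(round(days * 24 * 60 / bin_minutes))
  t <- (seq_len(n) - 1) * bin_minutes / 60
  x <- base * (1 + amp * sin(2 * pi * t / period_h))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    x <- x + rnorm(n, 0, noise_sd)
  }
  activity_record(pmax(round(x), 0), bin_minutes, channel = channel)
}

# Phase-integrated chirp record with linear period ramp from->to over the
# record; returns list(record, period_of = function(t_hours)).
chirp_record <- function(from_h, to_h, days, bin_minutes = 5, base = 50) {
  n <- as.integer(round(days * 24 * 60 / bin_minutes))
  dt <- bin_minutes / 60
  tt <- (seq_len(n) - 1) * dt + dt / 2
  t_end <- n * dt
  period_of <- function(t) from_h + (to_h - from_h) * t / t_end
  phi <- cumsum(2 * pi * dt / period_of(tt))
  rec <- activity_record(pmax(round(base * (1 + sin(phi))), 0), bin_minutes)
  list(record = rec, period_of = period_of)
}

# Right-angle zigzag microevent fixture: corners at
# (0,0),(2,0),(2,2),(4,2),...,(8,8) -- nine microevents with 2-cm legs.
zigzag_corners <- function() {
  xs <- c(0, 2, 2, 4, 4, 6, 6, 8, 8)
  ys <- c(0, 0, 2, 2, 4, 4, 6, 6, 8)
  cbind(xs, ys)
}

# Hand OLS on (x, y) pairs: returns the slope.
hand_ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Frequency-space tolerance check: peak within one grid step of the target.
within_one_grid_step <- function(peak_h, target_h, grid_df) {
  is.finite(peak_h) && abs(1 / peak_h - 1 / target_h) <= grid_df + 1e-12
}
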