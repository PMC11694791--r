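#' Continuous wavelet scalogram of an activity record
#'
#' Analytic continuous wavelet transform on a geometric period grid with 24
#' voices per octave (adjacent periods differ by exactly `2^(1/24)`).
#' The default wavelet is the generalized Morse family with `gamma = 3`,
#' `beta = 20` (a Morlet-like time-bandwidth); a classic Morlet
#' (`omega0 = 6`) is available via `family = "morlet"`. Wavelets are
#' bandpass-normalized (peak value 2 in the frequency domain), so a
#' unit-amplitude tone produces the same peak power at every period.
#'
#' Gaps are linearly interpolated before the transform and the affected
#' times are excluded from the valid region via the cone of influence: the
#' per-time maximum trustworthy period is the distance to the nearest record
#' edge or gap divided by the wavelet's e-folding-time factor (computed
#' numerically from the time-domain envelope).
#'
#' The series is standardized (z-scored) before the transform by default so
#' that power is comparable across animals and epochs.
#'
#' @param record an [activity_record()]
#' @param period_range numeric length-2 period bounds in hours
#' @param family `"morse"` or `"morlet"`
#' @param gamma,beta Morse parameters (default 3, 20)
#' @param omega0 Morlet center frequency (default 6)
#' @param voices voices per octave (default 24)
#' @param standardize z-score the series first (default `TRUE`)
#' @return object of class `scalogram`: `times` (h), `periods` (h,
#'   geometric), `power` (time x period matrix), `coi` (max valid period
#'   per time, h), plus the wavelet parameters.
#' @export
cwt_scalogram <- function(record, period_range = c(16, 96),
                          family = c("morse", "morlet"),
                          gamma = 3, beta = 20, omega0 = 6,
                          voices = 24, standardize = TRUE) {
  stopifnot(inherits(record, "activity_record"))
  family <- match.arg(family)
  if (length(period_range) != 2L || min(period_range) <= 0)
    stop("cwt_scalogram: invalid period_range")
  pmin <- min(period_range); pmax <- max(period_range)
  dt <- record$bin_minutes / 60
  n <- length(record$counts)
  if (n * dt < 2 * pmax)
    stop("cwt_scalogram: record shorter than twice the longest requested period")

  x <- record$counts
  tt <- time_hours(record)
  if (any(record$gap_mask)) {
    ok <- !record$gap_mask
    if (sum(ok) < 2L) stop("cwt_scalogram: record almost fully masked")
    x <- stats::approx(tt[ok], x[ok], xout = tt, rule = 2)$y
  }
  if (standardize) {
    s <- stats::sd(x)
    x <- if (s > 0) (x - mean(x)) / s else x - mean(x)
  }

  nj <- ceiling(voices * log2(pmax / pmin))
  periods <- pmin * 2^((0:nj) / voices)
  periods <- periods[periods <= pmax * 2^(0.5 / voices)]

  # zero-pad to the next power of two to suppress wraparound contamination
  npad <- 2^ceiling(log2(n + pmax / dt))
  xf <- stats::fft(c(x, numeric(npad - n)))
  k <- 0:(npad - 1)
  omega <- 2 * pi * k / (npad * dt)       # rad/hour, DFT bins
  pos <- k <= floor(npad / 2) & omega > 0 # analytic: positive frequencies only

  power <- matrix(0, nrow = n, ncol = length(periods))
  for (j in seq_along(periods)) {
    wc <- 2 * pi / periods[j]
    psi <- numeric(npad)
    if (family == "morse") {
      wp <- (beta / gamma)^(1 / gamma)    # mother peak frequency
      s <- wp / wc                        # scale mapping peak to wc
      w <- omega[pos]
      psi[pos] <- 2 * exp(beta * log(s * w / wp) - (s * w)^gamma + beta / gamma)
    } else {
      s <- omega0 / wc
      psi[pos] <- 2 * exp(-0.5 * (s * omega[pos] - omega0)^2)
    }
    wcoef <- stats::fft(xf * psi, inverse = TRUE) / npad
    power[, j] <- Mod(wcoef[1:n])^2
  }

  efold <- wavelet_efold_factor(family, gamma, beta, omega0)
  dist_edge <- pmin(tt - tt[1], tt[n] - tt)
  if (any(record$gap_mask)) {
    gap_t <- tt[record$gap_mask]
    dist_gap <- vapply(tt, function(ti) min(abs(ti - gap_t)), numeric(1))
    dist_edge <- pmin(dist_edge, dist_gap)
  }
  coi <- dist_edge / efold

  structure(list(times = tt, periods = periods, power = power, coi = coi,
                 family = family, gamma = gamma, beta = beta,
                 omega0 = omega0, voices = voices,
                 standardized = standardize),
            class = "scalogram")
}

# e-folding half-width of the time-domain envelope, in units of the period:
# computed numerically from the mother wavelet synthesized on a fine grid.
wavelet_efold_factor <- function(family, gamma, beta, omega0) {
  n <- 8192L
  period <- 1                      # arbitrary units; factor is scale-free
  dt <- period / 64
  k <- 0:(n - 1)
  omega <- 2 * pi * k / (n * dt)
  pos <- k <= n / 2 & omega > 0
  psi <- numeric(n)
  wc <- 2 * pi / period
  if (family == "morse") {
    wp <- (beta / gamma)^(1 / gamma)
    s <- wp / wc
    psi[pos] <- 2 * exp(beta * log(s * omega[pos] / wp) -
                          (s * omega[pos])^gamma + beta / gamma)
  } else {
    s <- omega0 / wc
    psi[pos] <- 2 * exp(-0.5 * (s * omega[pos] - omega0)^2)
  }
  w <- Mod(stats::fft(psi, inverse = TRUE))
  env <- w / max(w)                # peak at index 1 (t = 0), wraps around
  half <- env[1:(n / 2)]
  ie <- which(half < exp(-1))[1]
  ((ie - 1) * dt) / period
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf(
    "<scalogram> %s(gamma=%g,beta=%g) %d times x %d periods (%.1f-%.1f h), %d voices/octave\n",
    x$family, x$gamma, x$beta, nrow(x$power), ncol(x$power),
    min(x$periods), max(x$periods), x$voices))
  invisible(x)
}

#' Wavelet ridge: instantaneous peak period
#'
#' For each time point, the period of maximal scalogram power among periods
#' inside the cone of influence. Points where no period is valid carry `NA`
#' and `valid = FALSE`. The ridge is optionally median-smoothed over a 12-h
#' window.
#'
#' @param scal a `scalogram`
#' @param smooth logical, apply running-median smoothing (default `TRUE`)
#' @param smooth_hours smoothing window length (default 12)
#' @return object of class `ridge`: `times`, `peak_period`, `valid`
#' @export
extract_ridge <- function(scal, smooth = TRUE, smooth_hours = 12) {
  stopifnot(inherits(scal, "scalogram"))
  np <- length(scal$periods)
  nt <- length(scal$times)
  peak <- rep(NA_real_, nt)
  valid <- rep(FALSE, nt)
  for (i in seq_len(nt)) {
    ok <- scal$periods <= scal$coi[i]
    if (!any(ok)) next
    j <- which(ok)[which.max(scal$power[i, ok])]
    peak[i] <- scal$periods[j]
    valid[i] <- TRUE
  }
  if (smooth && any(valid)) {
    dt <- if (nt > 1) scal$times[2] - scal$times[1] else 1
    kk <- max(3L, as.integer(round(smooth_hours / dt)))
    if (kk %% 2L == 0L) kk <- kk + 1L
    idx <- which(valid)
    if (length(idx) > kk)
      peak[idx] <- as.numeric(stats::runmed(peak[idx], kk, endrule = "median"))
  }
  structure(list(times = scal$times, peak_period = peak, valid = valid),
            class = "ridge")
}

#' Scale-averaged wavelet band power
#'
#' Mean scalogram power over the periods falling in a band, as a per-time
#' series. With bandpass-normalized wavelets the power of a unit tone is
#' period-independent at its ridge, so a plain (unweighted) mean across
#' in-band periods is already balanced across scales; averaging the result
#' over a time window gives the scalar band power used for window selection
#' and circadian-versus-infradian contrasts.
#'
#' @param scal a `scalogram`
#' @param band numeric length-2 period bounds in hours, within the scalogram
#'   range
#' @return object of class `band_power`: `times`, `band`, `value`
#' @export
scale_averaged_power <- function(scal, band) {
  stopifnot(inherits(scal, "scalogram"))
  if (length(band) != 2L || diff(range(band)) <= 0)
    stop("scale_averaged_power: empty band")
  inb <- scal$periods >= min(band) & scal$periods <= max(band)
  if (!any(inb)) stop("scale_averaged_power: no scalogram periods in band")
  value <- rowMeans(scal$power[, inb, drop = FALSE])
  structure(list(times = scal$times, band = sort(band), value = value),
            class = "band_power")
}

#' Time-mean band power over a window
#'
#' @param bp a `band_power`
#' @param window optional [time_window()]; default full span
#' @return scalar mean power
#' @export
mean_band_power <- function(bp, window = NULL) {
  stopifnot(inherits(bp, "band_power"))
  keep <- rep(TRUE, length(bp$times))
  if (!is.null(window)) {
    keep <- bp$times >= window$start_offset &
      bp$times < window$start_offset + window$duration
  }
  mean(bp$value[keep])
}
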