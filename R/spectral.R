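#' Lomb-Scargle periodogram of an activity record
#'
#' Computes the classical normalized Lomb-Scargle periodogram of the unmasked
#' bins of a count series, on a grid uniform in frequency across the
#' requested period range. Masked bins are simply excluded, which is the
#' unevenly-sampled path the Lomb-Scargle estimator is built for. Power is
#' normalized by the sample variance of the unmasked counts, so under white
#' Gaussian noise each power follows (approximately) a unit-exponential law
#' and the familiar analytic false-alarm threshold applies.
#'
#' The grid step is `1 / (oversample * span)` in frequency, i.e. `oversample`
#' grid points per independent Fourier frequency.
#'
#' @param record an [activity_record()]
#' @param period_range numeric length-2, period bounds in hours
#'   (default `c(20, 96)`, the canonical circadian + infradian scan).
#' @param oversample frequency-grid oversampling factor (default 10)
#' @param alpha family-wise significance level for the threshold
#'   (default 0.001)
#' @param n_independent number of independent frequency trials used for the
#'   threshold. Default: a Horne-Baliunas-style estimate restricted to the
#'   scanned band, `round(2 * span * (f_hi - f_lo))` -- twice the number of
#'   Fourier spacings in the band, which reduces to the classical
#'   "approximately n" estimate when the scan covers the full Nyquist range.
#' @param sig_method `"analytic"` (exponential tail) or `"permutation"`
#'   (circular-shift null, see `n_perm`)
#' @param n_perm number of circular shifts for the permutation null
#' @return object of class `periodogram`: `periods` (hours, decreasing with
#'   frequency), `freq` (cycles/hour), `power`, `sig_level`, `alpha`,
#'   `n_effective`, `n_independent`.
#' @export
lomb_scargle <- function(record, period_range = c(20, 96), oversample = 10,
                         alpha = 0.001, n_independent = NULL,
                         sig_method = c("analytic", "permutation"),
                         n_perm = 200) {
  stopifnot(inherits(record, "activity_record"))
  sig_method <- match.arg(sig_method)
  if (length(period_range) != 2L || any(!is.finite(period_range)) ||
      min(period_range) <= 0 || diff(range(period_range)) <= 0)
    stop("lomb_scargle: invalid period_range")
  ok <- !record$gap_mask
  t <- time_hours(record)[ok]
  y <- record$counts[ok]
  n <- length(y)
  if (n < 8L) stop("lomb_scargle: fewer than 8 unmasked bins")
  span <- diff(range(t))
  if (span < 3 * max(period_range))
    warning("lomb_scargle: unmasked span covers fewer than 3 cycles of the ",
            "longest requested period")
  f_lo <- 1 / max(period_range)
  f_hi <- 1 / min(period_range)
  df <- 1 / (oversample * span)
  freq <- seq(f_lo, f_hi, by = df)
  if (freq[length(freq)] < f_hi - 1e-12) freq <- c(freq, f_hi)

  ybar <- mean(y)
  yc <- y - ybar
  ss <- sum(yc^2)
  sigma2 <- ss / (n - 1)
  power <- if (sigma2 <= 0) numeric(length(freq)) else
    ls_power_tau(t, yc, 2 * pi * freq, sigma2)

  m <- if (is.null(n_independent)) max(1L, round(2 * span * (f_hi - f_lo)))
       else n_independent
  sig <- if (sig_method == "analytic") {
    significance_level(n, alpha, m)
  } else {
    ls_permutation_threshold(t, y, freq, alpha, n_perm)
  }
  structure(list(periods = 1 / freq, freq = freq, power = power,
                 sig_level = sig, alpha = alpha, n_effective = n,
                 n_independent = m, oversample = oversample,
                 grid_df = df),
            class = "periodogram")
}

# Classical Lomb formulation with the tau phase offset, vectorized over
# frequencies in chunks to bound memory.
ls_power_tau <- function(t, yc, omega, sigma2, chunk = 64L) {
  p <- numeric(length(omega))
  for (i0 in seq(1L, length(omega), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, length(omega))
    w <- omega[idx]
    wt <- t %o% w                               # n x k
    tau_num <- colSums(sin(2 * wt))
    tau_den <- colSums(cos(2 * wt))
    wtau <- 0.5 * atan2(tau_num, tau_den)       # omega * tau
    arg <- sweep(wt, 2, wtau, "-")
    ca <- cos(arg); sa <- sin(arg)
    ycs <- colSums(yc * ca); yss <- colSums(yc * sa)
    cc <- colSums(ca * ca);  ssm <- colSums(sa * sa)
    term_c <- ifelse(cc > 0, ycs^2 / cc, 0)
    term_s <- ifelse(ssm > 0, yss^2 / ssm, 0)
    p[idx] <- (term_c + term_s) / (2 * sigma2)
  }
  p
}

#' @export
print.periodogram <- function(x, ...) {
  cat(sprintf(
    "<periodogram> %d grid points, %.1f-%.1f h, alpha=%g, sig_level=%.2f, n=%d\n",
    length(x$power), min(x$periods), max(x$periods), x$alpha, x$sig_level,
    x$n_effective))
  invisible(x)
}

#' Analytic family-wise significance threshold for Lomb-Scargle power
#'
#' Under Gaussian white noise, each normalized Lomb-Scargle power follows a
#' unit-exponential law, so the maximum over `n_independent` independent
#' frequencies exceeds `z` with probability `1 - (1 - exp(-z))^M`. The
#' returned threshold sets that family-wise false-alarm probability to
#' `alpha`.
#'
#' @param n_effective number of unmasked samples (> 2; enters only as a
#'   validity check: the exponential tail is the large-sample law)
#' @param alpha family-wise false-alarm probability in (0, 1)
#' @param n_independent number of independent frequency trials
#' @return power threshold (scalar)
#' @export
significance_level <- function(n_effective, alpha, n_independent) {
  if (n_effective <= 2) stop("significance_level: n_effective must exceed 2")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("significance_level: alpha must lie in (0, 1)")
  m <- max(1, n_independent)
  -log(1 - (1 - alpha)^(1 / m))
}

# Circular-shift permutation null: threshold is the (1 - alpha) quantile of
# the max power over n_perm circular shifts of the counts.
ls_permutation_threshold <- function(t, y, freq, alpha, n_perm) {
  n <- length(y)
  shifts <- floor(seq(1, n - 1, length.out = min(n_perm, n - 1)))
  mx <- vapply(shifts, function(s) {
    ys <- y[c((s + 1):n, 1:s)]
    ysc <- ys - mean(ys)
    s2 <- sum(ysc^2) / (n - 1)
    if (s2 <= 0) return(0)
    max(ls_power_tau(t, ysc, 2 * pi * freq, s2))
  }, numeric(1))
  as.numeric(stats::quantile(mx, 1 - alpha, type = 1))
}

#' Percentage amplitude spectral density per period band
#'
#' Sums the Lomb-Scargle power of all significantly rhythmic grid points
#' (power above the periodogram's threshold) within each band, normalizes by
#' the significant sum over the full edge span, and expresses the result as a
#' percentage. The default edges `c(20, 27, 96)` split the scan into a
#' circadian (20-27 h) and an infradian (27-96 h) band; 27 h is used as the
#' divider because it sits near the upper entrainment limit of the circadian
#' clock, so longer periods cannot plausibly be of circadian origin.
#'
#' When no grid point is significant the partition is undefined and all
#' percentages are `NA`.
#'
#' @param pg a `periodogram`
#' @param band_edges increasing period bounds in hours; band *i* is
#'   `[edge_i, edge_{i+1})`, the last band right-closed.
#' @return object of class `band_partition`: `band_edges`, `asd_percent`
#'   (named by band), `total_sig_density`, `n_significant`.
#' @export
percent_asd <- function(pg, band_edges = c(20, 27, 96)) {
  stopifnot(inherits(pg, "periodogram"))
  band_edges <- sort(band_edges)
  if (length(band_edges) < 2L)
    stop("percent_asd: need at least two band edges")
  prng <- range(pg$periods)
  if (band_edges[1] < prng[1] - 1e-6 ||
      band_edges[length(band_edges)] > prng[2] + 1e-6)
    stop("percent_asd: band edges outside periodogram range")
  p <- pg$periods
  sig <- pg$power > pg$sig_level
  lo <- band_edges[1]; hi <- band_edges[length(band_edges)]
  in_span <- p >= lo - 1e-9 & p <= hi + 1e-9
  total <- sum(pg$power[sig & in_span])
  nb <- length(band_edges) - 1L
  nm <- paste0(band_edges[-length(band_edges)], "-", band_edges[-1], "h")
  if (sum(sig & in_span) == 0L || total <= 0) {
    asd <- stats::setNames(rep(NA_real_, nb), nm)
  } else {
    asd <- vapply(seq_len(nb), function(i) {
      e1 <- band_edges[i]; e2 <- band_edges[i + 1]
      inb <- if (i == nb) p >= e1 - 1e-9 & p <= e2 + 1e-9
             else p >= e1 - 1e-9 & p < e2 - 1e-9
      100 * sum(pg$power[sig & inb]) / total
    }, numeric(1))
    names(asd) <- nm
  }
  structure(list(band_edges = band_edges, asd_percent = asd,
                 total_sig_density = total,
                 n_significant = sum(sig & in_span)),
            class = "band_partition")
}

#' @export
print.band_partition <- function(x, ...) {
  cat("<band_partition> %ASD:",
      paste(sprintf("%s=%.1f", names(x$asd_percent), x$asd_percent),
            collapse = ", "),
      sprintf(" (n_sig=%d)\n", x$n_significant))
  invisible(x)
}

#' Period of the highest significant periodogram peak
#'
#' @param pg a `periodogram`
#' @param search_range period bounds in hours (default `c(20, 96)`); must lie
#'   within the periodogram range.
#' @return peak period in hours, or `NA` when no grid point in range is
#'   significant.
#' @export
highest_peak <- function(pg, search_range = c(20, 96)) {
  stopifnot(inherits(pg, "periodogram"))
  prng <- range(pg$periods)
  if (min(search_range) < prng[1] - 1e-6 || max(search_range) > prng[2] + 1e-6)
    stop("highest_peak: search_range outside periodogram range")
  inr <- pg$periods >= min(search_range) - 1e-9 &
         pg$periods <= max(search_range) + 1e-9
  cand <- which(inr & pg$power > pg$sig_level)
  if (length(cand) == 0L) return(NA_real_)
  pg$periods[cand[which.max(pg$power[cand])]]
}

#' Trough-anchored split of spectral power below 24 h
#'
#' For clock-deficient animals the dominant locomotor period varies from
#' animal to animal (typically 2-8 h), so a fixed circadian/infradian divider
#' cannot be used. Instead, the dominant peak of a baseline periodogram
#' (computed over a 96-h pre-treatment span, period range up to 24 h) is
#' located, and the first power trough at periods above that peak -- `Tro` --
#' becomes the animal-specific divider. The significant power of a target
#' periodogram is then partitioned into the segments "0 h to Tro" and
#' "Tro to 24 h" and expressed as percentages of their sum.
#'
#' The baseline power is smoothed with a centered 5-point moving average
#' before the trough search (raw periodograms are serrated); ties break
#' toward the smaller period. If no trough exists below 24 h, the midpoint
#' between the peak and 24 h is used and the result is flagged.
#'
#' @param pg target `periodogram` (period range within 0-24 h)
#' @param baseline `periodogram` used to locate the peak and trough;
#'   defaults to `pg` itself.
#' @param smooth logical; apply the 5-point moving average (default `TRUE`)
#' @return object of class `trough_split`: `tro`, `asd_below_pct`,
#'   `asd_above_pct`, `peak_period`, `fallback` (logical: midpoint rule
#'   used).
#' @export
trough_after_peak <- function(pg, baseline = pg, smooth = TRUE) {
  stopifnot(inherits(pg, "periodogram"), inherits(baseline, "periodogram"))
  if (max(baseline$periods) > 24 + 1e-6)
    stop("trough_after_peak: baseline periodogram must be restricted to <= 24 h")
  pw <- baseline$power
  if (smooth && length(pw) >= 5L) {
    sm <- stats::filter(pw, rep(1 / 5, 5), sides = 2)
    pw <- ifelse(is.na(sm), pw, as.numeric(sm))
  }
  ipk <- which.max(pw)
  peak_period <- baseline$periods[ipk]
  # periods increase as the frequency index decreases; walk toward longer
  # periods looking for the first local minimum (ties -> smaller period)
  tro <- NA_real_
  if (ipk > 2L) {
    for (i in (ipk - 1L):2L) {
      if (pw[i] < pw[i + 1L] && pw[i] <= pw[i - 1L]) {
        tro <- baseline$periods[i]
        break
      }
    }
  }
  fallback <- FALSE
  if (!is.finite(tro)) {
    tro <- (peak_period + 24) / 2
    fallback <- TRUE
  }
  p <- pg$periods
  sig <- pg$power > pg$sig_level
  below <- sig & p < tro
  above <- sig & p >= tro & p <= 24 + 1e-9
  tot <- sum(pg$power[below | above])
  if (tot > 0) {
    bel <- 100 * sum(pg$power[below]) / tot
    abv <- 100 * sum(pg$power[above]) / tot
  } else {
    bel <- NA_real_; abv <- NA_real_
  }
  structure(list(tro = tro, asd_below_pct = bel, asd_above_pct = abv,
                 peak_period = peak_period, fallback = fallback),
            class = "trough_split")
}

#' @export
print.trough_split <- function(x, ...) {
  cat(sprintf(
    "<trough_split> peak %.2f h, Tro %.2f h%s: below %.1f%%, above %.1f%%\n",
    x$peak_period, x$tro, if (x$fallback) " (midpoint fallback)" else "",
    x$asd_below_pct, x$asd_above_pct))
  invisible(x)
}

#' Composite matrix of normalized periodograms
#'
#' Interpolates each periodogram onto a common period grid and divides each
#' row by its own maximum, the standard display for comparing spectral shape
#' across animals. Rows of periodograms without any finite power are left as
#' zeros.
#'
#' @param pgs list of `periodogram` objects
#' @param n_grid number of common grid points (default 500)
#' @return list with `periods` (common grid, hours) and `matrix`
#'   (one normalized row per periodogram), plus `significant` (logical
#'   per row: any point above its own threshold).
#' @export
composite_periodogram <- function(pgs, n_grid = 500) {
  stopifnot(length(pgs) > 0L, all(vapply(pgs, inherits, TRUE, "periodogram")))
  lo <- max(vapply(pgs, function(p) min(p$periods), numeric(1)))
  hi <- min(vapply(pgs, function(p) max(p$periods), numeric(1)))
  grid <- seq(lo, hi, length.out = n_grid)
  mat <- t(vapply(pgs, function(p) {
    v <- stats::approx(p$periods, p$power, xout = grid, rule = 2)$y
    mx <- max(v)
    if (is.finite(mx) && mx > 0) v / mx else v * 0
  }, numeric(n_grid)))
  sig <- vapply(pgs, function(p) any(p$power > p$sig_level), logical(1))
  list(periods = grid, matrix = mat, significant = sig)
}
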