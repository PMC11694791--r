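# Evaluate code with a local RNG state: bit-reproducible for a fixed seed
# and side-effect free for the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

as_trajectory <- function(x) {
  if (is.function(x)) x else {
    v <- as.numeric(x)
    function(t) rep(v, length(t))
  }
}

#' Linear ramp trajectory
#'
#' A time course that holds `from` before `t_start` hours, ramps linearly to
#' `to` at `t_end`, and holds `to` after. Used for emergence ramps of the
#' second-component amplitude and for gradual period lengthening.
#'
#' @param from,to start and end values
#' @param t_start,t_end ramp interval in hours
#' @return a function of time (hours)
#' @export
ramp_trajectory <- function(from, to, t_start, t_end) {
  stopifnot(t_end > t_start)
  function(t) {
    w <- pmin(pmax((t - t_start) / (t_end - t_start), 0), 1)
    from + w * (to - from)
  }
}

#' Two-oscillator locomotor specification
#'
#' Parameters of the synthetic locomotor generator: a circadian (SCN)
#' oscillator at a fixed period and a second, dopamine-oscillator-like (DO)
#' component whose period and amplitude may change over time. The DO phase
#' integrates an instantaneous period that can be modulated by the phase
#' difference to the SCN (relative coordination).
#'
#' @param scn_period circadian period in hours (default 24)
#' @param scn_amplitude SCN gate amplitude (dimensionless, default 1)
#' @param do_period DO period trajectory: a constant (hours) or a function
#'   of time in hours (see [ramp_trajectory()]); default 48
#' @param do_amplitude DO gate amplitude: constant or function of time;
#'   default 1
#' @param coordination_gain period modulation in hours per unit
#'   `sin(phi_scn - phi_do)` (default 0 = no relative coordination)
#' @param baseline_rate expected counts per bin at closed gates (default 2)
#' @param noise `"poisson"` or `"negbin"`
#' @param dispersion negative-binomial size parameter (required for
#'   `noise = "negbin"`)
#' @param seed RNG seed
#' @return object of class `oscillator_spec`
#' @export
oscillator_spec <- function(scn_period = 24, scn_amplitude = 1,
                            do_period = 48, do_amplitude = 1,
                            coordination_gain = 0, baseline_rate = 2,
                            noise = c("poisson", "negbin"),
                            dispersion = NULL, seed = 1L) {
  noise <- match.arg(noise)
  if (noise == "negbin" && is.null(dispersion))
    stop("oscillator_spec: negbin noise needs a dispersion parameter")
  if (scn_period <= 0) stop("oscillator_spec: scn_period must be positive")
  if (scn_amplitude < 0) stop("oscillator_spec: amplitudes must be >= 0")
  structure(list(scn_period = scn_period, scn_amplitude = scn_amplitude,
                 do_period = as_trajectory(do_period),
                 do_amplitude = as_trajectory(do_amplitude),
                 coordination_gain = coordination_gain,
                 baseline_rate = baseline_rate, noise = noise,
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "oscillator_spec")
}

#' Simulate a two-oscillator locomotor count series
#'
#' The count rate is multiplicative log-linear with half-rectified cosine
#' gates:
#' `rate(t) = baseline * exp(a_scn * g(phi_scn) + a_do(t) * g(phi_do))`
#' with `g(phi) = max(cos(phi), 0)`, which yields actogram-like off/on
#' activity blocks with analytically known component periods. The DO phase
#' integrates `2*pi / T_do(t)` with
#' `T_do(t) = trajectory(t) + gain * sin(phi_scn - phi_do)` (relative
#' coordination: the instantaneous period depends on the phase angle to the
#' circadian oscillator). Counts are drawn per bin from the requested noise
#' model. Output is bit-identical for a fixed seed.
#'
#' @param spec an [oscillator_spec()]
#' @param days number of simulated days (>= 1)
#' @param bin_minutes bin width (default 5)
#' @param gap_spans optional list of `c(start_h, end_h)` spans to mask
#' @return an [activity_record()] with `channel = "wheel"`
#' @export
simulate_locomotor <- function(spec, days, bin_minutes = 5, gap_spans = NULL) {
  stopifnot(inherits(spec, "oscillator_spec"), days >= 1)
  n <- as.integer(round(days * 24 * 60 / bin_minutes))
  dt <- bin_minutes / 60
  tt <- (seq_len(n) - 1) * dt + dt / 2      # bin centers
  phi_scn <- 2 * pi * tt / spec$scn_period
  t_base <- spec$do_period(tt)
  if (any(!is.finite(t_base)) || any(t_base <= 0))
    stop("simulate_locomotor: do_period trajectory must stay positive")
  phi_do <- numeric(n)
  g <- spec$coordination_gain
  if (g == 0) {
    # pure integration of 2*pi/T(t)
    phi_do <- cumsum(2 * pi * dt / t_base) - 2 * pi * dt / t_base[1] / 2
  } else {
    ph <- 0
    for (i in seq_len(n)) {
      ti <- t_base[i] + g * sin(phi_scn[i] - ph)
      if (ti <= 0) stop("simulate_locomotor: modulated period became non-positive")
      phi_do[i] <- ph
      ph <- ph + 2 * pi * dt / ti
    }
  }
  gate <- function(phi) pmax(cos(phi), 0)
  a_do <- spec$do_amplitude(tt)
  rate <- spec$baseline_rate *
    exp(spec$scn_amplitude * gate(phi_scn) + a_do * gate(phi_do))
  counts <- with_seed(spec$seed, {
    if (spec$noise == "poisson") stats::rpois(n, rate)
    else stats::rnbinom(n, size = spec$dispersion, mu = rate)
  })
  mask <- rep(FALSE, n)
  for (sp in gap_spans) {
    mask[tt >= sp[1] & tt < sp[2]] <- TRUE
  }
  activity_record(counts, bin_minutes = bin_minutes, channel = "wheel",
                  gap_mask = mask)
}

#' Sleep-wake pattern specification
#'
#' @param cycle_period infradian cycle length in hours (default 48)
#' @param active_fraction daily sleep fraction on active (short-sleep) days
#'   (default 0.35, the 30-40\% regime)
#' @param inactive_fraction daily sleep fraction on inactive days (default
#'   0.70, the 60-80\% regime)
#' @param bout_minutes mean sleep-bout length in minutes (default 15)
#' @param wake_rate mean extra PIR counts per wake minute (default 3;
#'   wake minutes always count at least 1)
#' @param seed RNG seed
#' @return object of class `sleep_pattern_spec`
#' @export
sleep_pattern_spec <- function(cycle_period = 48, active_fraction = 0.35,
                               inactive_fraction = 0.70, bout_minutes = 15,
                               wake_rate = 3, seed = 1L) {
  if (active_fraction <= 0 || active_fraction > 1 ||
      inactive_fraction <= 0 || inactive_fraction > 1)
    stop("sleep_pattern_spec: fractions must lie in (0, 1]")
  if (active_fraction > inactive_fraction)
    stop("sleep_pattern_spec: active fraction must not exceed inactive fraction")
  structure(list(cycle_period = cycle_period,
                 active_fraction = active_fraction,
                 inactive_fraction = inactive_fraction,
                 bout_minutes = bout_minutes, wake_rate = wake_rate,
                 seed = as.integer(seed)),
            class = "sleep_pattern_spec")
}

# Random composition of `total` into `parts` pieces, each >= minimum.
rand_composition <- function(total, parts, minimum = 1L) {
  if (parts <= 1L) return(total)
  free <- total - parts * minimum
  cuts <- sort(sample.int(free + parts - 1L, parts - 1L))
  sizes <- diff(c(0L, cuts, free + parts)) - 1L + minimum
  sizes
}

#' Simulate a PIR sleep-wake record
#'
#' Builds a 1-min PIR record whose days alternate between active
#' (short-sleep) and inactive (long-sleep) at the specified cycle. Each
#' day's sleep occupancy is matched exactly to its labeled fraction: the
#' day's sleep-minute quota is split into bouts of random length (mean
#' `bout_minutes`) interleaved with wake bouts. Sleep minutes carry zero
#' counts; wake minutes carry counts >= 1. Day 1 is active.
#'
#' @param spec a [sleep_pattern_spec()]
#' @param days number of days; must be even for a 48-h cycle
#' @return an [activity_record()] with `channel = "pir"`, 1-min bins
#' @export
simulate_pir_sleepwake <- function(spec, days) {
  stopifnot(inherits(spec, "sleep_pattern_spec"), days >= 1)
  if (abs(spec$cycle_period - 48) < 1e-9 && days %% 2 != 0)
    stop("simulate_pir_sleepwake: days must be even for a 48-h cycle")
  days <- as.integer(days)
  with_seed(spec$seed, {
    counts <- integer(0)
    for (d in seq_len(days)) {
      f <- if (d %% 2L == 1L) spec$active_fraction else spec$inactive_fraction
      s_min <- as.integer(round(f * 1440))
      w_min <- 1440L - s_min
      day <- integer(1440)
      if (s_min >= 1440L) {
        # saturated sleep day
        counts <- c(counts, day)
        next
      }
      nb <- max(1L, as.integer(round(s_min / spec$bout_minutes)))
      sleep_bouts <- rand_composition(s_min, nb, minimum = 1L)
      wake_bouts <- if (w_min > 0)
        rand_composition(w_min, nb + 1L, minimum = 0L) else integer(nb + 1L)
      minute_state <- integer(0)
      for (b in seq_len(nb)) {
        minute_state <- c(minute_state, rep(0L, wake_bouts[b]),
                          rep(1L, sleep_bouts[b]))
      }
      minute_state <- c(minute_state, rep(0L, wake_bouts[nb + 1L]))
      wake_idx <- which(minute_state == 0L)
      day[wake_idx] <- 1L + stats::rpois(length(wake_idx),
                                         max(spec$wake_rate - 1, 0))
      counts <- c(counts, day)
    }
    activity_record(counts, bin_minutes = 1, channel = "pir")
  })
}

#' Open-field path specification
#'
#' @param step_cm per-frame step length (default 0.15 cm, about 4.5 cm/s at
#'   30 fps)
#' @param turning_sd angular dispersion of the correlated random walk, in
#'   rad per square-root second (default 0.5): heading increments are
#'   wrapped-normal with per-frame standard deviation
#'   `turning_sd * sqrt(1/fps)`, i.e. rotational diffusion at a rate
#'   independent of the frame rate
#' @param duration_s recording length in seconds (default 600)
#' @param fps frame rate (default 30)
#' @param arena_cm arena side (default 50); the walk reflects at the walls
#' @param seed RNG seed
#' @return object of class `path_spec`
#' @export
path_spec <- function(step_cm = 0.15, turning_sd = 0.5, duration_s = 600,
                      fps = 30, arena_cm = 50, seed = 1L) {
  if (step_cm <= 0) stop("path_spec: step_cm must be positive")
  structure(list(step_cm = step_cm, turning_sd = turning_sd,
                 duration_s = duration_s, fps = fps, arena_cm = arena_cm,
                 seed = as.integer(seed)),
            class = "path_spec")
}

#' Simulate an open-field path of controlled tortuosity
#'
#' Correlated random walk: heading increments are drawn from a normal with
#' per-frame standard deviation `turning_sd * sqrt(1/fps)` (wrapped by
#' construction), constant step length, specular reflection at the arena
#' walls (implemented by folding the free trajectory coordinate-wise, which
#' is exact for axis-aligned walls). `turning_sd = 0` gives a straight
#' path; larger values give more tortuous paths and hence larger spatial d.
#'
#' @param spec a [path_spec()]
#' @return a [path_trace()]
#' @export
simulate_path <- function(spec) {
  stopifnot(inherits(spec, "path_spec"))
  n <- as.integer(round(spec$duration_s * spec$fps))
  a <- spec$arena_cm
  with_seed(spec$seed, {
    h0 <- stats::runif(1, 0, 2 * pi)
    sd_frame <- spec$turning_sd * sqrt(1 / spec$fps)
    inc <- if (sd_frame > 0) stats::rnorm(n - 2, 0, sd_frame)
           else numeric(max(n - 2, 0))
    heading <- cumsum(c(h0, inc))
    xf <- a / 2 + cumsum(c(0, spec$step_cm * cos(heading)))
    yf <- a / 2 + cumsum(c(0, spec$step_cm * sin(heading)))
    fold <- function(z) {
      m <- z %% (2 * a)
      ifelse(m > a, 2 * a - m, m)
    }
    path_trace(fold(xf), fold(yf), fps = spec$fps, arena_cm = a)
  })
}

#' Beat period of two oscillators
#'
#' The envelope period of two superposed oscillators with periods `a` and
#' `b` is `1 / |1/a - 1/b|`. Equal periods are phase-locked (infinite beat
#' period); harmonic period ratios (2:1, 3:1, ...) are also flagged as
#' locked, since harmonically related oscillators hold a fixed phase
#' relationship rather than drifting in and out of phase.
#'
#' @param period_a,period_b oscillator periods in hours (> 0)
#' @param harmonic_tol relative tolerance for calling a ratio harmonic
#'   (default 0.02)
#' @return object of class `beat`: `period` (hours; `Inf` when locked at
#'   equal periods), `locked` (logical), `harmonic_ratio` (integer ratio
#'   when locked, else `NA`)
#' @export
beat_period <- function(period_a, period_b, harmonic_tol = 0.02) {
  if (period_a <= 0 || period_b <= 0)
    stop("beat_period: periods must be positive")
  dfreq <- abs(1 / period_a - 1 / period_b)
  r <- max(period_a, period_b) / min(period_a, period_b)
  rint <- round(r)
  harmonic <- rint >= 1 && abs(r - rint) <= harmonic_tol * rint
  period <- if (dfreq < .Machine$double.eps) Inf else 1 / dfreq
  structure(list(period = period, locked = harmonic,
                 harmonic_ratio = if (harmonic) as.integer(rint) else NA_integer_),
            class = "beat")
}

#' @export
print.beat <- function(x, ...) {
  cat(sprintf("<beat> period %.2f h%s\n", x$period,
              if (x$locked) sprintf(" [locked, %d:1]", x$harmonic_ratio) else ""))
  invisible(x)
}

#' Dominant period of the daily-activity envelope
#'
#' Sums the record into non-overlapping 24-h daily totals -- the
#' daily-activity envelope whose slow variation reflects the in-and-out of
#' phase beating of the two locomotor components -- and returns the period
#' of the highest Lomb-Scargle peak of that daily series within
#' `period_range`.
#'
#' Because the envelope is sampled once per day, an envelope line at
#' frequency `f` is indistinguishable from its daily alias at
#' `1/24 - f` cycles/hour: both produce identical values on the daily grid.
#' The returned object therefore carries the alias partner alongside the
#' peak period; a measured envelope should be compared against a predicted
#' beat period via whichever of the pair is closer in frequency.
#'
#' @param record an [activity_record()]
#' @param period_range envelope period search range in hours (default
#'   `c(30, 150)`)
#' @return object of class `envelope_peak`: `period` (h, the grid peak),
#'   `alias_period` (h, its daily-sampling alias, `NA` if the alias
#'   frequency is non-positive), `sampling_hours` (24)
#' @export
envelope_period <- function(record, period_range = c(30, 150)) {
  stopifnot(inherits(record, "activity_record"))
  bpd <- as.integer(round(24 * 60 / record$bin_minutes))
  x <- ifelse(record$gap_mask, 0, record$counts)
  nd <- length(x) %/% bpd
  if (nd < 8L) stop("envelope_period: need at least 8 full days")
  env <- colSums(matrix(x[1:(nd * bpd)], nrow = bpd))
  env_rec <- activity_record(env, bin_minutes = 24 * 60, channel = "wheel")
  pg <- suppressWarnings(lomb_scargle(env_rec, period_range = period_range,
                                      oversample = 10))
  pk <- highest_peak(pg, period_range)
  if (is.na(pk)) pk <- pg$periods[which.max(pg$power)]
  f_alias <- 1 / 24 - 1 / pk
  structure(list(period = pk,
                 alias_period = if (f_alias > 0) 1 / f_alias else NA_real_,
                 sampling_hours = 24),
            class = "envelope_peak")
}

#' @export
print.envelope_peak <- function(x, ...) {
  cat(sprintf("<envelope_peak> %.1f h (daily alias %.1f h)\n",
              x$period, x$alias_period))
  invisible(x)
}
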