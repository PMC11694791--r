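#' Score sleep from a 1-min PIR record
#'
#' Immobility-defined sleep scoring: any 1-min bin with a count of exactly
#' zero is scored as sleep (1), any bin with activity as wake (0). The rule
#' has been validated against EEG-defined sleep in mice. Masked bins stay
#' masked.
#'
#' @param pir an [activity_record()] with `channel = "pir"` and 1-min bins
#'   (rebin first if needed)
#' @return object of class `sleep_series`: `minutes` (0/1/NA per minute),
#'   `gap_mask`, `bin_minutes`, `start_time`
#' @export
pir_to_sleep <- function(pir) {
  stopifnot(inherits(pir, "activity_record"))
  if (pir$channel != "pir")
    stop("pir_to_sleep: record channel must be 'pir'")
  if (abs(pir$bin_minutes - 1) > 1e-9)
    stop("pir_to_sleep: record must be at 1-min bins (rebin first)")
  sc <- ifelse(pir$gap_mask, NA_real_, as.numeric(pir$counts == 0))
  structure(list(minutes = sc, gap_mask = pir$gap_mask, bin_minutes = 1,
                 start_time = pir$start_time),
            class = "sleep_series")
}

#' @export
print.sleep_series <- function(x, ...) {
  ok <- !x$gap_mask
  cat(sprintf("<sleep_series> %d min (%.1f days), sleep fraction %.2f, %d masked\n",
              length(x$minutes), length(x$minutes) / 1440,
              mean(x$minutes[ok]), sum(!ok)))
  invisible(x)
}

#' Select the strongest 48-h-cycling window of a PIR record
#'
#' Slides a window of `span_days` across the record and selects the one
#' maximizing the ratio of infradian (default 44-52 h) to circadian (default
#' 22-26 h) scale-averaged wavelet power, the spectral guide used to pick
#' 4-day spans of 48-h rhythmicity for sleep analysis. Ties break to the
#' earliest window. If even the best window has ratio below 1 the window is
#' returned with a low-confidence flag.
#'
#' The record is re-binned (default 15-min bins) before the wavelet
#' transform; the window start is aligned to those coarse bins.
#'
#' @param pir an [activity_record()]
#' @param span_days window length in days (default 4)
#' @param bands list with `circadian` and `infradian` period bounds (hours)
#' @param rebin_minutes coarse bin width for the transform (default 15; must
#'   be a multiple of the record bin width)
#' @return a [time_window()] with attributes `ratio` and `low_confidence`
#' @export
select_cycling_window <- function(pir, span_days = 4,
                                  bands = list(circadian = c(22, 26),
                                               infradian = c(44, 52)),
                                  rebin_minutes = 15) {
  stopifnot(inherits(pir, "activity_record"))
  if (span_hours(pir) < span_days * 24)
    stop("select_cycling_window: record shorter than the requested span")
  coarse <- rebin(pir, rebin_minutes)
  pmax_needed <- max(bands$infradian) * 1.1
  scal <- cwt_scalogram(coarse,
                        period_range = c(min(bands$circadian) * 0.9, pmax_needed))
  bc <- scale_averaged_power(scal, bands$circadian)$value
  bi <- scale_averaged_power(scal, bands$infradian)$value
  nb <- length(bc)
  wlen <- as.integer(round(span_days * 24 * 60 / rebin_minutes))
  if (wlen > nb) stop("select_cycling_window: record shorter than span")
  csc <- cumsum(c(0, bc)); csi <- cumsum(c(0, bi))
  starts <- 1:(nb - wlen + 1L)
  mc <- (csc[starts + wlen] - csc[starts]) / wlen
  mi <- (csi[starts + wlen] - csi[starts]) / wlen
  ratio <- mi / mc
  best <- which.max(ratio)           # earliest on exact ties
  start_h <- (best - 1L) * rebin_minutes / 60
  win <- time_window(start_h, span_days * 24)
  attr(win, "ratio") <- ratio[best]
  attr(win, "low_confidence") <- ratio[best] < 1
  win
}

#' Locate infradian activity onset
#'
#' Finds the first 30-min run whose mean activity exceeds the window's
#' median (50th percentile) after at least `quiet_hours` below it -- a
#' reproducible anchor for day boundaries under constant darkness, where
#' zeitgeber time is undefined.
#'
#' @param record an [activity_record()]
#' @param window optional [time_window()] restricting the search
#' @param run_minutes onset run length (default 30)
#' @param quiet_hours required preceding quiescence (default 6)
#' @return onset time in hours from record start, or `NA` if none found
#' @export
activity_onset <- function(record, window = NULL, run_minutes = 30,
                           quiet_hours = 6) {
  stopifnot(inherits(record, "activity_record"))
  rec <- if (is.null(window)) record else extract_window(record, window)
  off <- if (is.null(window)) 0 else window$start_offset
  x <- ifelse(rec$gap_mask, NA, rec$counts)
  thr <- stats::median(x, na.rm = TRUE)
  k <- max(1L, as.integer(round(run_minutes / rec$bin_minutes)))
  run_mean <- as.numeric(stats::filter(ifelse(is.na(x), 0, x), rep(1 / k, k),
                                       sides = 1))
  hi <- !is.na(run_mean) & run_mean > thr
  qbins <- as.integer(round(quiet_hours * 60 / rec$bin_minutes))
  for (i in which(hi)) {
    lo0 <- i - k - qbins + 1L
    if (lo0 < 1L) next
    if (!any(hi[lo0:(i - k)])) {
      return(off + (i - k) * rec$bin_minutes / 60)
    }
  }
  NA_real_
}

#' Label 24-h days as active or inactive within a cycling window
#'
#' Folds the window at `cycle_period`, partitions it into consecutive 24-h
#' days from the window start, and labels a day "active" iff its total sleep
#' lies below the window median. For a 48-h cycle this is equivalent to
#' alternating labels anchored to the lower-sleep phase, and alternation is
#' enforced: the two 24-h phases of the fold are compared by mean sleep and
#' the lower-sleep phase is labeled active throughout.
#'
#' @param sleep a `sleep_series`
#' @param window a [time_window()] spanning a whole, even number of days for
#'   `cycle_period = 48`
#' @param cycle_period infradian cycle length in hours (default 48)
#' @return object of class `day_labeling`: `day_edges` (hours), `labels`
#'   (`"active"`/`"inactive"`), `cycle_period`, `daily_sleep_minutes`
#' @export
label_days <- function(sleep, window, cycle_period = 48) {
  stopifnot(inherits(sleep, "sleep_series"), inherits(window, "time_window"))
  n_days <- window$duration / 24
  if (abs(n_days - round(n_days)) > 1e-9)
    stop("label_days: window must span a whole number of days")
  n_days <- as.integer(round(n_days))
  if (abs(cycle_period - 48) < 1e-9 && n_days %% 2L != 0L)
    stop("label_days: window must span an even number of days for a 48-h cycle")
  i0 <- as.integer(round(window$start_offset * 60)) + 1L
  i1 <- i0 + as.integer(round(window$duration * 60)) - 1L
  if (i0 < 1L || i1 > length(sleep$minutes))
    stop("label_days: window outside sleep series")
  day_of <- rep(seq_len(n_days), each = 1440L)
  sl <- sleep$minutes[i0:i1]
  daily <- vapply(seq_len(n_days),
                  function(d) sum(sl[day_of == d], na.rm = TRUE), numeric(1))
  if (length(unique(daily)) == 1L)
    stop("label_days: all daily sleep totals equal; labeling is ambiguous")
  if (abs(cycle_period - 48) < 1e-9) {
    phase_a <- mean(daily[seq(1, n_days, by = 2)])
    phase_b <- mean(daily[seq(2, n_days, by = 2)])
    if (phase_a == phase_b)
      stop("label_days: phases have equal mean sleep; labeling is ambiguous")
    active_phase <- if (phase_a < phase_b) 1L else 0L
    labels <- ifelse(seq_len(n_days) %% 2L == active_phase, "active", "inactive")
  } else {
    med <- stats::median(daily)
    labels <- ifelse(daily < med, "active", "inactive")
  }
  structure(list(day_edges = window$start_offset + 24 * (0:n_days),
                 labels = labels, cycle_period = cycle_period,
                 daily_sleep_minutes = daily),
            class = "day_labeling")
}

#' @export
print.day_labeling <- function(x, ...) {
  cat(sprintf("<day_labeling> %d days (cycle %g h): %s\n",
              length(x$labels), x$cycle_period,
              paste(substr(x$labels, 1, 1), collapse = "")))
  invisible(x)
}

#' Daily sleep fractions by active/inactive label
#'
#' Per-day sleep fraction (sleep minutes over unmasked minutes), the mean
#' fraction per label, and total sleep per full infradian cycle (consecutive
#' day pairs for a 48-h cycle), as used for pre/post cycling contrasts.
#'
#' @param sleep a `sleep_series`
#' @param labeling a `day_labeling` covering a window of the series
#' @return list with `per_day` (data.frame: day, label, sleep_minutes,
#'   unmasked_minutes, fraction), `mean_fraction` (named numeric by label),
#'   `per_cycle_sleep_minutes`
#' @export
daily_sleep_fraction <- function(sleep, labeling) {
  stopifnot(inherits(sleep, "sleep_series"), inherits(labeling, "day_labeling"))
  n_days <- length(labeling$labels)
  i0 <- as.integer(round(labeling$day_edges[1] * 60)) + 1L
  per_day <- do.call(rbind, lapply(seq_len(n_days), function(d) {
    idx <- (i0 + (d - 1L) * 1440L):(i0 + d * 1440L - 1L)
    sl <- sleep$minutes[idx]
    ok <- sum(!is.na(sl))
    data.frame(day = d, label = labeling$labels[d],
               sleep_minutes = sum(sl, na.rm = TRUE),
               unmasked_minutes = ok,
               fraction = if (ok > 0) sum(sl, na.rm = TRUE) / ok else NA_real_)
  }))
  mean_fraction <- tapply(per_day$fraction, per_day$label, mean)
  days_per_cycle <- max(1L, as.integer(round(labeling$cycle_period / 24)))
  n_cyc <- n_days %/% days_per_cycle
  per_cycle <- vapply(seq_len(n_cyc), function(cy) {
    dd <- ((cy - 1L) * days_per_cycle + 1L):(cy * days_per_cycle)
    sum(per_day$sleep_minutes[dd])
  }, numeric(1))
  list(per_day = per_day,
       mean_fraction = c(mean_fraction),
       per_cycle_sleep_minutes = per_cycle)
}
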