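#' Locomotor activity record
#'
#' Container for an evenly binned, possibly gapped locomotor count series,
#' either running-wheel revolutions (default 5-min bins) or passive-infrared
#' (PIR) locomotion counts (default 1-min bins). Missing or invalid intervals
#' are represented by a gap mask, never by zeros: a zero count is meaningful
#' (it is the basis of immobility-defined sleep scoring), whereas a masked bin
#' is ignored by every downstream computation.
#'
#' Bins are left-closed, right-open intervals; a bin's time is its left edge,
#' expressed in hours from the start of the record. An absolute start time may
#' be attached for display but plays no computational role.
#'
#' @param counts numeric vector of non-negative counts per bin. Non-finite
#'   entries are masked.
#' @param bin_minutes bin width in minutes (> 0). Conventional defaults are
#'   5 for wheel records and 1 for PIR records.
#' @param channel `"wheel"` or `"pir"`.
#' @param gap_mask logical vector, `TRUE` marking missing/invalid bins.
#'   Defaults to all-`FALSE`; non-finite counts are always masked.
#' @param start_time optional absolute start timestamp (POSIXct or string),
#'   retained for display only.
#' @return an object of class `activity_record` with elements `counts`
#'   (masked bins stored as `NA`), `gap_mask`, `bin_minutes`, `channel`,
#'   `start_time`.
#' @export
activity_record <- function(counts, bin_minutes = 5,
                            channel = c("wheel", "pir"),
                            gap_mask = NULL, start_time = NULL) {
  channel <- match.arg(channel)
  counts <- as.numeric(counts)
  if (length(counts) == 0L) stop("activity_record: empty count series")
  if (!is.numeric(bin_minutes) || length(bin_minutes) != 1L || bin_minutes <= 0)
    stop("activity_record: bin_minutes must be a single positive number")
  if (is.null(gap_mask)) gap_mask <- rep(FALSE, length(counts))
  gap_mask <- as.logical(gap_mask)
  if (length(gap_mask) != length(counts))
    stop("activity_record: counts and gap_mask lengths differ")
  gap_mask <- gap_mask | !is.finite(counts)
  if (any(counts[!gap_mask] < 0))
    stop("activity_record: negative counts in unmasked bins")
  counts[gap_mask] <- NA_real_
  structure(
    list(counts = counts, gap_mask = gap_mask, bin_minutes = bin_minutes,
         channel = channel, start_time = start_time),
    class = "activity_record")
}

#' @export
print.activity_record <- function(x, ...) {
  cat(sprintf("<activity_record> %s, %d bins @ %g min (%.2f days), %d masked\n",
              x$channel, length(x$counts), x$bin_minutes,
              length(x$counts) * x$bin_minutes / 1440, sum(x$gap_mask)))
  invisible(x)
}

#' Bin left-edge times in hours from record start
#' @param record an `activity_record`
#' @return numeric vector of hours
#' @export
time_hours <- function(record) {
  (seq_along(record$counts) - 1) * record$bin_minutes / 60
}

#' Record span in hours
#' @param record an `activity_record`
#' @return total covered duration in hours
#' @export
span_hours <- function(record) {
  length(record$counts) * record$bin_minutes / 60
}

#' Analysis time window
#'
#' A half-open interval `[start_offset, start_offset + duration)` in hours
#' from the start of a record.
#'
#' @param start_offset hours from record start
#' @param duration window length in hours (> 0)
#' @return object of class `time_window`
#' @export
time_window <- function(start_offset, duration) {
  if (!is.finite(start_offset) || !is.finite(duration) || duration <= 0)
    stop("time_window: duration must be positive and offsets finite")
  structure(list(start_offset = start_offset, duration = duration),
            class = "time_window")
}

#' @export
print.time_window <- function(x, ...) {
  cat(sprintf("<time_window> [%g, %g) h (%.2f days)\n", x$start_offset,
              x$start_offset + x$duration, x$duration / 24))
  invisible(x)
}

#' Extract a sub-record for a time window
#'
#' Bins whose left edge falls inside the window are retained; bin width,
#' mask and channel are preserved.
#'
#' @param record an `activity_record`
#' @param window a `time_window` intersecting the record span
#' @return an `activity_record` covering the window
#' @export
extract_window <- function(record, window) {
  stopifnot(inherits(record, "activity_record"), inherits(window, "time_window"))
  t <- time_hours(record)
  lo <- window$start_offset
  hi <- window$start_offset + window$duration
  if (lo < -1e-9 || lo >= span_hours(record) || hi > span_hours(record) + 1e-9)
    stop("extract_window: window outside record span")
  keep <- t >= lo - 1e-9 & t < hi - 1e-9
  if (!any(keep)) stop("extract_window: window contains no bins")
  st <- record$start_time
  if (inherits(st, "POSIXct")) st <- st + lo * 3600
  out <- record
  out$counts <- record$counts[keep]
  out$gap_mask <- record$gap_mask[keep]
  out$start_time <- st
  out
}

#' Re-bin an activity record to a coarser bin width
#'
#' Counts are summed within each new bin; a new bin is masked iff any
#' constituent bin is masked (only unmasked constituents contribute to the
#' stored sum). If the record length is not a multiple of the rebin factor,
#' the trailing bins are summed into a final short bin so that total unmasked
#' counts are conserved.
#'
#' @param record an `activity_record`
#' @param new_width target bin width in minutes; must be an integer multiple
#'   of `record$bin_minutes`.
#' @return an `activity_record` at the new bin width
#' @export
rebin <- function(record, new_width) {
  stopifnot(inherits(record, "activity_record"))
  fac <- new_width / record$bin_minutes
  if (abs(fac - round(fac)) > 1e-9 || fac < 1)
    stop("rebin: new_width must be an integer multiple of the current bin width")
  fac <- as.integer(round(fac))
  if (fac == 1L) return(record)
  grp <- (seq_along(record$counts) - 1L) %/% fac
  counts <- as.numeric(tapply(ifelse(record$gap_mask, 0, record$counts), grp, sum))
  mask <- as.logical(tapply(record$gap_mask, grp, any))
  counts[mask & as.numeric(tapply(record$gap_mask, grp, all))] <- NA_real_
  activity_record(counts, bin_minutes = new_width, channel = record$channel,
                  gap_mask = mask, start_time = record$start_time)
}

#' Total counts over unmasked bins
#' @param record an `activity_record`
#' @return scalar sum
#' @export
total_activity <- function(record) {
  sum(record$counts[!record$gap_mask])
}

#' Mean counts per 24 h over unmasked bins
#'
#' Used for total-activity comparisons across windows of unequal length.
#' @param record an `activity_record`
#' @return counts per day
#' @export
daily_activity <- function(record) {
  n_ok <- sum(!record$gap_mask)
  if (n_ok == 0L) return(NA_real_)
  total_activity(record) / (n_ok * record$bin_minutes / 1440)
}
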