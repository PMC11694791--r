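#' Read a locomotor count series from tabular text
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`"timestamp"`}{a delimited file with columns `timestamp,count`;
#'     the timestamp is either elapsed minutes (numeric) or an ISO-8601
#'     date-time. Bin width is inferred from the timestamp spacing, which
#'     must be uniform to within 1\% jitter.}
#'   \item{`"counts"`}{a headerless single count column; bin width, channel
#'     and start time come from a YAML sidecar `<path>.yml` (keys
#'     `bin_minutes`, `channel`, `start`) or from the `bin_minutes`/`channel`
#'     arguments.}
#' }
#' Blank, unparseable, or negative count fields become masked bins.
#'
#' @param path file path
#' @param dialect `"auto"` (header sniffing), `"timestamp"`, or `"counts"`
#' @param bin_minutes,channel fallbacks for the `"counts"` dialect
#' @return an [activity_record()]
#' @export
load_activity <- function(path, dialect = c("auto", "timestamp", "counts"),
                          bin_minutes = NULL, channel = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("load_activity: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) | grepl(",", lines)]
  if (length(lines) == 0L) stop("load_activity: empty file: ", path)
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  if (dialect == "auto") {
    dialect <- if (grepl(sep, lines[[1]], fixed = TRUE)) "timestamp" else "counts"
  }

  if (dialect == "timestamp") {
    header <- grepl("timestamp", lines[[1]], ignore.case = TRUE)
    body <- if (header) lines[-1] else lines
    parts <- strsplit(body, sep, fixed = TRUE)
    ts_raw <- trimws(vapply(parts, function(p) if (length(p) >= 1) p[[1]] else "", ""))
    ct_raw <- trimws(vapply(parts, function(p) if (length(p) >= 2) p[[2]] else "", ""))
    ts_num <- suppressWarnings(as.numeric(ts_raw))
    start_time <- NULL
    if (anyNA(ts_num)) {
      ts_posix <- as.POSIXct(ts_raw, tz = "UTC",
                             tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
      if (anyNA(ts_posix)) stop("load_activity: unparseable timestamps")
      start_time <- ts_posix[[1]]
      ts_num <- as.numeric(difftime(ts_posix, ts_posix[[1]], units = "mins"))
    }
    d <- diff(ts_num)
    if (length(d) == 0L) stop("load_activity: need at least 2 rows")
    med <- stats::median(d)
    if (med <= 0 || any(abs(d - med) > 0.01 * med))
      stop("load_activity: inconsistent sampling interval (> 1% jitter)")
    counts <- suppressWarnings(as.numeric(ct_raw))
    mask <- !is.finite(counts) | counts < 0
    counts[mask] <- NA_real_
    if (is.null(channel)) channel <- if (abs(med - 1) < 1e-6) "pir" else "wheel"
    return(activity_record(counts, bin_minutes = med, channel = channel,
                           gap_mask = mask, start_time = start_time))
  }

  # headerless counts column, metadata from sidecar or arguments
  side <- paste0(path, ".yml")
  meta <- if (file.exists(side)) yaml::read_yaml(side) else list()
  if (is.null(bin_minutes)) bin_minutes <- meta$bin_minutes
  if (is.null(channel)) channel <- meta$channel
  if (is.null(bin_minutes) || is.null(channel))
    stop("load_activity: counts dialect needs bin_minutes and channel ",
         "(argument or YAML sidecar)")
  counts <- suppressWarnings(as.numeric(trimws(lines)))
  mask <- !is.finite(counts) | counts < 0
  counts[mask] <- NA_real_
  activity_record(counts, bin_minutes = bin_minutes, channel = channel,
                  gap_mask = mask, start_time = meta$start)
}

#' Write a locomotor count series as delimited text
#'
#' Writes the `timestamp,count` dialect with elapsed minutes as timestamps.
#' Gap bins are serialized as empty count fields. Counts are printed with
#' `%.17g` so that a load/write round trip reproduces the numeric content
#' exactly.
#'
#' @param record an [activity_record()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_activity <- function(record, path) {
  stopifnot(inherits(record, "activity_record"))
  ts <- (seq_along(record$counts) - 1) * record$bin_minutes
  ct <- ifelse(record$gap_mask, "",
               sprintf("%.17g", ifelse(record$gap_mask, 0, record$counts)))
  writeLines(c("timestamp,count", paste(sprintf("%.17g", ts), ct, sep = ",")),
             path)
  invisible(path)
}
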