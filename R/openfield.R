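#' Open-field path trace
#'
#' A calibrated x-y trajectory from open-field video tracking, sampled at a
#' uniform frame rate (30 frames/s by convention) within a square arena
#' (50 x 50 cm by convention). Positions may be supplied in pixels together
#' with a px-to-cm calibration factor.
#'
#' @param x,y positions; multiplied by `calibration` to obtain cm
#' @param fps frame rate (default 30)
#' @param arena_cm arena side length in cm (default 50)
#' @param calibration px-to-cm factor (default 1, i.e. already in cm)
#' @param tol out-of-arena tolerance in cm (default 0.5)
#' @return object of class `path_trace`: `xy` (n x 2 matrix, cm),
#'   `frame_times` (s), `fps`, `arena_cm`
#' @export
path_trace <- function(x, y, fps = 30, arena_cm = 50, calibration = 1,
                       tol = 0.5) {
  if (length(x) != length(y)) stop("path_trace: x and y lengths differ")
  if (length(x) < 2L) stop("path_trace: need at least 2 frames")
  xy <- cbind(x = as.numeric(x) * calibration, y = as.numeric(y) * calibration)
  if (any(!is.finite(xy))) stop("path_trace: non-finite positions")
  if (any(xy < -tol) || any(xy > arena_cm + tol))
    stop("path_trace: positions outside arena bounds")
  structure(list(xy = xy, frame_times = (seq_len(nrow(xy)) - 1) / fps,
                 fps = fps, arena_cm = arena_cm),
            class = "path_trace")
}

#' Read an ezTrack-style location CSV
#'
#' Expects columns `frame`, `x`, `y` (case-insensitive; extra columns are
#' ignored). Single missing frames are bridged by linear interpolation; runs
#' of more than 5 consecutive missing frames invalidate the trace.
#'
#' @param path CSV path
#' @param calibration px-to-cm factor
#' @param fps,arena_cm see [path_trace()]
#' @return a `path_trace`
#' @export
load_path_trace <- function(path, calibration = 1, fps = 30, arena_cm = 50) {
  d <- utils::read.csv(path, check.names = FALSE)
  names(d) <- tolower(names(d))
  if (!all(c("x", "y") %in% names(d)))
    stop("load_path_trace: need x and y columns")
  x <- suppressWarnings(as.numeric(d$x))
  y <- suppressWarnings(as.numeric(d$y))
  bad <- !is.finite(x) | !is.finite(y)
  if (any(bad)) {
    r <- rle(bad)
    if (any(r$lengths[r$values] > 5L))
      stop("load_path_trace: more than 5 consecutive missing frames")
    idx <- seq_along(x)
    x <- stats::approx(idx[!bad], x[!bad], xout = idx, rule = 2)$y
    y <- stats::approx(idx[!bad], y[!bad], xout = idx, rule = 2)$y
  }
  path_trace(x, y, fps = fps, arena_cm = arena_cm, calibration = calibration)
}

#' Total distance traveled
#'
#' Sum of Euclidean frame-to-frame displacements, in cm.
#'
#' @param trace a `path_trace`
#' @return distance in cm
#' @export
total_distance <- function(trace) {
  stopifnot(inherits(trace, "path_trace"))
  sum(sqrt(rowSums(diff(trace$xy)^2)))
}

#' Segment a path into 2-cm microevents
#'
#' Walks the trace and retains the first frame at or after each successive
#' crossing of `segment_cm` of cumulative path length since the previous
#' retained frame, starting with frame 1. The cumulative length between
#' consecutive microevents therefore always lies in
#' `[segment_cm, segment_cm + max frame step)`. The trailing partial
#' segment is discarded. These retained frames are the "microevents" of the
#' fractal path analysis.
#'
#' @param trace a `path_trace`
#' @param segment_cm segment length in cm (default 2)
#' @param min_events minimum number of microevents required (default 9,
#'   enough to evaluate resolution k = 8)
#' @return integer vector of frame indices (1-based)
#' @export
segment_microevents <- function(trace, segment_cm = 2, min_events = 9L) {
  stopifnot(inherits(trace, "path_trace"))
  step <- sqrt(rowSums(diff(trace$xy)^2))
  cumlen <- c(0, cumsum(step))
  total <- cumlen[length(cumlen)]
  if (total < 2 * segment_cm)
    stop("segment_microevents: total path length below 2 segments")
  idx <- 1L
  repeat {
    target <- cumlen[idx[length(idx)]] + segment_cm
    if (target > total) break
    nxt <- findInterval(target, cumlen, left.open = TRUE) + 1L
    idx <- c(idx, nxt)
  }
  if (length(idx) < min_events)
    stop("segment_microevents: fewer than ", min_events, " microevents")
  idx
}

#' Path length at resolution k
#'
#' Sum of straight-line distances between microevents taken `k` apart:
#' first to (k+1)-st, (k+1)-st to (2k+1)-st, and so forth; microevents
#' beyond the last full stride are dropped.
#'
#' @param xy n x 2 matrix of microevent positions (cm)
#' @param k stride (resolution)
#' @return L_k in cm
#' @export
path_length_at_resolution <- function(xy, k) {
  xy <- as.matrix(xy)
  if (nrow(xy) < k + 1L)
    stop("path_length_at_resolution: need at least k + 1 microevents")
  idx <- seq(1L, nrow(xy), by = k)
  sum(sqrt(rowSums(diff(xy[idx, , drop = FALSE])^2)))
}

#' Spatial d: fractal straightness of an open-field path
#'
#' Multi-resolution path-length scaling: the trace is reduced to 2-cm
#' microevents, the path length `L_k` is measured at strides
#' `k = 1, 2, 4, 8`, and a least-squares line is fitted to `log2(L_k)`
#' versus `log2(k)`. Under the default `neg_slope` convention spatial d is
#' the negative of that slope (0 for a perfectly straight path, larger for
#' more tortuous paths); the `one_minus_slope` convention (`1 - slope`,
#' the classical fractal-dimension scaling in [1, 2]) is also available.
#' Straighter paths give lower spatial d.
#'
#' @param trace a `path_trace`
#' @param segment_cm microevent segment length (default 2)
#' @param ks strides (default `c(1, 2, 4, 8)`)
#' @param convention `"neg_slope"` (default) or `"one_minus_slope"`
#' @return object of class `spatial_d_fit`: `microevent_indices`, `L_k`
#'   (named by k), `slope`, `spatial_d`, `convention`
#' @export
spatial_d <- function(trace, segment_cm = 2, ks = c(1, 2, 4, 8),
                      convention = c("neg_slope", "one_minus_slope")) {
  convention <- match.arg(convention)
  me <- segment_microevents(trace, segment_cm = segment_cm,
                            min_events = max(ks) + 1L)
  # trim so every resolution ends on the same microevent: without a common
  # endpoint the dropped remainder differs across k and biases the slope
  # (a perfectly straight path would not fit slope 0)
  kmax <- max(ks)
  n_use <- kmax * ((length(me) - 1L) %/% kmax) + 1L
  me <- me[seq_len(n_use)]
  xy <- trace$xy[me, , drop = FALSE]
  lk <- vapply(ks, function(k) path_length_at_resolution(xy, k), numeric(1))
  names(lk) <- paste0("L", ks)
  if (any(lk <= 0)) stop("spatial_d: zero path length at some resolution")
  fit <- stats::lm.fit(cbind(1, log2(ks)), log2(lk))
  slope <- unname(fit$coefficients[2])
  d <- if (convention == "neg_slope") -slope else 1 - slope
  structure(list(microevent_indices = me, L_k = lk, slope = slope,
                 spatial_d = d, convention = convention),
            class = "spatial_d_fit")
}

#' @export
print.spatial_d_fit <- function(x, ...) {
  cat(sprintf("<spatial_d_fit> %s: d = %.3f (slope %.3f; %s)\n",
              paste(sprintf("%s=%.1f", names(x$L_k), x$L_k), collapse = " "),
              x$spatial_d, x$slope, x$convention))
  invisible(x)
}
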