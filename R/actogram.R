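#' Actogram matrix
#'
#' Folds a count series at a row period into the classical raster display:
#' one row per cycle, optionally double-plotted (each row shows its own
#' cycle followed by the next). The trailing partial row is padded with
#' masked cells. Folding at a non-24-h row period gives the "modulo"
#' actogram used to display robust infradian rhythmicity.
#'
#' @param record an [activity_record()]
#' @param row_period row length in hours, within `[16, 96]`
#' @param n_plot 1 (single plot) or 2 (double plot)
#' @return object of class `actogram_matrix`: `matrix` (rows x bins,
#'   masked/padded cells `NA`), `mask`, `row_period`, `n_plot`,
#'   `bin_minutes`
#' @export
actogram_matrix <- function(record, row_period = 24, n_plot = 1) {
  stopifnot(inherits(record, "activity_record"))
  if (row_period < 16 || row_period > 96)
    stop("actogram_matrix: row_period must lie in [16, 96] hours")
  if (!n_plot %in% c(1, 2)) stop("actogram_matrix: n_plot must be 1 or 2")
  bpr_exact <- row_period * 60 / record$bin_minutes
  bpr <- as.integer(round(bpr_exact))
  if (abs(bpr_exact - bpr) > 1e-9)
    warning(sprintf(
      "actogram_matrix: row_period rounded to %d bins (residual %.3g min/row)",
      bpr, (bpr_exact - bpr) * record$bin_minutes))
  n <- length(record$counts)
  nrow_ <- as.integer(ceiling(n / bpr))
  padded <- c(record$counts, rep(NA_real_, nrow_ * bpr - n))
  pmask <- c(record$gap_mask, rep(TRUE, nrow_ * bpr - n))
  m <- matrix(padded, nrow = nrow_, ncol = bpr, byrow = TRUE)
  mk <- matrix(pmask, nrow = nrow_, ncol = bpr, byrow = TRUE)
  if (n_plot == 2) {
    nxt <- rbind(m[-1, , drop = FALSE], matrix(NA_real_, 1, bpr))
    nxtm <- rbind(mk[-1, , drop = FALSE], matrix(TRUE, 1, bpr))
    m <- cbind(m, nxt)
    mk <- cbind(mk, nxtm)
  }
  structure(list(matrix = m, mask = mk, row_period = row_period,
                 n_plot = n_plot, bin_minutes = record$bin_minutes),
            class = "actogram_matrix")
}

#' @export
print.actogram_matrix <- function(x, ...) {
  cat(sprintf("<actogram_matrix> %d rows x %d bins, row period %g h%s\n",
              nrow(x$matrix), ncol(x$matrix), x$row_period,
              if (x$n_plot == 2) " (double plot)" else ""))
  invisible(x)
}

#' Pipeline configuration
#'
#' Validated bundle of the analysis parameters shared by [run_pipeline()].
#'
#' @param period_range Lomb-Scargle scan range in hours
#' @param band_edges \%ASD band edges in hours
#' @param alpha significance level
#' @param oversample frequency-grid oversampling
#' @param wavelet list of CWT options (`family`, `gamma`, `beta`,
#'   `omega0`, `period_range`)
#' @param do_wavelet compute scalogram + ridge per record (default `TRUE`)
#' @param spatial_convention spatial-d convention
#' @param out_dir output directory
#' @param seed seed recorded in the run log (the pipeline itself is
#'   deterministic)
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(period_range = c(20, 96),
                            band_edges = c(20, 27, 96),
                            alpha = 0.001, oversample = 10,
                            wavelet = list(family = "morse", gamma = 3,
                                           beta = 20, omega0 = 6,
                                           period_range = c(16, 96)),
                            do_wavelet = TRUE,
                            spatial_convention = "neg_slope",
                            out_dir = tempfile("infrakit_run_"),
                            seed = 1L) {
  stopifnot(length(period_range) == 2L, min(period_range) > 0,
            length(band_edges) >= 2L, alpha > 0, alpha < 1, oversample >= 1)
  if (!spatial_convention %in% c("neg_slope", "one_minus_slope"))
    stop("pipeline_config: unknown spatial convention")
  structure(list(period_range = period_range, band_edges = sort(band_edges),
                 alpha = alpha, oversample = oversample, wavelet = wavelet,
                 do_wavelet = do_wavelet,
                 spatial_convention = spatial_convention,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

fmt_num <- function(x, digits = 3) sprintf(paste0("%.", digits, "f"), x)

write_csv_plain <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
}

#' Run the periodogram quantification pipeline over a batch of records
#'
#' For each input record: Lomb-Scargle periodogram with significance
#' threshold, \%ASD band partition, highest significant peak, total and
#' per-day activity, and (optionally) the wavelet ridge. Outputs one CSV
#' per stage and record, a composite normalized-periodogram matrix across
#' records, and a YAML run log holding the package version, the resolved
#' configuration, and the per-record status. A failing stage is logged for
#' that record and does not abort the batch.
#'
#' All period axes are written in hours with 3 decimals; composite matrices
#' are interpolated to a common 500-point grid.
#'
#' @param config a [pipeline_config()]
#' @param inputs a named list of [activity_record()] objects, or a character
#'   vector of file paths readable by [load_activity()]
#' @return (invisibly) list with `summary` (data.frame per record),
#'   `composite`, `out_dir`, `status`
#' @export
run_pipeline <- function(config, inputs) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(inputs)) {
    nms <- tools::file_path_sans_ext(basename(inputs))
    inputs <- stats::setNames(lapply(inputs, load_activity), nms)
  }
  if (is.null(names(inputs)) && length(inputs) > 0)
    names(inputs) <- sprintf("record%02d", seq_along(inputs))
  if (length(inputs) == 0L) {
    warning("run_pipeline: empty input list; writing empty report")
    log <- list(package = "infrakit",
                version = as.character(utils::packageVersion("infrakit")),
                config = unclass(config), records = list())
    yaml::write_yaml(log, file.path(config$out_dir, "run_log.yml"))
    return(invisible(list(summary = NULL, composite = NULL,
                          out_dir = config$out_dir, status = character(0))))
  }

  status <- character(length(inputs))
  names(status) <- names(inputs)
  pgs <- list()
  rows <- list()
  for (nm in names(inputs)) {
    rec <- inputs[[nm]]
    res <- tryCatch({
      pg <- suppressWarnings(lomb_scargle(
        rec, period_range = config$period_range,
        oversample = config$oversample, alpha = config$alpha))
      write_csv_plain(
        data.frame(period_hours = fmt_num(pg$periods),
                   power = pg$power,
                   significant = as.integer(pg$power > pg$sig_level)),
        file.path(config$out_dir, paste0("periodogram_", nm, ".csv")))
      bp <- percent_asd(pg, config$band_edges)
      write_csv_plain(
        data.frame(band = names(bp$asd_percent),
                   asd_percent = bp$asd_percent),
        file.path(config$out_dir, paste0("asd_", nm, ".csv")))
      pk <- highest_peak(pg, config$period_range)
      if (config$do_wavelet) {
        scal <- cwt_scalogram(rec,
                              period_range = config$wavelet$period_range,
                              family = config$wavelet$family,
                              gamma = config$wavelet$gamma,
                              beta = config$wavelet$beta,
                              omega0 = config$wavelet$omega0)
        rg <- extract_ridge(scal)
        write_csv_plain(
          data.frame(time_h = fmt_num(rg$times),
                     period_h = ifelse(rg$valid, fmt_num(rg$peak_period), ""),
                     valid = as.integer(rg$valid)),
          file.path(config$out_dir, paste0("ridge_", nm, ".csv")))
      }
      pgs[[nm]] <- pg
      rows[[nm]] <- data.frame(
        record = nm,
        n_bins = length(rec$counts),
        highest_peak_h = pk,
        asd_first_band_pct = bp$asd_percent[[1]],
        asd_last_band_pct = bp$asd_percent[[length(bp$asd_percent)]],
        total_counts = total_activity(rec),
        counts_per_day = daily_activity(rec))
      "ok"
    }, error = function(e) paste("error:", conditionMessage(e)))
    status[[nm]] <- res
  }

  composite <- NULL
  if (length(pgs) > 0) {
    composite <- composite_periodogram(pgs, n_grid = 500)
    cm <- as.data.frame(composite$matrix)
    names(cm) <- fmt_num(composite$periods)
    cm <- cbind(record = names(pgs), cm)
    write_csv_plain(cm, file.path(config$out_dir, "composite_periodograms.csv"))
  }
  summary_df <- if (length(rows) > 0) do.call(rbind, rows) else NULL
  if (!is.null(summary_df))
    write_csv_plain(summary_df, file.path(config$out_dir, "summary.csv"))

  log <- list(package = "infrakit",
              version = as.character(utils::packageVersion("infrakit")),
              config = list(period_range = config$period_range,
                            band_edges = config$band_edges,
                            alpha = config$alpha,
                            oversample = config$oversample,
                            wavelet = config$wavelet,
                            do_wavelet = config$do_wavelet,
                            spatial_convention = config$spatial_convention,
                            seed = config$seed),
              records = as.list(status))
  yaml::write_yaml(log, file.path(config$out_dir, "run_log.yml"))
  invisible(list(summary = summary_df, composite = composite,
                 out_dir = config$out_dir, status = status))
}

#' Sleep summary export
#'
#' Convenience wrapper writing the per-day sleep summary of a PIR record:
#' day offset, label, sleep minutes and fraction.
#'
#' @param pir a PIR [activity_record()] at 1-min bins
#' @param window a [time_window()] (e.g. from [select_cycling_window()])
#' @param path output CSV path
#' @param cycle_period infradian cycle (default 48 h)
#' @return (invisibly) the [daily_sleep_fraction()] result
#' @export
export_sleep_summary <- function(pir, window, path, cycle_period = 48) {
  sl <- pir_to_sleep(pir)
  lab <- label_days(sl, window, cycle_period)
  dsf <- daily_sleep_fraction(sl, lab)
  out <- dsf$per_day
  out$day_offset_h <- lab$day_edges[out$day]
  write_csv_plain(out[, c("day_offset_h", "label", "sleep_minutes",
                          "unmasked_minutes", "fraction")], path)
  invisible(dsf)
}
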