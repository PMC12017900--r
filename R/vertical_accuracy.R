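# Tide correction of field depths and DEM vertical-error summaries.

#' Tide table
#'
#' Ordered water-height samples for one station, heights in metres relative
#' to the LAT datum (interpreted as the correction term added to an observed
#' depth-below-surface; see the package vignette for the sign convention).
#'
#' @param station_id station identifier.
#' @param time numeric or POSIXct sample times, strictly increasing.
#' @param height_m water heights (m), finite.
#' @return an object of class `tide_table`.
#' @export
tide_table <- function(station_id, time, height_m) {
  time <- as.numeric(time)
  if (is.unsorted(time, strictly = TRUE)) stop("tide times must be strictly increasing")
  if (!all(is.finite(height_m))) stop("tide heights must be finite")
  structure(list(station_id = as.character(station_id),
                 time = time, height_m = as.numeric(height_m)),
            class = "tide_table")
}

tide_at <- function(tt, when) {
  when <- as.numeric(when)
  out <- rep(NA_real_, length(when))
  ok <- when >= tt$time[1] & when <= tt$time[length(tt$time)]
  if (any(ok)) out[ok] <- approx(tt$time, tt$height_m, xout = when[ok])$y
  out
}

#' Standardise observed depths to the LAT datum
#'
#' For each record, the tide height at the observation time is linearly
#' interpolated between bracketing tide samples and the LAT-referenced
#' elevation computed as `lat_depth = -(raw_depth + tide_height)` (negative,
#' metres). Records whose timestamp falls outside their station's tide series
#' are excluded and reported in the `excluded` attribute.
#'
#' @param records data.frame with columns `record_id`, `reef_id`, `x`, `y`,
#'   `raw_depth` (m below surface, positive down), `timestamp` (numeric or
#'   POSIXct).
#' @param tides named list of [tide_table()]s by station id.
#' @param stations named character vector mapping reef_id to station id.
#' @return `records` with a `lat_depth` column appended; excluded record ids
#'   in `attr(, "excluded")`.
#' @export
correct_to_lat <- function(records, tides, stations) {
  need <- c("record_id", "reef_id", "raw_depth", "timestamp")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (any(records$raw_depth < 0)) stop("raw_depth must be >= 0")
  st <- stations[records$reef_id]
  if (anyNA(st)) stop("no tide station mapped for reef(s): ",
                      paste(unique(records$reef_id[is.na(st)]), collapse = ", "))
  h <- rep(NA_real_, nrow(records))
  for (s in unique(st)) {
    tt <- tides[[s]]
    if (is.null(tt)) stop("no tide table for station ", s)
    sel <- st == s
    h[sel] <- tide_at(tt, records$timestamp[sel])
  }
  drop <- is.na(h)
  if (any(drop))
    message(sum(drop), " record(s) outside the tide series span were excluded")
  out <- records[!drop, , drop = FALSE]
  out$lat_depth <- -(out$raw_depth + h[!drop])
  attr(out, "excluded") <- records$record_id[drop]
  out
}

#' DEM vertical error at field records
#'
#' `dh_i = lat_depth_i - DEM(cell containing record i)` (in situ minus
#' modelled, both negative elevations): a negative `dh` means the DEM is
#' shallower than the in-situ measurement. Records on nodata cells or
#' off-grid are excluded and counted in `attr(, "n_excluded")`.
#'
#' @param records data.frame with `x`, `y`, `lat_depth` (from
#'   [correct_to_lat()]).
#' @param dem a [grid_create()] DEM.
#' @return numeric vector of errors (m), names = record ids if present.
#' @export
vertical_error <- function(records, dem) {
  stopifnot(is_grid(dem), all(c("x", "y", "lat_depth") %in% names(records)))
  z <- grid_extract(dem, records$x, records$y)
  ok <- !is.na(z)
  if (!any(ok)) stop("no records fall on valid DEM cells")
  dh <- records$lat_depth[ok] - z[ok]
  if ("record_id" %in% names(records)) names(dh) <- records$record_id[ok]
  attr(dh, "n_excluded") <- sum(!ok)
  dh
}

#' Summarise a vertical-error vector
#'
#' Median and SD of `dh`, `RMSE = sqrt(mean(dh^2))`,
#' `NMAD = 1.4826 * median(|dh - median(dh)|)`, outliers (records with
#' `|dh| > 3 * RMSE`), and Q-Q pairs of the sorted sample against normal
#' quantiles with the sample's mean/SD at plotting positions `(k - 0.5)/n`.
#'
#' @param dh numeric error vector (n >= 2), optionally named by record id.
#' @return an `error_summary` list: `n`, `median_dh`, `sd_dh`, `nmad`,
#'   `rmse`, `outlier_ids`, `qq` (data.frame `theoretical`, `sampled`).
#' @export
summarize_error <- function(dh) {
  dh <- dh[!is.na(dh)]
  n <- length(dh)
  if (n < 2) stop("need at least 2 error values")
  med <- median(dh)
  rmse <- sqrt(mean(dh^2))
  nmad <- 1.4826 * median(abs(dh - med))
  out_idx <- which(abs(dh) > 3 * rmse)
  ids <- if (!is.null(names(dh))) names(dh)[out_idx] else as.character(out_idx)
  qq <- data.frame(
    theoretical = qnorm((seq_len(n) - 0.5) / n, mean = mean(dh), sd = sd(dh)),
    sampled = sort(dh))
  structure(list(n = n, median_dh = med, sd_dh = sd(dh), nmad = nmad,
                 rmse = rmse, outlier_ids = ids, qq = qq),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf(
    "<error_summary> n = %d; median dh = %.3f +/- %.3f m; NMAD = %.3f m; RMSE = %.3f m; %d outlier(s)\n",
    x$n, x$median_dh, x$sd_dh, x$nmad, x$rmse, length(x$outlier_ids)))
  invisible(x)
}

#' Per-level accuracy assessment of a DEM stack
#'
#' Runs [vertical_error()] and [summarize_error()] for every level of a
#' multiscale DEM stack against one set of LAT-corrected records.
#'
#' @param records LAT-corrected records (see [correct_to_lat()]).
#' @param stack a `multiscale_stack`.
#' @return data.frame with one row per DEM level (source, resolution, n,
#'   median_dh, sd_dh, nmad, rmse, n_outliers).
#' @export
accuracy_by_level <- function(records, stack) {
  stopifnot(inherits(stack, "multiscale_stack"))
  rows <- lapply(seq_len(nrow(stack$key)), function(i) {
    dem <- stack$levels[[stack$key$key[i]]]
    s <- summarize_error(vertical_error(records, dem))
    data.frame(source = stack$key$source[i],
               resolution_m = stack$key$resolution_m[i],
               n = s$n, median_dh = s$median_dh, sd_dh = s$sd_dh,
               nmad = s$nmad, rmse = s$rmse,
               n_outliers = length(s$outlier_ids), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
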