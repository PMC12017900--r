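# Occurrence thinning, biased background sampling, predictor extraction.

#' Thin presence records to one per reference-grid pixel
#'
#' Retains exactly one point per occupied pixel of the fine reference grid
#' (15 m by convention): the first point in a stable sort by `record_id`.
#' Points off-grid or on nodata cells are dropped first.
#'
#' @param points data.frame with `record_id`, `x`, `y`, `reef_id`.
#' @param ref_grid the fine reference [grid_create()] grid.
#' @return the retained rows, with `attr(, "n_dropped")` (off-grid) and
#'   `attr(, "n_thinned")` (removed duplicates-per-pixel).
#' @export
thin_occurrences <- function(points, ref_grid) {
  if (!"record_id" %in% names(points) && "point_id" %in% names(points))
    points$record_id <- points$point_id
  stopifnot(is_grid(ref_grid),
            all(c("record_id", "x", "y") %in% names(points)))
  rc <- grid_cell_of(ref_grid, points$x, points$y)
  on <- !is.na(rc$row) & !is.na(ref_grid$values[cbind(rc$row, rc$col)])
  if (!any(on)) stop("no points fall on valid cells of the reference grid")
  pts <- points[on, , drop = FALSE]
  rc <- rc[on, , drop = FALSE]
  ord <- order(as.character(pts$record_id))
  pts <- pts[ord, , drop = FALSE]
  cell <- paste(rc$row[ord], rc$col[ord])
  keep <- !duplicated(cell)
  out <- pts[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!on)
  attr(out, "n_thinned") <- sum(!keep)
  out
}

#' Sample sampling-intensity-biased background points
#'
#' Draws `n` background cells (with replacement; one point at each drawn cell
#' centre) from the union of valid cells across the cropped reef grids, with
#' probability proportional to `eps * max(d) + d`, where `d` is a Gaussian
#' kernel density of all georeferenced survey coordinates (bandwidth
#' `bias_bandwidth_m`). This emulates background biased to areas of high
#' sampling intensity. `bias_bandwidth_m = Inf` gives uniform sampling.
#'
#' @param all_coords data.frame with `x`, `y`: every georeferenced record.
#' @param reef_grids named list (by reef id) of cropped grids, as returned by
#'   [crop_to_reefs()].
#' @param n number of background points (default 10000).
#' @param bias_bandwidth_m Gaussian kernel bandwidth (m, default 500).
#' @param seed RNG seed.
#' @param eps density floor as a fraction of the maximum density (default 0.05).
#' @return data.frame with `point_id`, `x`, `y`, `reef_id`, `role = "background"`.
#' @export
sample_background <- function(all_coords, reef_grids, n = 10000,
                              bias_bandwidth_m = 500, seed = 1, eps = 0.05) {
  stopifnot(n >= 1, length(reef_grids) >= 1)
  cells <- NULL
  for (rid in names(reef_grids)) {
    g <- reef_grids[[rid]]
    idx <- which(!is.na(g$values), arr.ind = TRUE)
    if (nrow(idx) == 0) next
    cells <- rbind(cells, data.frame(
      x = g$x_origin + (idx[, 2] - 0.5) * g$pixel_size,
      y = g$y_origin - (idx[, 1] - 0.5) * g$pixel_size,
      reef_id = rid, stringsAsFactors = FALSE))
  }
  if (is.null(cells) || nrow(cells) == 0) stop("no valid cells in any reef grid")
  if (is.finite(bias_bandwidth_m) && nrow(all_coords) > 0) {
    bw2 <- 2 * bias_bandwidth_m^2
    d <- numeric(nrow(cells))
    for (i in seq_len(nrow(all_coords))) {
      d <- d + exp(-((cells$x - all_coords$x[i])^2 +
                       (cells$y - all_coords$y[i])^2) / bw2)
    }
    w <- eps * max(d) + d
    if (max(d) == 0) w <- rep(1, nrow(cells))
  } else {
    w <- rep(1, nrow(cells))
  }
  set.seed(seed)
  pick <- sample.int(nrow(cells), n, replace = TRUE, prob = w)
  out <- cells[pick, , drop = FALSE]
  out <- data.frame(point_id = paste0("bg", seq_len(n)), out,
                    role = "background", stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Extract predictor values at points
#'
#' Nearest-cell (containing-cell) extraction of the requested layers at each
#' point. Rows with any nodata among the requested keys are dropped and
#' counted in `attr(, "n_dropped")`.
#'
#' @param points data.frame with `point_id`, `x`, `y`, optional `reef_id` and
#'   `label` (1 presence / 0 background).
#' @param stack a `variable_stack` from [derive_all()].
#' @param keys layer keys to extract (default: all layers).
#' @return a `feature_table` data.frame: `point_id`, `reef_id`, `label`, one
#'   column per key.
#' @export
extract_values <- function(points, stack, keys = NULL) {
  stopifnot(inherits(stack, "variable_stack"))
  if (is.null(keys)) keys <- names(stack$layers)
  missing_keys <- setdiff(keys, names(stack$layers))
  if (length(missing_keys) > 0)
    stop("keys not in stack: ", paste(missing_keys, collapse = ", "))
  vals <- sapply(keys, function(k)
    grid_extract(stack$layers[[k]], points$x, points$y))
  vals <- matrix(vals, nrow = nrow(points),
                 dimnames = list(NULL, keys))
  ok <- rowSums(is.na(vals)) == 0
  out <- data.frame(
    point_id = points$point_id,
    reef_id = if ("reef_id" %in% names(points)) points$reef_id else NA_character_,
    label = if ("label" %in% names(points)) points$label else NA_integer_,
    stringsAsFactors = FALSE)[ok, , drop = FALSE]
  out <- cbind(out, as.data.frame(vals[ok, , drop = FALSE]))
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!ok)
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Assemble a model-ready presence/background feature table
#'
#' Convenience wrapper: labels presences 1 and background 0, stacks them and
#' extracts the requested layers.
#'
#' @param presences data.frame with `point_id` (or `record_id`), `x`, `y`,
#'   `reef_id`.
#' @param background data.frame from [sample_background()].
#' @inheritParams extract_values
#' @return a `feature_table` (see [extract_values()]).
#' @export
build_feature_table <- function(presences, background, stack, keys = NULL) {
  if (!"point_id" %in% names(presences) && "record_id" %in% names(presences))
    presences$point_id <- as.character(presences$record_id)
  pres <- data.frame(point_id = presences$point_id, x = presences$x,
                     y = presences$y, reef_id = presences$reef_id,
                     label = 1L, stringsAsFactors = FALSE)
  bg <- data.frame(point_id = background$point_id, x = background$x,
                   y = background$y, reef_id = background$reef_id,
                   label = 0L, stringsAsFactors = FALSE)
  extract_values(rbind(pres, bg), stack, keys)
}
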