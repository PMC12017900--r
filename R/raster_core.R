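# DEM preprocessing, reef cropping and Gaussian-pyramid generalisation.

# half-sample symmetric reflection of indices 1..n
reflect_idx <- function(i, n) {
  i <- ifelse(i < 1, 1 - i, i)
  i <- ifelse(i > n, 2 * n + 1 - i, i)
  # repeat in case of very small n
  while (any(i < 1 | i > n)) {
    i <- ifelse(i < 1, 1 - i, i)
    i <- ifelse(i > n, 2 * n + 1 - i, i)
  }
  i
}

# shift matrix by (dr, dc) with NA fill outside
shift_matrix <- function(m, dr, dc, fill = NA_real_) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  rok <- rs >= 1 & rs <= nr; cok <- cs >= 1 & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

# shift with half-sample symmetric (reflect) boundary
shift_matrix_reflect <- function(m, dr, dc) {
  m[reflect_idx(seq_len(nrow(m)) + dr, nrow(m)),
    reflect_idx(seq_len(ncol(m)) + dc, ncol(m)), drop = FALSE]
}

#' Convert and gap-fill a raw satellite-derived DEM
#'
#' Raw satellite depth products ship as positive integer depths in
#' centimetres; dividing by `divisor` (default -100) converts them to metres
#' below sea level as negative elevations. Nodata cells with at least one
#' valid neighbour in their 3x3 window are filled with the mean of the valid
#' neighbours in a single pass (fills read only original values); cells still
#' empty afterwards are taken from `fallback`, an independent depth grid
#' resampled onto the same lattice. A cell stays nodata only where both
#' sources are empty.
#'
#' @param raw a [grid_create()] grid in raw units (positive, cm of depth).
#' @param fallback depth grid (m, negative down) aligned to `raw`.
#' @param divisor unit-conversion divisor applied to `raw` (default `-100`).
#' @return a depth grid in metres (negative below sea level).
#' @export
preprocess_aca <- function(raw, fallback, divisor = -100) {
  stopifnot(is_grid(raw), is_grid(fallback))
  if (!grids_aligned(raw, fallback)) stop("`fallback` grid is not aligned to `raw`")
  if (all(is.na(raw$values))) stop("`raw` is all nodata")
  v <- raw$values / divisor
  # single-pass 3x3 neighbour mean at nodata cells, reading original values only
  val <- !is.na(v)
  v0 <- ifelse(val, v, 0)
  s <- matrix(0, nrow(v), ncol(v)); n <- matrix(0, nrow(v), ncol(v))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    s <- s + shift_matrix(v0, dr, dc, fill = 0)
    n <- n + shift_matrix(val + 0, dr, dc, fill = 0)
  }
  fill <- is.na(v) & n > 0
  v[fill] <- (s / pmax(n, 1))[fill]
  rest <- is.na(v)
  v[rest] <- fallback$values[rest]
  out <- raw
  out$values <- v
  out
}

#' Crop a grid to buffered reef outlines
#'
#' Each reef's outline is buffered outward by `buffer_m` and the grid is
#' cropped to the buffered footprint, snapped outward to whole pixels. Cells
#' whose centre lies outside the buffered polygon are masked. Reefs whose
#' buffered footprint misses the grid are skipped with a warning.
#'
#' @param grid a [grid_create()] object.
#' @param reefs a [reef_set()].
#' @param buffer_m outward buffer distance in metres (default 500).
#' @return named list (by reef id) of cropped grids.
#' @export
crop_to_reefs <- function(grid, reefs, buffer_m = 500) {
  stopifnot(is_grid(grid), inherits(reefs, "reef_set"), buffer_m >= 0)
  px <- grid$pixel_size
  out <- list()
  for (i in seq_along(reefs$reef_id)) {
    poly <- reefs$polygons[[i]]
    xmin <- min(poly[, 1]) - buffer_m; xmax <- max(poly[, 1]) + buffer_m
    ymin <- min(poly[, 2]) - buffer_m; ymax <- max(poly[, 2]) + buffer_m
    c0 <- max(1L, floor((xmin - grid$x_origin) / px) + 1L)
    c1 <- min(ncol(grid$values), ceiling((xmax - grid$x_origin) / px))
    r0 <- max(1L, floor((grid$y_origin - ymax) / px) + 1L)
    r1 <- min(nrow(grid$values), ceiling((grid$y_origin - ymin) / px))
    if (c0 > c1 || r0 > r1) {
      warning("reef ", reefs$reef_id[i], " is disjoint from the grid; skipped")
      next
    }
    sub <- grid$values[r0:r1, c0:c1, drop = FALSE]
    cx <- grid$x_origin + (seq(c0, c1) - 0.5) * px
    cy <- grid$y_origin - (seq(r0, r1) - 0.5) * px
    xy <- expand.grid(y = cy, x = cx) # row-major over sub
    keep <- dist_to_polygon(xy$x, xy$y, poly) <= buffer_m
    sub[!matrix(keep, nrow(sub), ncol(sub))] <- NA_real_
    if (all(is.na(sub))) {
      warning("reef ", reefs$reef_id[i], " has no valid cells after cropping; skipped")
      next
    }
    g <- grid
    g$values <- sub
    g$x_origin <- grid$x_origin + (c0 - 1L) * px
    g$y_origin <- grid$y_origin - (r0 - 1L) * px
    out[[reefs$reef_id[i]]] <- g
  }
  out
}

#' One Gaussian-pyramid REDUCE step
#'
#' Smooths with the separable 5-tap binomial kernel (1,4,6,4,1)/16 under
#' half-sample symmetric (reflect) padding, then decimates by two keeping
#' even-indexed rows/columns (0-based), so the parent origin is preserved and
#' the pixel size doubles. Nodata is handled by renormalising the kernel over
#' valid cells; an output cell is nodata only when every contributing cell is.
#'
#' @param grid a [grid_create()] object with at least 2 rows and columns.
#' @return the reduced grid (half the rows/columns, double the pixel size).
#' @export
gaussian_reduce <- function(grid) {
  stopifnot(is_grid(grid))
  v <- grid$values
  if (nrow(v) < 2 || ncol(v) < 2) stop("grid smaller than 2x2 cannot be reduced")
  k <- c(1, 4, 6, 4, 1) / 16
  val <- !is.na(v)
  num <- ifelse(val, v, 0)
  den <- val + 0
  conv1 <- function(m, along_rows) {
    acc <- 0
    for (t in -2:2) {
      w <- k[t + 3]
      acc <- acc + w * (if (along_rows) shift_matrix_reflect(m, t, 0)
                        else shift_matrix_reflect(m, 0, t))
    }
    acc
  }
  num <- conv1(conv1(num, TRUE), FALSE)
  den <- conv1(conv1(den, TRUE), FALSE)
  sm <- ifelse(den > 1e-12, num / den, NA_real_)
  rs <- seq(1, nrow(v), by = 2); cs <- seq(1, ncol(v), by = 2)
  out <- grid
  out$values <- sm[rs, cs, drop = FALSE]
  out$pixel_size <- grid$pixel_size * 2
  out
}

#' Build the nested multi-resolution DEM set
#'
#' Generalises three co-located bathymetry sources with repeated
#' [gaussian_reduce()] steps into the canonical eight-DEM set: the 15 m
#' source at 15/30/60/120 m, the 30 m source at 30/60/120 m, and the 100 m
#' source passed through unreduced.
#'
#' @param aca15 fine satellite-derived DEM at 15 m.
#' @param dr30 DEM at 30 m.
#' @param dr100 DEM at 100 m.
#' @return a `multiscale_stack`: list with `levels`, a named list of grids
#'   keyed `"<source>_<resolution>"`, plus a `key` data.frame.
#' @export
build_dem_set <- function(aca15, dr30, dr100) {
  stopifnot(is_grid(aca15), is_grid(dr30), is_grid(dr100))
  chk <- function(g, res, nm) {
    if (abs(g$pixel_size - res) > 1e-9)
      stop(nm, ": expected native resolution ", res, " m, found ", g$pixel_size, " m")
  }
  chk(aca15, 15, "aca15"); chk(dr30, 30, "dr30"); chk(dr100, 100, "dr100")
  crs <- unique(c(aca15$crs_id, dr30$crs_id, dr100$crs_id))
  if (length(crs) != 1) stop("input DEMs disagree on CRS: ", paste(crs, collapse = " vs "))
  pyramid <- function(g, n_levels) {
    out <- list(g)
    for (i in seq_len(n_levels - 1)) out[[i + 1]] <- gaussian_reduce(out[[i]])
    out
  }
  aca <- pyramid(aca15, 4L)
  dr  <- pyramid(dr30, 3L)
  levels <- c(
    setNames(aca, paste0("ACA_", c(15, 30, 60, 120))),
    setNames(dr, paste0("DR30_", c(30, 60, 120))),
    list(DR100_100 = dr100))
  key <- data.frame(
    source = c(rep("ACA", 4), rep("DR30", 3), "DR100"),
    resolution_m = c(15, 30, 60, 120, 30, 60, 120, 100),
    stringsAsFactors = FALSE)
  key$key <- paste0(key$source, "_", key$resolution_m)
  structure(list(levels = levels, key = key), class = "multiscale_stack")
}

#' @export
print.multiscale_stack <- function(x, ...) {
  cat(sprintf("<multiscale_stack> %d DEM level(s): %s\n",
              length(x$levels), paste(names(x$levels), collapse = ", ")))
  invisible(x)
}

#' @export
length.multiscale_stack <- function(x) length(x$levels)
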