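#' Single-band raster grid
#'
#' In-memory container for a single-band raster: a numeric matrix (row-major,
#' origin at the top-left corner) with an affine transform restricted to
#' square, axis-aligned pixels. Depths are stored as negative elevations in
#' metres; nodata cells are `NA`.
#'
#' Pixel `(r, c)` covers the half-open square
#' `[x0 + (c-1) px, x0 + c px) x (y0 - r px, y0 - (r-1) px]` and its centre is
#' `(x0 + (c - 0.5) px, y0 - (r - 0.5) px)`.
#'
#' @param values numeric matrix of elevations (m); `NA` marks nodata.
#' @param x_origin,y_origin coordinates of the grid's top-left corner (m).
#' @param pixel_size square pixel edge length (m), `> 0`.
#' @param crs_id free-text identifier of the projected CRS (metres).
#' @param source_tag one of `"ACA"`, `"DR30"`, `"DR100"`, `"SYNTH"`.
#' @return an object of class `reef_grid`.
#' @export
grid_create <- function(values, x_origin = 0, y_origin = 0, pixel_size = 1,
                        crs_id = "local-metres", source_tag = "SYNTH") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be a positive number")
  if (any(is.infinite(values)))
    stop("grid values must be finite or NA")
  structure(
    list(values = values,
         x_origin = as.numeric(x_origin),
         y_origin = as.numeric(y_origin),
         pixel_size = as.numeric(pixel_size),
         crs_id = as.character(crs_id),
         source_tag = match.arg(source_tag, c("ACA", "DR30", "DR100", "SYNTH"))),
    class = "reef_grid")
}

#' @export
print.reef_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<reef_grid> %d x %d @ %g m  [%s, %s]\n",
              nrow(v), ncol(v), x$pixel_size, x$source_tag, x$crs_id))
  cat(sprintf("  origin (%.1f, %.1f); nodata %d/%d cells; range [%.3g, %.3g]\n",
              x$x_origin, x$y_origin, sum(is.na(v)), length(v),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

#' @export
dim.reef_grid <- function(x) dim(x$values)

is_grid <- function(x) inherits(x, "reef_grid")

#' Cell-centre coordinates
#'
#' @param grid a [grid_create()] object.
#' @return list with numeric vectors `x` (per column) and `y` (per row).
#' @export
grid_centres <- function(grid) {
  stopifnot(is_grid(grid))
  list(x = grid$x_origin + (seq_len(ncol(grid$values)) - 0.5) * grid$pixel_size,
       y = grid$y_origin - (seq_len(nrow(grid$values)) - 0.5) * grid$pixel_size)
}

#' Row/column of the cells containing points
#'
#' Points outside the grid extent get `NA` indices.
#'
#' @param grid a [grid_create()] object.
#' @param x,y point coordinates (m, grid CRS).
#' @return data.frame with columns `row`, `col`.
#' @export
grid_cell_of <- function(grid, x, y) {
  stopifnot(is_grid(grid))
  px <- grid$pixel_size
  col <- floor((x - grid$x_origin) / px) + 1
  row <- floor((grid$y_origin - y) / px) + 1
  bad <- col < 1 | col > ncol(grid$values) | row < 1 | row > nrow(grid$values) |
    !is.finite(col) | !is.finite(row)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Look up grid values at point coordinates (nearest cell)
#'
#' @inheritParams grid_cell_of
#' @return numeric vector; `NA` for points off-grid or on nodata cells.
#' @export
grid_extract <- function(grid, x, y) {
  rc <- grid_cell_of(grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  out[ok] <- grid$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

grids_aligned <- function(a, b, tol = 1e-6) {
  abs(a$x_origin - b$x_origin) < tol && abs(a$y_origin - b$y_origin) < tol &&
    abs(a$pixel_size - b$pixel_size) < tol && all(dim(a$values) == dim(b$values))
}

# ---- ESRI ASCII grid I/O --------------------------------------------------
# Plain-text interchange format: 6 header lines then `nrows` rows of values,
# top row first. A JSON sidecar (<path>.json) stores crs_id and source_tag,
# which the .asc header cannot carry.

#' Read a raster from an ESRI ASCII grid file
#'
#' The header must declare square cells (`cellsize`). `xllcorner`/`yllcorner`
#' give the lower-left corner; the top-left origin is derived from them. A
#' sidecar `<path>.json` (written by [write_raster()]) restores `crs_id` and
#' `source_tag`; without it the CRS must be supplied.
#'
#' @param path path to a `.asc` file.
#' @param band band index; ASCII grids are single-band so only `1` is valid.
#' @param crs_id CRS identifier used when no sidecar is present.
#' @return a [grid_create()] object with nodata cells masked (`NA`).
#' @export
read_raster <- function(path, band = 1L, crs_id = NULL) {
  if (!file.exists(path)) stop("raster file does not exist: ", path)
  if (band != 1L) stop("ASCII grids are single-band; band = ", band, " requested")
  hdr <- readLines(path, n = 6L)
  kv <- lapply(strsplit(trimws(hdr), "\\s+"), function(p) {
    if (length(p) != 2) stop("malformed ASCII grid header line: ", paste(p, collapse = " "))
    p
  })
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% keys)) stop("ASCII grid header missing: ",
                                 paste(setdiff(need, keys), collapse = ", "))
  if (any(c("dx", "dy") %in% keys)) stop("non-square pixels (dx/dy header) not supported")
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  px <- vals[["cellsize"]]
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else -9999
  xll <- if ("xllcorner" %in% keys) vals[["xllcorner"]] else vals[["xllcenter"]] - px / 2
  yll <- if ("yllcorner" %in% keys) vals[["yllcorner"]] else vals[["yllcenter"]] - px / 2
  body <- scan(path, what = double(), skip = 6L, quiet = TRUE)
  if (length(body) != nr * nc)
    stop("ASCII grid body has ", length(body), " values, expected ", nr * nc)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else NULL
  crs <- if (!is.null(meta$crs_id)) meta$crs_id else crs_id
  if (is.null(crs)) stop("raster has no CRS: no sidecar ", basename(side),
                         " and no `crs_id` supplied")
  tag <- if (!is.null(meta$source_tag)) meta$source_tag else "SYNTH"
  grid_create(m, x_origin = xll, y_origin = yll + nr * px, pixel_size = px,
              crs_id = crs, source_tag = tag)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' Values are written at full double precision (`%.17g`) so a
#' write-read round trip is value-identical. A JSON sidecar `<path>.json`
#' stores `crs_id` and `source_tag`.
#'
#' @param grid a [grid_create()] object.
#' @param path output `.asc` path.
#' @param nodata sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, nodata = -9999) {
  stopifnot(is_grid(grid))
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(sprintf("ncols %d", nc),
           sprintf("nrows %d", nr),
           sprintf("xllcorner %.10f", grid$x_origin),
           sprintf("yllcorner %.10f", grid$y_origin - nr * grid$pixel_size),
           sprintf("cellsize %.10f", grid$pixel_size),
           sprintf("NODATA_value %g", nodata))
  v[is.na(v)] <- nodata
  rows <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  jsonlite::write_json(list(crs_id = grid$crs_id, source_tag = grid$source_tag),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
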