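#' Reef outlines and tide-station assignments
#'
#' A `reef_set` is a list of reefs, each with a unique id, an outline polygon
#' (two-column matrix of x/y vertices in the grid CRS, implicitly closed) and
#' the id of its nearest tide station.
#'
#' @param reef_id character vector of unique reef ids.
#' @param polygons list of two-column numeric matrices (x, y vertices).
#' @param tide_station_id character vector of station ids (recycled).
#' @return an object of class `reef_set`.
#' @export
reef_set <- function(reef_id, polygons, tide_station_id) {
  reef_id <- as.character(reef_id)
  if (anyDuplicated(reef_id)) stop("reef ids must be unique")
  if (length(polygons) != length(reef_id)) stop("one polygon per reef required")
  tide_station_id <- rep_len(as.character(tide_station_id), length(reef_id))
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2 || nrow(p) < 3) stop("polygons need >= 3 (x, y) vertices")
    storage.mode(p) <- "double"
    p
  })
  structure(list(reef_id = reef_id, polygons = polygons,
                 tide_station_id = tide_station_id),
            class = "reef_set")
}

#' @export
print.reef_set <- function(x, ...) {
  cat(sprintf("<reef_set> %d reef(s): %s\n", length(x$reef_id),
              paste(x$reef_id, collapse = ", ")))
  invisible(x)
}

#' @export
length.reef_set <- function(x) length(x$reef_id)

# Even-odd rule ray casting; points exactly on an edge count as inside.
point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  px <- poly[, 1]; py <- poly[, 2]
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside
}

# Euclidean distance from points to a polygon boundary; 0 for interior points.
dist_to_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  d2 <- rep(Inf, length(x))
  j <- n
  for (i in seq_len(n)) {
    ax <- poly[j, 1]; ay <- poly[j, 2]
    bx <- poly[i, 1]; by <- poly[i, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    t <- if (L2 == 0) rep(0, length(x)) else
      pmin(1, pmax(0, ((x - ax) * vx + (y - ay) * vy) / L2))
    dx <- x - (ax + t * vx); dy <- y - (ay + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
    j <- i
  }
  d <- sqrt(d2)
  d[point_in_polygon(x, y, poly)] <- 0
  d
}

#' Read reef outlines from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon features. Feature properties must
#' carry `reef_id` and may carry `tide_station_id` (default `"S1"`). Only the
#' outer ring of each polygon is used.
#'
#' @param path GeoJSON file path.
#' @return a [reef_set()].
#' @export
read_reefs_geojson <- function(path) {
  if (!file.exists(path)) stop("GeoJSON file does not exist: ", path)
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("expected a GeoJSON FeatureCollection")
  ids <- character(0); polys <- list(); stations <- character(0)
  for (f in gj$features) {
    if (!identical(f$geometry$type, "Polygon"))
      stop("only Polygon features are supported (found ", f$geometry$type, ")")
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    # drop the GeoJSON closing vertex (first == last)
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    ids <- c(ids, as.character(f$properties$reef_id))
    stations <- c(stations,
                  if (is.null(f$properties$tide_station_id)) "S1"
                  else as.character(f$properties$tide_station_id))
    polys <- c(polys, list(m))
  }
  reef_set(ids, polys, stations)
}

#' Write reef outlines to GeoJSON
#'
#' @param reefs a [reef_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reefs_geojson <- function(reefs, path) {
  feats <- lapply(seq_along(reefs$reef_id), function(i) {
    p <- reefs$polygons[[i]]
    ring <- lapply(seq_len(nrow(p)), function(j) c(p[j, 1], p[j, 2]))
    ring <- c(ring, ring[1])
    list(type = "Feature",
         properties = list(reef_id = reefs$reef_id[i],
                           tide_station_id = reefs$tide_station_id[i]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
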