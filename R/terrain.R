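# Terrain attribute derivation: a shared local quadratic (Evans-style) fit
# feeds slope, aspect components and curvatures; secondary attributes (VRM,
# BPI, SVF) use focal windows, an annulus and horizon rays respectively.

#' Terrain derivation parameters
#'
#' Window sizes are in cells and scale with the DEM resolution, so one
#' parameter set yields comparable neighbourhood extents per level of the
#' pyramid. Defaults are the conventional small-window choices for reef-scale
#' morphometry; all are configuration-exposed.
#'
#' @param fit_window odd window (cells) of the local quadratic fit (default 3).
#' @param vrm_window odd window (cells) of the ruggedness vector sum (default 3).
#' @param bpi_inner_r,bpi_outer_r annulus radii in cells (defaults 1 and 3);
#'   cells at distance `d` with `inner < d <= outer` form the annulus.
#' @param svf_azimuths number of horizon rays (default 16).
#' @param svf_radius ray length in cells (default 10).
#' @param flat_tol slope (radians) below which a cell counts as flat and gets
#'   nodata aspect components.
#' @return an object of class `terrain_params`.
#' @export
terrain_params <- function(fit_window = 3L, vrm_window = 3L,
                           bpi_inner_r = 1, bpi_outer_r = 3,
                           svf_azimuths = 16L, svf_radius = 10L,
                           flat_tol = 1e-6) {
  stopifnot(fit_window >= 3, fit_window %% 2 == 1,
            vrm_window >= 3, vrm_window %% 2 == 1,
            bpi_outer_r > bpi_inner_r, bpi_inner_r >= 0,
            svf_azimuths >= 4, svf_radius >= 1)
  structure(list(fit_window = as.integer(fit_window),
                 vrm_window = as.integer(vrm_window),
                 bpi_inner_r = bpi_inner_r, bpi_outer_r = bpi_outer_r,
                 svf_azimuths = as.integer(svf_azimuths),
                 svf_radius = as.integer(svf_radius),
                 flat_tol = flat_tol),
            class = "terrain_params")
}

#' Local quadratic surface coefficients
#'
#' Least-squares fit of `z = a x^2 + b y^2 + c xy + d x + e y + f` over the
#' `fit_window` neighbourhood of every cell (x east, y north, metres,
#' centred on the cell), solved once via the normal equations and applied as
#' a stack of shifted-matrix weights. Cells whose window leaves the grid or
#' touches a nodata cell are nodata (the usual focal-statistics edge policy).
#'
#' @param dem a [grid_create()] DEM.
#' @param params a [terrain_params()] object.
#' @return list of matrices `zx`, `zy`, `zxx`, `zyy`, `zxy` (per-metre units).
#' @export
local_quadratic <- function(dem, params = terrain_params()) {
  stopifnot(is_grid(dem))
  v <- dem$values
  w <- params$fit_window
  if (w > min(dim(v))) stop("fit window (", w, ") larger than grid")
  px <- dem$pixel_size
  h <- (w - 1L) / 2L
  off <- expand.grid(dr = -h:h, dc = -h:h)
  X <- with(off, {
    x <- dc * px; y <- -dr * px
    cbind(x^2, y^2, x * y, x, y, 1)
  })
  P <- solve(crossprod(X), t(X)) # 6 x w^2 weight rows
  acc <- vector("list", 6L)
  for (i in 1:6) acc[[i]] <- matrix(0, nrow(v), ncol(v))
  anyna <- matrix(FALSE, nrow(v), ncol(v))
  v0 <- ifelse(is.na(v), 0, v)
  for (k in seq_len(nrow(off))) {
    sh <- shift_matrix(v0, off$dr[k], off$dc[k], fill = 0)
    na_sh <- shift_matrix(is.na(v) + 0, off$dr[k], off$dc[k], fill = 1) > 0
    anyna <- anyna | na_sh
    for (i in 1:6) acc[[i]] <- acc[[i]] + P[i, k] * sh
  }
  for (i in 1:6) acc[[i]][anyna] <- NA_real_
  list(zx = acc[[4]], zy = acc[[5]],
       zxx = 2 * acc[[1]], zyy = 2 * acc[[2]], zxy = acc[[3]])
}

wrap_grid <- function(dem, values) { g <- dem; g$values <- values; g }

#' Slope (radians)
#'
#' Maximum rate of change of the fitted surface, `atan(sqrt(zx^2 + zy^2))`,
#' in `[0, pi/2)`. 0 is a flat surface; 1 rad (~57 deg) a steep slope.
#'
#' @inheritParams local_quadratic
#' @param coefs optional precomputed [local_quadratic()] output.
#' @return slope grid in radians.
#' @export
slope <- function(dem, params = terrain_params(), coefs = NULL) {
  cf <- if (is.null(coefs)) local_quadratic(dem, params) else coefs
  wrap_grid(dem, atan(sqrt(cf$zx^2 + cf$zy^2)))
}

#' Aspect components: eastness and northness
#'
#' Aspect is the downslope azimuth (north = 0, clockwise positive);
#' `EAST = sin(aspect)` and `NORTH = cos(aspect)`, so +1 means east- and
#' north-facing respectively. Cells flatter than `flat_tol` have undefined
#' orientation and get nodata in both components.
#'
#' @inheritParams slope
#' @return list with grids `east` and `north`.
#' @export
aspect_components <- function(dem, params = terrain_params(), coefs = NULL) {
  cf <- if (is.null(coefs)) local_quadratic(dem, params) else coefs
  g <- sqrt(cf$zx^2 + cf$zy^2)
  flat <- !is.na(g) & atan(g) < params$flat_tol
  east <- -cf$zx / g
  north <- -cf$zy / g
  east[flat] <- NA_real_
  north[flat] <- NA_real_
  list(east = wrap_grid(dem, east), north = wrap_grid(dem, north))
}

#' Vertical (profile) and horizontal (plan) curvature
#'
#' Normal-section curvatures of the fitted quadratic in the downslope and
#' cross-slope directions, signed per the usual geomorphometric reading:
#' `VCU > 0` upwardly concave (e.g. channel floors along flow), `VCU < 0`
#' upwardly convex; `HCU > 0` sideward convex (ridges), `HCU < 0` sideward
#' concave (gullies). Both are zero on planes and, by convention, on cells
#' with near-zero gradient. Units: radians per metre.
#'
#' @inheritParams slope
#' @return list with grids `vcu` and `hcu`.
#' @export
curvatures <- function(dem, params = terrain_params(), coefs = NULL) {
  cf <- if (is.null(coefs)) local_quadratic(dem, params) else coefs
  zx <- cf$zx; zy <- cf$zy; zxx <- cf$zxx; zyy <- cf$zyy; zxy <- cf$zxy
  g2 <- zx^2 + zy^2
  vcu <- (zxx * zx^2 + 2 * zxy * zx * zy + zyy * zy^2) / (g2 * (1 + g2)^1.5)
  hcu <- -(zxx * zy^2 - 2 * zxy * zx * zy + zyy * zx^2) / g2^1.5
  flat <- !is.na(g2) & atan(sqrt(g2)) < params$flat_tol
  vcu[flat] <- 0; hcu[flat] <- 0
  list(vcu = wrap_grid(dem, vcu), hcu = wrap_grid(dem, hcu))
}

#' Vector ruggedness measure
#'
#' Sappington-style decomposition: each cell's unit surface normal
#' `(-zx, -zy, 1) / sqrt(1 + |grad|^2)` is summed over the `vrm_window`
#' neighbourhood; `VRM = 1 - |sum| / n_valid`. 0 on any plane (normals
#' aligned), approaching 1 when normals cancel. Bounded in `[0, 1]`.
#'
#' @inheritParams slope
#' @return VRM grid.
#' @export
vrm <- function(dem, params = terrain_params(), coefs = NULL) {
  cf <- if (is.null(coefs)) local_quadratic(dem, params) else coefs
  norm <- sqrt(1 + cf$zx^2 + cf$zy^2)
  nx <- -cf$zx / norm; ny <- -cf$zy / norm; nz <- 1 / norm
  val <- !is.na(nx)
  zero <- function(m) ifelse(val, m, 0)
  nx <- zero(nx); ny <- zero(ny); nz <- zero(nz)
  h <- (params$vrm_window - 1L) / 2L
  sx <- sy <- sz <- n <- matrix(0, nrow(nx), ncol(nx))
  for (dr in -h:h) for (dc in -h:h) {
    sx <- sx + shift_matrix(nx, dr, dc, 0)
    sy <- sy + shift_matrix(ny, dr, dc, 0)
    sz <- sz + shift_matrix(nz, dr, dc, 0)
    n <- n + shift_matrix(val + 0, dr, dc, 0)
  }
  out <- 1 - sqrt(sx^2 + sy^2 + sz^2) / pmax(n, 1)
  out[n == 0 | !val] <- NA_real_
  out <- pmin(pmax(out, 0), 1) # guard rounding at the boundaries
  wrap_grid(dem, out)
}

#' Bathymetric position index (metres)
#'
#' Cell elevation minus the mean elevation over an annulus-shaped focal
#' window (`bpi_inner_r < d <= bpi_outer_r`, Euclidean cell distance).
#' Positive values are local highs (peaks, crests), negative local lows.
#'
#' @inheritParams local_quadratic
#' @return BPI grid.
#' @export
bpi <- function(dem, params = terrain_params()) {
  stopifnot(is_grid(dem))
  v <- dem$values
  r_out <- params$bpi_outer_r
  off <- expand.grid(dr = -ceiling(r_out):ceiling(r_out),
                     dc = -ceiling(r_out):ceiling(r_out))
  d <- sqrt(off$dr^2 + off$dc^2)
  off <- off[d > params$bpi_inner_r & d <= r_out, , drop = FALSE]
  if (nrow(off) == 0) stop("empty annulus: check bpi_inner_r/bpi_outer_r")
  val <- !is.na(v)
  v0 <- ifelse(val, v, 0)
  s <- n <- matrix(0, nrow(v), ncol(v))
  for (k in seq_len(nrow(off))) {
    s <- s + shift_matrix(v0, off$dr[k], off$dc[k], 0)
    n <- n + shift_matrix(val + 0, off$dr[k], off$dc[k], 0)
  }
  out <- v - s / pmax(n, 1)
  out[n == 0] <- NA_real_
  wrap_grid(dem, out)
}

#' Sky view factor
#'
#' Fraction of the overhead hemisphere left open by surrounding terrain. For
#' each of `svf_azimuths` evenly spaced directions, the horizon angle is the
#' maximum (clamped at 0) of `atan((z_sample - z_cell) / distance)` over ray
#' samples at 1-cell steps up to `svf_radius`; `SVF = 1 - mean(sin(horizon))`,
#' in `[0, 1]` (1 = fully open, 0 = fully obstructed). Rays truncated at the
#' grid edge use the available samples.
#'
#' @inheritParams local_quadratic
#' @return SVF grid.
#' @export
svf <- function(dem, params = terrain_params()) {
  stopifnot(is_grid(dem))
  v <- dem$values
  px <- dem$pixel_size
  naz <- params$svf_azimuths
  sin_sum <- matrix(0, nrow(v), ncol(v))
  for (a in seq_len(naz)) {
    theta <- 2 * pi * (a - 1) / naz # azimuth from north, clockwise
    hmax <- matrix(0, nrow(v), ncol(v))
    for (k in seq_len(params$svf_radius)) {
      dc <- round(sin(theta) * k)
      dr <- -round(cos(theta) * k)
      if (dc == 0 && dr == 0) next
      dist <- sqrt(dr^2 + dc^2) * px
      zs <- shift_matrix(v, dr, dc, NA_real_)
      tanh_ <- (zs - v) / dist
      upd <- !is.na(tanh_) & tanh_ > 0
      # running max of positive obstruction tangents
      hmax[upd] <- pmax(hmax[upd], tanh_[upd])
    }
    sin_sum <- sin_sum + sin(atan(hmax))
  }
  out <- 1 - sin_sum / naz
  out[is.na(v)] <- NA_real_
  wrap_grid(dem, out)
}

variable_codes <- c("DEPTH", "SLOPE", "EAST", "NORTH", "VCU", "HCU",
                    "VRM", "BPI", "SVF")

derive_one <- function(dem, params) {
  cf <- local_quadratic(dem, params)
  asp <- aspect_components(dem, params, coefs = cf)
  cur <- curvatures(dem, params, coefs = cf)
  list(DEPTH = dem,
       SLOPE = slope(dem, params, coefs = cf),
       EAST = asp$east, NORTH = asp$north,
       VCU = cur$vcu, HCU = cur$hcu,
       VRM = vrm(dem, params, coefs = cf),
       BPI = bpi(dem, params),
       SVF = svf(dem, params))
}

#' Derive the full predictor stack
#'
#' Computes depth plus the eight topographic attributes for every DEM level
#' of a [build_dem_set()] stack: 9 layers per level, 72 for the canonical
#' eight-DEM set.
#'
#' @param stack a `multiscale_stack`.
#' @param params a [terrain_params()] object.
#' @return a `variable_stack`: named list of grids keyed
#'   `"<source>_<resolution>_<VARIABLE>"`, plus a `key` data.frame.
#' @export
derive_all <- function(stack, params = terrain_params()) {
  stopifnot(inherits(stack, "multiscale_stack"))
  layers <- list()
  key <- NULL
  for (i in seq_len(nrow(stack$key))) {
    src <- stack$key$source[i]; res <- stack$key$resolution_m[i]
    dem <- stack$levels[[stack$key$key[i]]]
    vars <- tryCatch(derive_one(dem, params), error = function(e)
      stop("terrain derivation failed for (", src, ", ", res, " m): ",
           conditionMessage(e)))
    nm <- paste0(src, "_", res, "_", variable_codes)
    layers[nm] <- vars[variable_codes]
    key <- rbind(key, data.frame(source = src, resolution_m = res,
                                 variable = variable_codes, key = nm,
                                 stringsAsFactors = FALSE))
  }
  structure(list(layers = layers, key = key), class = "variable_stack")
}

#' @export
print.variable_stack <- function(x, ...) {
  cat(sprintf("<variable_stack> %d layer(s) over %d DEM level(s)\n",
              length(x$layers), length(unique(paste(x$key$source, x$key$resolution_m)))))
  invisible(x)
}

#' @export
length.variable_stack <- function(x) length(x$layers)

#' Spearman comparison of two derived-variable stacks
#'
#' For every (resolution, variable) pair shared by two sources, Spearman's
#' rank correlation is computed at up to `n_points` seeded random cells,
#' restricted to cells valid in both layers, with at most one point per cell
#' of the coarsest shared grid. Pairs with `|r_s| >= threshold` are flagged as
#' strongly correlated (default 0.8).
#'
#' @param a,b `variable_stack`s from two sources over the same extent.
#' @param n_points sample-size cap (default 15000).
#' @param seed RNG seed.
#' @param threshold flagging threshold on `|r_s|`.
#' @return data.frame (class `correlation_report`) with columns `variable`,
#'   `resolution_m`, `r_s`, `n_points`, `flagged`.
#' @export
compare_sources <- function(a, b, n_points = 15000, seed = 1, threshold = 0.8) {
  stopifnot(inherits(a, "variable_stack"), inherits(b, "variable_stack"))
  ka <- a$key; kb <- b$key
  shared <- merge(ka[, c("resolution_m", "variable", "key")],
                  kb[, c("resolution_m", "variable", "key")],
                  by = c("resolution_m", "variable"), suffixes = c("_a", "_b"))
  if (nrow(shared) == 0) stop("stacks share no (resolution, variable) keys")
  # sample once per resolution on the coarsest shared grid, reuse across variables
  rs_out <- numeric(0); np_out <- integer(0)
  set.seed(seed)
  coarsest <- max(shared$resolution_m)
  samples <- list()
  for (res in unique(shared$resolution_m)) {
    ga <- a$layers[[shared$key_a[shared$resolution_m == res][1]]]
    # one point per pixel of the coarsest grid: subsample cells whose
    # coarse-cell index is unique
    ok_cells <- which(!is.na(ga$values), arr.ind = TRUE)
    if (nrow(ok_cells) == 0) { samples[[as.character(res)]] <- NULL; next }
    ratio <- max(1, round(coarsest / res))
    coarse_id <- paste(ceiling(ok_cells[, 1] / ratio), ceiling(ok_cells[, 2] / ratio))
    pick <- sample(nrow(ok_cells))
    pick <- pick[!duplicated(coarse_id[pick])]
    pick <- pick[seq_len(min(length(pick), n_points))]
    samples[[as.character(res)]] <- ok_cells[pick, , drop = FALSE]
  }
  for (i in seq_len(nrow(shared))) {
    ga <- a$layers[[shared$key_a[i]]]; gb <- b$layers[[shared$key_b[i]]]
    if (!grids_aligned(ga, gb)) stop("layers not aligned for ",
                                     shared$variable[i], " @ ", shared$resolution_m[i], " m")
    cells <- samples[[as.character(shared$resolution_m[i])]]
    va <- ga$values[cells]; vb <- gb$values[cells]
    ok <- !is.na(va) & !is.na(vb)
    if (sum(ok) < 3) { rs_out[i] <- NA_real_; np_out[i] <- sum(ok); next }
    rs_out[i] <- suppressWarnings(cor(va[ok], vb[ok], method = "spearman"))
    np_out[i] <- sum(ok)
  }
  out <- data.frame(variable = shared$variable, resolution_m = shared$resolution_m,
                    r_s = rs_out, n_points = np_out,
                    flagged = !is.na(rs_out) & abs(rs_out) >= threshold,
                    stringsAsFactors = FALSE)
  class(out) <- c("correlation_report", "data.frame")
  out
}
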