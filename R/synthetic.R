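# Seeded synthetic reef world: co-registered multi-resolution DEMs with a
# known analytic truth surface, reef outlines, tide series, colony depth
# records and occurrences driven by a known logistic terrain response.

#' Synthetic reef world specification
#'
#' The truth surface is analytic: per reef a radial lagoon-flat-crest-slope
#' profile (depths in metres, `crest < lagoon < slope_max`), combined across
#' reefs by taking the shallowest, plus a seeded Gaussian random-field
#' roughness with configurable correlation length. The three source DEMs
#' sample this surface at 15/30/100 m cell centres with independent sensor
#' noise.
#'
#' @param n_reefs number of reefs (default 3).
#' @param reef_radius_m nominal reef radius (default 600).
#' @param lagoon_depth_m,crest_depth_m,upper_slope_depth_m,slope_max_depth_m
#'   profile depths (positive metres; defaults 12, 1, 10, 25): lagoon basin,
#'   crest ring, toe of the gently dipping upper slope, and the plain beyond
#'   the fore-reef wall. The default lagoon is deeper than typical shallow
#'   colony habitat, so crests and upper slopes form the sampled band.
#' @param noise_sd_m per-source sensor noise SD (default 0.3).
#' @param roughness_sd_m SD of the roughness field (default 0.8, the scale of
#'   spur-and-groove and bommie relief seen at 15 m resolution).
#' @param roughness_corr_length_m roughness correlation length (default 60).
#' @param n_cells fine-grid edge length in cells (default 256).
#' @param pixel_size_m fine-grid pixel size (default 15).
#' @param seed RNG seed.
#' @return an object of class `reef_spec`.
#' @export
reef_spec <- function(n_reefs = 3, reef_radius_m = 600, lagoon_depth_m = 12,
                      crest_depth_m = 1, upper_slope_depth_m = 10,
                      slope_max_depth_m = 25,
                      noise_sd_m = 0.3, roughness_sd_m = 0.8,
                      roughness_corr_length_m = 60, n_cells = 256,
                      pixel_size_m = 15, seed = 1) {
  if (!(crest_depth_m < lagoon_depth_m && lagoon_depth_m < slope_max_depth_m))
    stop("profile depths must satisfy crest < lagoon < slope_max")
  if (!(crest_depth_m < upper_slope_depth_m &&
        upper_slope_depth_m < slope_max_depth_m))
    stop("upper_slope_depth_m must lie between crest and slope_max depths")
  stopifnot(noise_sd_m >= 0, roughness_sd_m >= 0, n_reefs >= 1, n_cells >= 16)
  structure(as.list(environment()), class = "reef_spec")
}

# stationary Gaussian random field by FFT smoothing of white noise,
# rescaled to unit SD (circular boundary; fine for fixtures)
gaussian_field <- function(n, sigma_cells) {
  w <- matrix(rnorm(n * n), n, n)
  if (sigma_cells <= 0) return(w)
  d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  k2 <- outer(d^2, d^2, "+")
  filt <- exp(-k2 / (2 * sigma_cells^2))
  f <- Re(fft(fft(w) * fft(filt / sum(filt)), inverse = TRUE)) / n^2
  f / sd(f)
}

# bilinear interpolation of a fine-lattice field at arbitrary coordinates
bilinear_at <- function(field, x_origin, y_origin, px, x, y) {
  n_r <- nrow(field); n_c <- ncol(field)
  gc <- (x - x_origin) / px + 0.5 # fractional column at cell centres
  gr <- (y_origin - y) / px + 0.5
  c0 <- pmin(pmax(floor(gc), 1), n_c - 1); r0 <- pmin(pmax(floor(gr), 1), n_r - 1)
  fc <- pmin(pmax(gc - c0, 0), 1); fr <- pmin(pmax(gr - r0, 0), 1)
  field[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    field[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    field[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    field[cbind(r0 + 1, c0 + 1)] * fr * fc
}

make_circle <- function(cx, cy, r, n = 48) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# radial depth profile (positive metres down) at scaled distance u = d / R:
# lagoon basin, shoaling flat, shallow crest ring, an upper slope down to
# `upper`, a steep fore-reef wall, then the surrounding plain at slope_max.
# The upper-slope width varies around the reef through the exposure factor
# `a` in [0, 1]: windward margins (a ~ 0) drop off almost directly from the
# crest, leeward margins (a ~ 1) carry a wide gently dipping upper slope --
# the classic asymmetry of platform reefs, and the habitat contrast that
# makes both slope- and position-driven colony responses expressible.
reef_profile_depth <- function(u, a, lagoon, crest, upper, slope_max) {
  wu <- 0.02 + 0.30 * a # upper-slope width (in units of R)
  u1 <- 0.70 + wu       # wall top
  u2 <- u1 + 0.10       # wall base
  ifelse(u < 0.35, lagoon,
    ifelse(u < 0.55, lagoon + (crest - lagoon) * (u - 0.35) / 0.20,
      ifelse(u < 0.70, crest,
        ifelse(u < u1, crest + (upper - crest) * (u - 0.70) / wu,
          ifelse(u < u2, upper + (slope_max - upper) * (u - u1) / 0.10,
                 slope_max)))))
}

#' Generate co-registered synthetic reef DEMs
#'
#' Builds the analytic truth surface for `spec`, samples it at 15/30/100 m
#' cell centres with independent sensor noise to emulate three co-located
#' bathymetry sources, and returns reef outline polygons with tide-station
#' assignments. Deterministic per `spec$seed`.
#'
#' @param spec a [reef_spec()].
#' @return list with grids `aca15`, `dr30`, `dr100`, a [reef_set()] `reefs`,
#'   reef centres `centres`, and `truth(x, y)`, the noise-free truth
#'   elevation function (m, negative down).
#' @export
generate_reef_dem <- function(spec) {
  stopifnot(inherits(spec, "reef_spec"))
  extent <- spec$n_cells * spec$pixel_size_m
  R <- spec$reef_radius_m
  if (2.6 * R > extent) stop("grid too small for reef radius: extent ", extent,
                             " m vs reef diameter (with slope) ", 2.6 * R, " m")
  set.seed(spec$seed)
  # reef centres on a ring (single reef at the centre)
  ctr <- extent / 2
  if (spec$n_reefs == 1) {
    cx <- ctr; cy <- ctr
  } else {
    ring <- max(0.28 * extent, 1.32 * R)
    th <- 2 * pi * (seq_len(spec$n_reefs) - 1) / spec$n_reefs + 0.4
    cx <- ctr + ring * cos(th); cy <- ctr + ring * sin(th)
  }
  phases <- runif(length(cx), 0, 2 * pi) # windward orientation per reef
  rough <- spec$roughness_sd_m *
    gaussian_field(spec$n_cells, spec$roughness_corr_length_m / spec$pixel_size_m)
  x0 <- 0; y0 <- extent; px <- spec$pixel_size_m
  truth <- function(x, y) {
    depth <- rep(spec$slope_max_depth_m, length(x))
    for (i in seq_along(cx)) {
      u <- sqrt((x - cx[i])^2 + (y - cy[i])^2) / R
      expo <- 0.5 * (1 + cos(atan2(y - cy[i], x - cx[i]) - phases[i]))
      depth <- pmin(depth, reef_profile_depth(u, expo, spec$lagoon_depth_m,
                                              spec$crest_depth_m,
                                              spec$upper_slope_depth_m,
                                              spec$slope_max_depth_m))
    }
    -depth + bilinear_at(rough, x0, y0, px, x, y)
  }
  sample_source <- function(res, tag) {
    nc <- floor(extent / res)
    gx <- (seq_len(nc) - 0.5) * res
    gy <- extent - (seq_len(nc) - 0.5) * res
    xy <- expand.grid(y = gy, x = gx)
    z <- truth(xy$x, xy$y)
    if (spec$noise_sd_m > 0) z <- z + rnorm(length(z), 0, spec$noise_sd_m)
    grid_create(matrix(z, nc, nc), x_origin = 0, y_origin = extent,
                pixel_size = res, crs_id = "synthetic-metres", source_tag = tag)
  }
  aca15 <- sample_source(spec$pixel_size_m, "ACA")
  dr30 <- sample_source(2 * spec$pixel_size_m, "DR30")
  dr100 <- sample_source(100, "DR100")
  reefs <- reef_set(
    paste0("reef", seq_along(cx)),
    lapply(seq_along(cx), function(i) make_circle(cx[i], cy[i], 1.35 * R)),
    paste0("S", seq_along(cx)))
  list(aca15 = aca15, dr30 = dr30, dr100 = dr100, reefs = reefs,
       centres = cbind(x = cx, y = cy), truth = truth)
}

#' Occurrence response specification
#'
#' Defaults follow the sampling conditions of shallow-water colony surveys:
#' colonies restricted to 8 m depth along crests and upper slopes, handheld
#' GPS location noise of about 3 m, and dive-computer depth noise of 1 m.
#'
#' @param coefficients named numeric vector of logistic coefficients on
#'   z-scored predictor layers (names = `variable_stack` keys).
#' @param intercept logistic intercept (default 0).
#' @param n_presence number of presence colonies to draw (default 250).
#' @param depth_cap_m maximum truth depth of candidate cells (default 8).
#' @param gps_noise_sd_m coordinate jitter SD (default 3).
#' @param depth_noise_sd_m depth-record noise SD (default 1).
#' @return an object of class `response_spec`.
#' @export
response_spec <- function(coefficients, intercept = 0, n_presence = 250,
                          depth_cap_m = 8, gps_noise_sd_m = 3,
                          depth_noise_sd_m = 1) {
  stopifnot(depth_cap_m > 0, gps_noise_sd_m >= 0, depth_noise_sd_m >= 0,
            length(coefficients) >= 1, !is.null(names(coefficients)))
  structure(as.list(environment()), class = "response_spec")
}

#' Simulate occurrences, depth records and tides from a known response
#'
#' Candidate cells are the valid cells of the finest DEPTH layer that lie
#' within a reef outline and are shallower than `resp$depth_cap_m`. Presence
#' probability is `plogis(intercept + sum(beta * z))` with the named layers
#' z-scored over candidates; `n_presence` cells are drawn without replacement
#' weighted by probability. Coordinates are jittered by GPS noise. Each
#' presence yields a depth record: `raw_depth = depth - tide(t) + noise`
#' (clamped at 0), where `depth` is the cell's DEM depth, so that
#' [correct_to_lat()] recovers the cell elevation. Tide series are synthetic
#' semidiurnal sinusoids per station.
#'
#' @param stack a `variable_stack` containing every layer named in
#'   `resp$coefficients` and at least one DEPTH layer.
#' @param resp a [response_spec()].
#' @param reefs a [reef_set()].
#' @param seed RNG seed.
#' @param tide_amplitude_m semidiurnal amplitude (default 0.8; 0 disables
#'   tides, giving constant-zero series).
#' @return list with `presences` (point_id, x, y, reef_id), `all_coords`,
#'   `depth_records`, `tides` (named list of [tide_table()]s), `stations`
#'   (reef -> station map), and `prob` (per-candidate probabilities).
#' @export
simulate_occurrences <- function(stack, resp, reefs, seed = 1,
                                 tide_amplitude_m = 0.8) {
  stopifnot(inherits(stack, "variable_stack"), inherits(resp, "response_spec"),
            inherits(reefs, "reef_set"))
  miss <- setdiff(names(resp$coefficients), names(stack$layers))
  if (length(miss) > 0) stop("stack is missing response layer(s): ",
                             paste(miss, collapse = ", "))
  depth_keys <- stack$key$key[stack$key$variable == "DEPTH"]
  if (length(depth_keys) == 0) stop("stack has no DEPTH layer")
  fine <- depth_keys[which.min(stack$key$resolution_m[match(depth_keys, stack$key$key)])]
  dem <- stack$layers[[fine]]
  set.seed(seed)
  idx <- which(!is.na(dem$values) & dem$values >= -resp$depth_cap_m, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("no candidate cells shallower than the depth cap")
  cxy <- data.frame(
    x = dem$x_origin + (idx[, 2] - 0.5) * dem$pixel_size,
    y = dem$y_origin - (idx[, 1] - 0.5) * dem$pixel_size)
  reef_of <- rep(NA_character_, nrow(cxy))
  for (i in seq_along(reefs$reef_id)) {
    inside <- point_in_polygon(cxy$x, cxy$y, reefs$polygons[[i]])
    reef_of[inside & is.na(reef_of)] <- reefs$reef_id[i]
  }
  keep <- !is.na(reef_of)
  idx <- idx[keep, , drop = FALSE]; cxy <- cxy[keep, , drop = FALSE]
  reef_of <- reef_of[keep]
  if (nrow(idx) == 0) stop("no candidate cells inside reef outlines")
  eta <- rep(resp$intercept, nrow(idx))
  for (k in names(resp$coefficients)) {
    v <- grid_extract(stack$layers[[k]], cxy$x, cxy$y)
    ok <- !is.na(v)
    # rank (ECDF) scaling to [-1, 1] over candidate cells: robust to the
    # heavy-tailed distributions of terrain attributes, so every named
    # variable contributes on a comparable scale
    z <- rep(0, length(v))
    if (length(unique(v[ok])) > 1)
      z[ok] <- 2 * ((rank(v[ok]) - 0.5) / sum(ok) - 0.5)
    eta <- eta + resp$coefficients[[k]] * z
    eta[!ok] <- -Inf # cells lacking a response layer can't host presences
  }
  prob <- plogis(eta)
  if (resp$n_presence > sum(prob > 0))
    stop("n_presence exceeds available candidate cells")
  pick <- sample.int(nrow(idx), resp$n_presence, prob = prob)
  px <- data.frame(
    point_id = sprintf("p%04d", seq_len(resp$n_presence)),
    x = cxy$x[pick] + rnorm(resp$n_presence, 0, resp$gps_noise_sd_m),
    y = cxy$y[pick] + rnorm(resp$n_presence, 0, resp$gps_noise_sd_m),
    reef_id = reef_of[pick], stringsAsFactors = FALSE)
  # synthetic semidiurnal tides over a 10-day window, one series per station
  t0 <- 0; t1 <- 10 * 86400
  tt_times <- seq(t0, t1, by = 1800)
  stations <- setNames(reefs$tide_station_id, reefs$reef_id)
  tides <- list()
  for (s in unique(reefs$tide_station_id)) {
    phase <- runif(1, 0, 2 * pi)
    h <- tide_amplitude_m * (1 + sin(2 * pi * tt_times / (12.42 * 3600) + phase))
    tides[[s]] <- tide_table(s, tt_times, h)
  }
  ts <- runif(resp$n_presence, t0 + 3600, t1 - 3600)
  cell_depth <- -dem$values[idx[pick, , drop = FALSE]] # positive metres
  tide_h <- vapply(seq_len(resp$n_presence), function(i)
    tide_at(tides[[stations[[px$reef_id[i]]]]], ts[i]), 0)
  raw <- pmax(0, cell_depth - tide_h +
                rnorm(resp$n_presence, 0, resp$depth_noise_sd_m))
  records <- data.frame(
    record_id = px$point_id, reef_id = px$reef_id,
    x = cxy$x[pick], y = cxy$y[pick],
    raw_depth = raw, timestamp = ts, species_code = "SP1",
    stringsAsFactors = FALSE)
  list(presences = px, all_coords = px[, c("x", "y")],
       depth_records = records, tides = tides, stations = stations,
       prob = prob)
}
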