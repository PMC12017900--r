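# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except files the tests themselves write to tempdir().

# grid whose values follow z = f(x, y) at cell centres (x east, y north)
surface_grid <- function(f, n = 9, px = 1, x0 = 0, y0 = n * px) {
  xs <- x0 + (seq_len(n) - 0.5) * px
  ys <- y0 - (seq_len(n) - 0.5) * px
  vals <- outer(seq_len(n), seq_len(n), function(r, c) f(xs[c], ys[r]))
  grid_create(vals, x_origin = x0, y_origin = y0, pixel_size = px)
}

plane_grid <- function(gx = 0, gy = 0, n = 9, px = 1, z0 = 0) {
  surface_grid(function(x, y) z0 + gx * x + gy * y, n = n, px = px)
}

# independent dense 2-D convolution oracle for the pyramid REDUCE step
# (5-tap binomial kernel, reflect padding, decimation by 2)
reduce_oracle <- function(m) {
  k <- c(1, 4, 6, 4, 1) / 16
  refl <- function(i, n) { if (i < 1) i <- 1 - i; if (i > n) i <- 2 * n + 1 - i; i }
  n <- nrow(m); p <- ncol(m)
  sm <- matrix(0, n, p)
  for (r in seq_len(n)) for (c in seq_len(p)) {
    acc <- 0
    for (dr in -2:2) for (dc in -2:2)
      acc <- acc + k[dr + 3] * k[dc + 3] * m[refl(r + dr, n), refl(c + dc, p)]
    sm[r, c] <- acc
  }
  sm[seq(1, n, 2), seq(1, p, 2), drop = FALSE]
}

# memoised small synthetic world shared across test files
.fixture_cache <- new.env(parent = emptyenv())

small_world <- function(seed = 3, n_cells = 96, reef_radius_m = 300) {
  key <- paste0("world_", seed, "_", n_cells, "_", reef_radius_m)
  if (is.null(.fixture_cache[[key]])) {
    sp <- reef_spec(n_reefs = 3, n_cells = n_cells, seed = seed,
                    reef_radius_m = reef_radius_m)
    .fixture_cache[[key]] <- generate_reef_dem(sp)
  }
  .fixture_cache[[key]]
}

# the strong-signal recovery fixture: response on 30 m slope and 15 m BPI
# (beta = 5 each) plus three smooth pure-noise layers; DEPTH available to the
# model as in the field protocol
recovery_fixture <- function(seed) {
  sp <- reef_spec(n_reefs = 3, n_cells = 144, seed = seed)
  w <- generate_reef_dem(sp)
  st <- build_dem_set(w$aca15, w$dr30, w$dr100)
  dem <- st$levels[["ACA_15"]]
  p <- terrain_params()
  vs <- structure(list(
    layers = list(DEPTH = dem,
                  SLOPE30 = slope(st$levels[["ACA_30"]], p),
                  BPI = bpi(dem, p)),
    key = data.frame(source = "ACA", resolution_m = c(15, 30, 15),
                     variable = c("DEPTH", "SLOPE", "BPI"),
                     key = c("DEPTH", "SLOPE30", "BPI"),
                     stringsAsFactors = FALSE)),
    class = "variable_stack")
  set.seed(1000 + seed)
  for (i in 1:3) {
    nz <- dem
    nz$values <- matrix(rnorm(length(dem$values)), nrow(dem$values))
    vs$layers[[paste0("NOISE", i)]] <- nz
    vs$key <- rbind(vs$key, data.frame(
      source = "SYNTH", resolution_m = 15, variable = paste0("NOISE", i),
      key = paste0("NOISE", i), stringsAsFactors = FALSE))
  }
  resp <- response_spec(c(SLOPE30 = 5, BPI = 5), n_presence = 250)
  sim <- simulate_occurrences(vs, resp, w$reefs, seed = seed + 100)
  thin <- thin_occurrences(sim$presences, dem)
  bg <- sample_background(sim$all_coords,
                          crop_to_reefs(dem, w$reefs, 500),
                          n = 800, seed = seed + 200)
  keys <- c("DEPTH", "SLOPE30", "BPI", paste0("NOISE", 1:3))
  list(world = w, stack = st, vstack = vs,
       table = build_feature_table(thin, bg, vs, keys), keys = keys)
}

# presence/background table with one informative column and pure noise
toy_signal_table <- function(n_pos = 150, n_neg = 450, n_noise = 2, seed = 1,
                             beta = 3) {
  set.seed(seed)
  n <- n_pos + n_neg
  x <- runif(n)
  eta <- beta * (x - 0.5) * 2
  lab <- integer(n)
  lab[order(-(eta + rlogis(n)))[seq_len(n_pos)]] <- 1L
  out <- data.frame(point_id = paste0("t", seq_len(n)),
                    reef_id = sample(c("r1", "r2", "r3"), n, replace = TRUE),
                    label = lab, sig = x, stringsAsFactors = FALSE)
  for (i in seq_len(n_noise)) out[[paste0("noise", i)]] <- runif(n)
  class(out) <- c("feature_table", "data.frame")
  out
}
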