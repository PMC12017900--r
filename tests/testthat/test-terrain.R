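# Terrain attributes against analytic surfaces and brute-force oracles.

inner <- function(g, b = 2) {
  n <- nrow(g$values)
  g$values[(1 + b):(n - b), (1 + b):(n - b)]
}

test_that("local quadratic fit is exact on polynomials and matches dense LS", {
  g <- plane_grid(gx = 2)
  cf <- local_quadratic(g)
  expect_equal(inner(list(values = cf$zx)), matrix(2, 5, 5), tolerance = 1e-10)
  expect_equal(max(abs(inner(list(values = cf$zxx)))), 0, tolerance = 1e-9)

  g2 <- plane_grid(gy = 3)
  cf2 <- local_quadratic(g2)
  expect_equal(inner(list(values = cf2$zy)), matrix(3, 5, 5), tolerance = 1e-10)

  par <- surface_grid(function(x, y) (x - 4.5)^2 + (y - 4.5)^2)
  cfp <- local_quadratic(par)
  expect_equal(inner(list(values = cfp$zxx)), matrix(2, 5, 5), tolerance = 1e-9)
  expect_equal(inner(list(values = cfp$zyy)), matrix(2, 5, 5), tolerance = 1e-9)
  expect_equal(max(abs(inner(list(values = cfp$zxy)))), 0, tolerance = 1e-9)
})

test_that("centre-cell coefficients equal the normal-equations oracle", {
  set.seed(21)
  px <- 2.5
  g <- grid_create(matrix(rnorm(25), 5, 5), 0, 5 * px, px)
  cf <- local_quadratic(g)
  # dense least squares at the centre cell (3, 3)
  rows <- expand.grid(dr = -1:1, dc = -1:1)
  X <- with(rows, { x <- dc * px; y <- -dr * px; cbind(x^2, y^2, x * y, x, y, 1) })
  z <- mapply(function(dr, dc) g$values[3 + dr, 3 + dc], rows$dr, rows$dc)
  beta <- solve(t(X) %*% X, t(X) %*% z)
  expect_equal(cf$zx[3, 3], beta[4], tolerance = 1e-10)
  expect_equal(cf$zy[3, 3], beta[5], tolerance = 1e-10)
  expect_equal(cf$zxx[3, 3], 2 * beta[1], tolerance = 1e-10)
  expect_equal(cf$zyy[3, 3], 2 * beta[2], tolerance = 1e-10)
  expect_equal(cf$zxy[3, 3], beta[3], tolerance = 1e-10)
  expect_error(local_quadratic(g, terrain_params(fit_window = 7)), "larger")
})

test_that("slope is exact on planes including the steep reference plane", {
  expect_equal(max(abs(slope(plane_grid())$values), na.rm = TRUE), 0,
               tolerance = 1e-9)
  s1 <- slope(plane_grid(gx = 1))
  expect_equal(inner(s1), matrix(atan(1), 5, 5), tolerance = 1e-9)
  # gradient tan(1) -> slope of 1 radian (~57 deg)
  s2 <- slope(plane_grid(gx = tan(1) / sqrt(2), gy = tan(1) / sqrt(2)))
  expect_equal(inner(s2), matrix(1, 5, 5), tolerance = 1e-9)
  expect_true(all(s2$values >= 0 & s2$values < pi / 2, na.rm = TRUE))
})

test_that("aspect components point downslope with unit norm", {
  north_dip <- plane_grid(gy = -0.5) # z falls northward -> north-facing
  a <- aspect_components(north_dip)
  expect_equal(inner(a$north), matrix(1, 5, 5), tolerance = 1e-9)
  expect_equal(max(abs(inner(a$east))), 0, tolerance = 1e-9)

  east_dip <- plane_grid(gx = -0.5)
  a2 <- aspect_components(east_dip)
  expect_equal(inner(a2$east), matrix(1, 5, 5), tolerance = 1e-9)

  set.seed(3)
  rg <- grid_create(matrix(rnorm(100), 10, 10), 0, 10, 1)
  a3 <- aspect_components(rg)
  sl <- slope(rg)$values
  ok <- !is.na(a3$east$values)
  expect_true(any(ok))
  expect_equal(a3$east$values[ok]^2 + a3$north$values[ok]^2,
               rep(1, sum(ok)), tolerance = 1e-12)
  # flat cells get nodata aspect
  expect_true(all(is.na(aspect_components(plane_grid())$east$values)))
})

test_that("curvature signs and magnitudes match the differential-geometry oracle", {
  cv <- curvatures(plane_grid(gx = 0.4, gy = -0.2))
  expect_equal(max(abs(inner(cv$vcu))), 0, tolerance = 1e-9)
  expect_equal(max(abs(inner(cv$hcu))), 0, tolerance = 1e-9)

  # channel floor dipping +x, concave upward along flow -> VCU > 0
  chan <- surface_grid(function(x, y) 0.05 * (x - 4.5)^2 - 0.8 * x)
  expect_true(all(inner(curvatures(chan)$vcu) > 0))

  # ridge running north with a northward dip -> sideward convex, HCU > 0
  ridge <- surface_grid(function(x, y) -0.05 * (x - 4.5)^2 + 0.3 * y)
  expect_true(all(inner(curvatures(ridge)$hcu) > 0))

  # z = x^2 + 3x at x = 0: zx = 3, zxx = 2; oracle from the closed form
  surf <- surface_grid(function(x, y) (x - 4.5)^2 + 3 * (x - 4.5))
  cvx <- curvatures(surf)
  cfo <- local_quadratic(surf)
  r <- 5; c <- 5
  zx <- cfo$zx[r, c]; zxx <- cfo$zxx[r, c]
  oracle <- (zxx * zx^2) / ((zx^2) * (1 + zx^2)^1.5)
  expect_equal(cvx$vcu$values[r, c], oracle, tolerance = 1e-9)
  expect_gt(cvx$vcu$values[r, c], 0)
})

test_that("ruggedness is 0 on planes and matches the vector-sum oracle", {
  expect_equal(max(abs(vrm(plane_grid())$values), na.rm = TRUE), 0,
               tolerance = 1e-12)
  expect_equal(max(abs(vrm(plane_grid(gx = 0.7, gy = -0.3))$values),
                   na.rm = TRUE), 0, tolerance = 1e-9)

  set.seed(9)
  g <- grid_create(matrix(rnorm(25, sd = 2), 5, 5), 0, 5, 1)
  v <- vrm(g)
  # oracle: per-cell normals from an independent dense quadratic fit,
  # then an explicit 3x3 vector sum at the centre cell
  rows <- expand.grid(dr = -1:1, dc = -1:1)
  X <- with(rows, { x <- dc; y <- -dr; cbind(x^2, y^2, x * y, x, y, 1) })
  P <- solve(t(X) %*% X, t(X))
  refl <- function(i) { if (i < 1) i <- 1 - i; if (i > 5) i <- 11 - i; i }
  grad <- function(r, c) {
    z <- mapply(function(dr, dc) g$values[refl(r + dr), refl(c + dc)],
                rows$dr, rows$dc)
    b <- P %*% z
    c(b[4], b[5])
  }
  sx <- sy <- sz <- 0
  for (dr in -1:1) for (dc in -1:1) {
    gr <- grad(3 + dr, 3 + dc)
    nrm <- sqrt(1 + sum(gr^2))
    sx <- sx - gr[1] / nrm; sy <- sy - gr[2] / nrm; sz <- sz + 1 / nrm
  }
  expect_equal(v$values[3, 3], 1 - sqrt(sx^2 + sy^2 + sz^2) / 9,
               tolerance = 1e-12)
  expect_true(all(v$values >= 0 & v$values <= 1, na.rm = TRUE))
})

test_that("position index matches explicit annulus enumeration", {
  expect_equal(max(abs(bpi(plane_grid(z0 = -4))$values)), 0, tolerance = 1e-12)

  bump <- grid_create(matrix(0, 9, 9), 0, 9, 1)
  bump$values[5, 5] <- 2
  expect_gt(bpi(bump)$values[5, 5], 0)

  set.seed(13)
  g <- grid_create(matrix(rnorm(49), 7, 7), 0, 7, 1)
  p <- terrain_params(bpi_inner_r = 1, bpi_outer_r = 2)
  b <- bpi(g, p)
  # hand enumeration at every interior cell
  off <- expand.grid(dr = -2:2, dc = -2:2)
  d <- sqrt(off$dr^2 + off$dc^2)
  off <- off[d > 1 & d <= 2, ]
  for (r in 3:5) for (c in 3:5) {
    ann <- mapply(function(dr, dc) g$values[r + dr, c + dc], off$dr, off$dc)
    expect_equal(b$values[r, c], g$values[r, c] - mean(ann), tolerance = 1e-12)
  }
})

test_that("sky view factor has the closed-form value for a single wall", {
  expect_equal(svf(plane_grid(z0 = -2))$values, matrix(1, 9, 9))

  # wall of height 1 one cell north of the target, 4 azimuths, radius 1
  g <- grid_create(matrix(0, 3, 3), 0, 3, 1)
  g$values[1, 2] <- 1
  p <- terrain_params(svf_azimuths = 4, svf_radius = 1)
  expect_equal(svf(g, p)$values[2, 2], 1 - sin(pi / 4) / 4, tolerance = 1e-12)

  # an enclosing pit tends to 0 as the walls steepen
  pit <- grid_create(matrix(50, 9, 9), 0, 9, 1)
  pit$values[5, 5] <- 0
  expect_lt(svf(pit)$values[5, 5], 0.1)
  v <- svf(small_world()$aca15)
  expect_true(all(v$values >= 0 & v$values <= 1, na.rm = TRUE))
})

test_that("attribute layers are translation invariant except depth", {
  set.seed(17)
  g <- grid_create(matrix(rnorm(144, -10, 2), 12, 12), 0, 120, 10)
  g5 <- g; g5$values <- g$values + 5
  p <- terrain_params(svf_radius = 4)
  for (f in list(slope, function(a, b) aspect_components(a, b)$east,
                 function(a, b) curvatures(a, b)$vcu,
                 function(a, b) curvatures(a, b)$hcu, vrm, bpi, svf)) {
    expect_equal(f(g, p)$values, f(g5, p)$values, tolerance = 1e-9)
  }
})

test_that("the derived stack enumerates 9 layers per DEM level", {
  w <- small_world()
  st <- build_dem_set(w$aca15, w$dr30, w$dr100)
  single <- structure(list(levels = st$levels["DR100_100"],
                           key = st$key[st$key$key == "DR100_100", ]),
                      class = "multiscale_stack")
  vs1 <- derive_all(single, terrain_params(svf_radius = 4))
  expect_length(vs1, 9)
  expect_setequal(vs1$key$variable,
                  c("DEPTH", "SLOPE", "EAST", "NORTH", "VCU", "HCU",
                    "VRM", "BPI", "SVF"))
  expect_false(anyDuplicated(names(vs1$layers)) > 0)
  expect_identical(vs1$layers$DR100_100_DEPTH$values,
                   st$levels$DR100_100$values)
})

test_that("source comparison reproduces rank correlations", {
  w <- small_world()
  st <- build_dem_set(w$aca15, w$dr30, w$dr100)
  p <- terrain_params(svf_radius = 4)
  sub <- structure(list(levels = st$levels["ACA_30"],
                        key = st$key[st$key$key == "ACA_30", ]),
                   class = "multiscale_stack")
  va <- derive_all(sub, p)
  rep1 <- compare_sources(va, va, n_points = 400, seed = 2)
  expect_true(all(abs(rep1$r_s[!is.na(rep1$r_s)] - 1) < 1e-12))
  expect_true(all(rep1$flagged[!is.na(rep1$r_s)]))

  # monotone transform leaves Spearman at 1
  vb <- va
  vb$layers <- lapply(va$layers, function(g) { g$values <- exp(g$values); g })
  rep2 <- compare_sources(va, vb, n_points = 400, seed = 2)
  expect_true(all(abs(rep2$r_s[!is.na(rep2$r_s)] - 1) < 1e-12))

  # 20 fixed pairs against a direct rank-correlation oracle
  set.seed(31)
  x <- rnorm(20); y <- x + rnorm(20)
  g1 <- structure(list(layers = list(A_1_DEPTH = grid_create(matrix(x, 4, 5), 0, 4, 1)),
                       key = data.frame(source = "A", resolution_m = 1,
                                        variable = "DEPTH", key = "A_1_DEPTH")),
                  class = "variable_stack")
  g2 <- structure(list(layers = list(B_1_DEPTH = grid_create(matrix(y, 4, 5), 0, 4, 1)),
                       key = data.frame(source = "B", resolution_m = 1,
                                        variable = "DEPTH", key = "B_1_DEPTH")),
                  class = "variable_stack")
  rep3 <- compare_sources(g1, g2, n_points = 20, seed = 1)
  rx <- rank(x); ry <- rank(y)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(rep3$r_s, oracle, tolerance = 1e-12)
})
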