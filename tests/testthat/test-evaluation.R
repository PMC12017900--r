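# AUC/BIC metrics, cross-validation bookkeeping, jackknife, response curves,
# model grouping and habitat overlap.

test_that("AUC equals the exhaustive pair count and its symmetries", {
  expect_equal(auc(c(3, 4, 5), c(0, 1, 2)), 1)
  expect_equal(auc(rep(1, 5), rep(1, 8)), 0.5)

  set.seed(23)
  pos <- rnorm(7); neg <- rnorm(9)
  wins <- 0
  for (p in pos) for (n in neg)
    wins <- wins + (p > n) + 0.5 * (p == n)
  expect_equal(auc(pos, neg), wins / 63)

  # with ties present the pair count still matches exactly
  posT <- c(1, 2, 2, 3); negT <- c(2, 2, 0)
  winsT <- 0
  for (p in posT) for (n in negT) winsT <- winsT + (p > n) + 0.5 * (p == n)
  expect_equal(auc(posT, negT), winsT / 12)

  expect_equal(auc(pos, neg) + auc(neg, pos), 1)
  expect_equal(auc(exp(pos), exp(neg)), auc(pos, neg)) # monotone invariance
  expect_error(auc(numeric(0), neg), "non-empty")
})

test_that("BIC matches the closed form and counts nonzero terms only", {
  d <- data.frame(x = runif(100))
  y <- rep(c(0L, 1L), 50)
  spec <- feature_spec("L", "x")
  fit <- fit_maxent(expand_features(d, spec), y, rm = 1e8, spec = spec)
  expect_true(all(fit$coefficients == 0))
  expect_equal(fit$intercept, 0) # balanced labels
  expect_equal(bic(fit, d, y), 1 * log(100) - 2 * 100 * log(0.5))

  # an extra always-zero feature leaves BIC unchanged
  d2 <- data.frame(x = d$x, z = runif(100))
  spec2 <- feature_spec("L", c("x", "z"))
  fit2 <- fit_maxent(expand_features(d2, spec2), y, rm = 1e8, spec = spec2)
  expect_equal(bic(fit2, d2, y), bic(fit, d, y))

  # per-row fit quality fixed -> BIC grows with n (duplicated data)
  d4 <- rbind(d2, d2); y4 <- c(y, y)
  fit4 <- fit_maxent(expand_features(d4, spec2), y4, rm = 1e8, spec = spec2)
  b1 <- bic(fit2, d2, y); b4 <- bic(fit4, d4, y4)
  expect_gt(b4, b1)
  expect_equal(b4 - log(200), 2 * (b1 - log(100)), tolerance = 1e-9)
})

test_that("leave-one-reef-out bookkeeping produces R x I x 3 records", {
  tab <- toy_signal_table(n_pos = 90, n_neg = 240, seed = 11)
  spec <- feature_spec("L", c("sig", "noise1", "noise2"))
  cv <- loro_cv(tab, spec, rm = 2, n_iterations = 2, seed = 4)
  expect_equal(nrow(cv), 3 * 2 * 3)
  expect_setequal(unique(cv$reef_id), c("r1", "r2", "r3"))
  expect_true(all(table(cv$reef_id, cv$iteration) == 3))
  expect_true(all(cv$auc_test >= 0 & cv$auc_test <= 1))
  # train and test never share rows: n_train + n_test == total + extra splits
  n_bg <- sum(tab$label == 0)
  expect_true(all(cv$n_test >= floor(0.25 * n_bg)))
  expect_error(loro_cv(tab[tab$reef_id == "r1" | tab$label == 0, ], spec, 2),
               "2 reefs")
})

test_that("an informative table beats its permuted-label baseline", {
  tab <- toy_signal_table(n_pos = 120, n_neg = 360, seed = 12, beta = 4)
  spec <- feature_spec("LQ", c("sig", "noise1", "noise2"))
  cv <- loro_cv(tab, spec, rm = 2, n_iterations = 1, seed = 5)
  perm <- tab
  set.seed(13)
  perm$sig <- sample(perm$sig) # break the signal, keep the marginals
  cvp <- loro_cv(perm, spec, rm = 2, n_iterations = 1, seed = 5)
  expect_gt(mean(cv$auc_test), mean(cvp$auc_test) + 0.2)
})

test_that("jackknife separates signal from noise and shares the total AUC", {
  tab <- toy_signal_table(n_pos = 150, n_neg = 450, n_noise = 3, seed = 14,
                          beta = 5)
  spec <- feature_spec("LQ", c("sig", "noise1", "noise2", "noise3"))
  jk <- jackknife(tab, spec, rm = 2, seed = 3)
  expect_equal(length(unique(jk$auc_total)), 1)
  expect_gt(jk$auc_only[jk$variable == "sig"],
            max(jk$auc_only[jk$variable != "sig"]))

  # duplicating the informative variable makes it redundant
  tab$sig2 <- tab$sig
  spec2 <- feature_spec("LQ", c("sig", "sig2", "noise1"))
  jk2 <- jackknife(tab, spec2, rm = 2, seed = 3)
  rowd <- jk2[jk2$variable == "sig", ]
  expect_lt(abs(rowd$auc_without - rowd$auc_total), 0.05)

  expect_error(jackknife(tab, feature_spec("L", "sig"), 2), "at least 2")
})

test_that("pure-noise jackknife finds no top variables across seeds", {
  aucs <- NULL
  for (s in 1:20) {
    set.seed(400 + s)
    n <- 3200
    tab <- data.frame(point_id = as.character(seq_len(n)),
                      reef_id = "r1",
                      label = rep(c(1L, 0L), c(800, 2400)),
                      v1 = runif(n), v2 = runif(n), v3 = runif(n))
    class(tab) <- c("feature_table", "data.frame")
    jk <- jackknife(tab, feature_spec("LQ", c("v1", "v2", "v3")), rm = 2,
                    seed = s, n_replicates = 1)
    aucs <- c(aucs, jk$auc_only)
  }
  expect_true(all(abs(aucs - 0.5) <= 0.1))
  expect_true(all(aucs <= 0.7)) # never flagged top
})

test_that("response curves reflect the fitted shape", {
  set.seed(15)
  n <- 600
  x <- runif(n)
  y <- rbinom(n, 1, plogis(4 * x - 2))
  tab <- data.frame(point_id = as.character(1:n), reef_id = "r1",
                    label = y, x = x, z = runif(n))
  class(tab) <- c("feature_table", "data.frame")
  spec <- feature_spec("L", c("x", "z"))
  fit <- fit_maxent(expand_features(tab, spec), y, rm = 1, spec = spec)
  rc <- response_curve(fit, tab, "x", "marginal")
  expect_equal(nrow(rc), 100)
  expect_true(all(rc$probability >= 0 & rc$probability <= 1))
  if (fit$coefficients[["x"]] > 0) expect_true(all(diff(rc$probability) >= 0))

  # unimodal quadratic response -> interior maximum on the individual curve
  set.seed(16)
  xq <- runif(n, -1, 1)
  yq <- rbinom(n, 1, plogis(1 - 5 * xq^2))
  tq <- data.frame(point_id = as.character(1:n), reef_id = "r1", label = yq,
                   x = xq, z = runif(n))
  class(tq) <- c("feature_table", "data.frame")
  specq <- feature_spec("LQ", c("x", "z"))
  fitq <- fit_maxent(expand_features(tq, specq), yq, rm = 1, spec = specq)
  rcq <- response_curve(fitq, tq, "x", "individual")
  peak <- which.max(rcq$probability)
  expect_gt(peak, 10)
  expect_lt(peak, 90)

  expect_error(response_curve(fit, tab, "missing_var"), "not in model")
})

# hand midrank Kruskal-Wallis H for a 3-group table
kw_oracle <- function(value, group) {
  r <- rank(value)
  N <- length(value)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, group, function(g) length(g) * (mean(g) - (N + 1) / 2)^2))
  ties <- table(r)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

test_that("model grouping matches the midrank formula and letters behave", {
  v0 <- rep(c(1, 2, 3), 6)
  g0 <- rep(c("a", "b", "c"), each = 6)
  res0 <- compare_model_groups(v0, g0)
  expect_equal(res0$kw_h, 0)
  expect_true(all(res0$dunn$p_holm >= res0$dunn$p - 1e-12))
  expect_length(unique(res0$letters), 1)

  set.seed(18)
  v1 <- c(rnorm(10), rnorm(10), rnorm(10) + 30) # one far-shifted group
  g1 <- rep(c("a", "b", "c"), each = 10)
  res1 <- compare_model_groups(v1, g1)
  expect_false(res1$letters[["c"]] %in% res1$letters[c("a", "b")])
  expect_true(grepl(substr(res1$letters[["a"]], 1, 1), res1$letters[["b"]]))

  v2 <- c(5, 7, 8, 1, 2, 2, 9, 9, 4)
  g2 <- rep(c("x", "y", "z"), each = 3)
  res2 <- compare_model_groups(v2, g2)
  expect_equal(res2$kw_h, kw_oracle(v2, g2), tolerance = 1e-12)
  expect_equal(res2$kw_df, 2)
  expect_error(compare_model_groups(1:3, c("a", "b", "c")), "n >= 2")
})

test_that("habitat overlap bins probabilities and aggregates across reefs", {
  mk <- function(m) grid_create(m, 0, 4, 1)
  pred <- mk(matrix(runif(16), 4, 4))
  hab <- mk(matrix(1, 4, 4))
  ov <- habitat_overlap(pred, hab, suitable_classes = 1)
  expect_true(all(ov$mean_fraction[ov$n_cells > 0] == 1))

  pred9 <- mk(matrix(0.9, 4, 4))
  hab30 <- mk(matrix(c(rep(1, 5), rep(2, 11)), 4, 4)) # ~30% suitable
  ov2 <- habitat_overlap(pred9, hab30, suitable_classes = 1)
  expect_equal(ov2$n_cells, c(0, 0, 0, 16))
  expect_equal(ov2$mean_fraction[4], 5 / 16)

  # prediction equal to suitability + noise -> non-decreasing fractions
  set.seed(19)
  suit <- matrix(rbinom(400, 1, 0.5), 20, 20)
  noisy <- pmin(pmax(suit * 0.7 + runif(400, 0, 0.3), 0), 1)
  ov3 <- habitat_overlap(mk2 <- grid_create(noisy, 0, 20, 1),
                         grid_create(suit, 0, 20, 1), suitable_classes = 1)
  fr <- ov3$mean_fraction[ov3$n_cells > 0]
  expect_true(all(diff(fr) >= 0))

  # per-reef SE path
  ovl <- habitat_overlap(list(a = pred9, b = pred9),
                         list(a = hab30, b = mk(matrix(1, 4, 4))),
                         suitable_classes = 1)
  expect_equal(ovl$n_reefs[4], 2)
  expect_equal(ovl$mean_fraction[4], mean(c(5 / 16, 1)))
  expect_error(habitat_overlap(pred9, mk(matrix(1, 3, 3)), 1), "misaligned")
})
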