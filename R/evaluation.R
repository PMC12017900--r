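# Model evaluation: AUC, BIC, leave-one-reef-out CV, jackknife importance,
# response curves, non-parametric model grouping, habitat overlap.

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Fraction of (presence, background) score pairs where the presence scores
#' higher, counting ties as 1/2; computed via midranks, identical to the
#' exhaustive pair count.
#'
#' @param pos_scores scores at presences.
#' @param neg_scores scores at background points.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(pos_scores, neg_scores) {
  np <- length(pos_scores); nn <- length(neg_scores)
  if (np == 0 || nn == 0) stop("both score sets must be non-empty")
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' BIC of a fitted presence-background model
#'
#' `BIC = k ln(n) - 2 lnL` with `k` = number of nonzero coefficients plus the
#' intercept, `n` the number of rows, and `lnL` the unpenalized binomial
#' log-likelihood at the fitted coefficients (probabilities clipped to
#' `[1e-12, 1 - 1e-12]`).
#'
#' @param model a `maxent_model`.
#' @param newdata data.frame holding the model's base columns.
#' @param y 0/1 labels aligned with `newdata`.
#' @return BIC (numeric scalar).
#' @export
bic <- function(model, newdata, y) {
  stopifnot(inherits(model, "maxent_model"))
  n <- length(y)
  if (n == 0) stop("empty data")
  p <- plogis(model_linear_predictor(model, newdata))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  ll <- sum(y * log(p) + (1 - y) * log(1 - p))
  k <- sum(model$coefficients != 0) + 1
  k * log(n) - 2 * ll
}

split_75_25 <- function(idx) {
  n <- length(idx)
  n_train <- round(0.75 * n)
  tr <- sample(idx, n_train)
  list(train = tr, test = setdiff(idx, tr))
}

#' Leave-one-reef-out cross-validation
#'
#' For each iteration and each reef with presences: training data are the
#' presences of every other reef plus a random 75% of the background; test
#' data are the held-out reef's presences plus the remaining 25% background.
#' The random background split is drawn in triplicate per fold, giving
#' `reefs x iterations x 3` evaluation records. Test AUC is computed on the
#' test set; BIC on the training set.
#'
#' @param table a `feature_table` from [build_feature_table()].
#' @param spec a [feature_spec()].
#' @param rm regularisation multiplier.
#' @param n_iterations iterations re-randomising the background splits
#'   (default 10).
#' @param seed RNG seed.
#' @return data.frame of evaluation records: `fc`, `rm`, `iteration`,
#'   `reef_id`, `replicate`, `auc_test`, `bic`, `n_train`, `n_test`.
#' @export
loro_cv <- function(table, spec, rm, n_iterations = 10, seed = 1) {
  stopifnot(inherits(spec, "feature_spec"))
  pres <- which(table$label == 1L)
  bg <- which(table$label == 0L)
  reefs <- sort(unique(table$reef_id[pres]))
  if (length(reefs) < 2) stop("need presences from at least 2 reefs")
  set.seed(seed)
  rows <- list()
  for (it in seq_len(n_iterations)) {
    for (rf in reefs) {
      hold <- pres[table$reef_id[pres] == rf]
      keep <- setdiff(pres, hold)
      if (length(hold) == 0) { message("reef ", rf, " has no presences; skipped"); next }
      for (rep_i in 1:3) {
        sp <- split_75_25(bg)
        tr <- c(keep, sp$train)
        te <- c(hold, sp$test)
        Xtr <- expand_features(table[tr, , drop = FALSE], spec)
        fit <- fit_maxent(Xtr, table$label[tr], rm, spec = spec)
        scores <- predict(fit, table[te, , drop = FALSE])
        a <- auc(scores[table$label[te] == 1L], scores[table$label[te] == 0L])
        b <- bic(fit, table[tr, , drop = FALSE], table$label[tr])
        rows[[length(rows) + 1]] <- data.frame(
          fc = spec$fc, rm = rm, iteration = it, reef_id = rf,
          replicate = rep_i, auc_test = a, bic = b,
          n_train = length(tr), n_test = length(te),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Tune feature class and regularisation multiplier
#'
#' Runs [loro_cv()] for every FC-RM candidate and selects the winner by
#' [select_parameters()] rank sum over mean test AUC and mean BIC.
#'
#' @inheritParams loro_cv
#' @param base_columns predictor columns used by every candidate.
#' @param fc_grid feature classes to try (default all four).
#' @param rm_grid regularisation multipliers to try (default 1, 2, 5, 10).
#' @return list with `selection` (a `selection_table`) and `records` (all
#'   evaluation records).
#' @export
tune_maxent <- function(table, base_columns, fc_grid = fc_levels,
                        rm_grid = c(1, 2, 5, 10), n_iterations = 1, seed = 1) {
  records <- list(); summ <- list()
  for (fc in fc_grid) for (rm in rm_grid) {
    spec <- feature_spec(fc, base_columns)
    rec <- loro_cv(table, spec, rm, n_iterations = n_iterations,
                   seed = seed + 1000L * match(fc, fc_levels) + round(rm))
    records[[paste(fc, rm)]] <- rec
    summ[[paste(fc, rm)]] <- data.frame(
      fc = fc, rm = rm, mean_auc_test = mean(rec$auc_test),
      mean_bic = mean(rec$bic), stringsAsFactors = FALSE)
  }
  list(selection = select_parameters(do.call(rbind, summ)),
       records = do.call(rbind, records))
}

#' Jackknife variable importance
#'
#' For each base variable `v`: a model with only `v` (`auc_only`), a model
#' with every variable except `v` (`auc_without`), and the full model
#' (`auc_total`, shared across rows). AUCs are computed on seeded 75/25
#' holdouts (split within presences and background separately) and averaged
#' over `n_replicates` re-splits to stabilise the estimate. `top_flag` marks
#' variables with `auc_only > 0.7` ("acceptable" discrimination when used
#' alone).
#'
#' @inheritParams loro_cv
#' @param n_replicates number of holdout re-splits averaged per AUC
#'   (default 3).
#' @return data.frame: `variable`, `auc_only`, `auc_without`, `auc_total`,
#'   `top_flag`.
#' @export
jackknife <- function(table, spec, rm, seed = 1, n_replicates = 3) {
  stopifnot(inherits(spec, "feature_spec"))
  vars <- spec$base_columns
  if (length(vars) < 2) stop("jackknife needs at least 2 variables")
  set.seed(seed)
  acc <- matrix(0, nrow = length(vars), ncol = 2,
                dimnames = list(vars, c("only", "without")))
  total <- 0
  for (r in seq_len(n_replicates)) {
    sp_p <- split_75_25(which(table$label == 1L))
    sp_b <- split_75_25(which(table$label == 0L))
    tr <- c(sp_p$train, sp_b$train); te <- c(sp_p$test, sp_b$test)
    eval_auc <- function(cols) {
      sub <- feature_spec(spec$fc, cols)
      X <- expand_features(table[tr, , drop = FALSE], sub)
      fit <- fit_maxent(X, table$label[tr], rm, spec = sub)
      s <- predict(fit, table[te, , drop = FALSE])
      auc(s[table$label[te] == 1L], s[table$label[te] == 0L])
    }
    total <- total + eval_auc(vars)
    for (v in vars) {
      acc[v, "only"] <- acc[v, "only"] + eval_auc(v)
      acc[v, "without"] <- acc[v, "without"] + eval_auc(setdiff(vars, v))
    }
  }
  out <- data.frame(variable = vars,
                    auc_only = acc[, "only"] / n_replicates,
                    auc_without = acc[, "without"] / n_replicates,
                    auc_total = total / n_replicates,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$top_flag <- out$auc_only > 0.7
  out
}

#' Response curve of one variable
#'
#' `kind = "marginal"`: predictions along the variable's training range with
#' every other variable held at its training mean (the variable's additive
#' effect given the full model). `kind = "individual"`: predictions from a
#' model refit on that variable alone over the same grid.
#'
#' @param model a fitted `maxent_model` (used for `"marginal"` and to supply
#'   fc/rm for the `"individual"` refit).
#' @param table the training `feature_table`.
#' @param variable_key one of the model's base columns.
#' @param kind `"marginal"` or `"individual"`.
#' @param n_grid number of evaluation points (default 100).
#' @return data.frame with `value` and `probability` columns; attribute
#'   `kind`.
#' @export
response_curve <- function(model, table, variable_key,
                           kind = c("marginal", "individual"), n_grid = 100) {
  kind <- match.arg(kind)
  vars <- model$spec$base_columns
  if (!variable_key %in% vars) stop("variable not in model: ", variable_key)
  r <- range(table[[variable_key]])
  grid <- seq(r[1], r[2], length.out = n_grid)
  if (kind == "marginal") {
    nd <- as.data.frame(lapply(setNames(vars, vars), function(v)
      rep(mean(table[[v]]), n_grid)))
    nd[[variable_key]] <- grid
    prob <- predict(model, nd)
  } else {
    sub <- feature_spec(model$spec$fc, variable_key)
    X <- expand_features(table, sub)
    fit <- fit_maxent(X, table$label, model$rm, spec = sub)
    nd <- setNames(data.frame(grid), variable_key)
    prob <- predict(fit, nd)
  }
  out <- data.frame(value = grid, probability = prob)
  attr(out, "kind") <- kind
  out
}

# -- non-parametric model grouping ------------------------------------------

# Dunn's pairwise z tests on midranks with tie correction
dunn_pairs <- function(value, group) {
  g <- factor(group)
  N <- length(value)
  r <- rank(value, ties.method = "average")
  tie_tab <- table(r)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  mean_r <- tapply(r, g, mean)
  n_g <- tapply(r, g, length)
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  z <- p <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n_g[[a]] + 1 / n_g[[b]]))
    z[i] <- if (se > 0) (mean_r[[a]] - mean_r[[b]]) / se else 0
    p[i] <- 2 * pnorm(-abs(z[i]))
  }
  data.frame(group_a = pairs[1, ], group_b = pairs[2, ], z = z, p = p,
             p_holm = p.adjust(p, method = "holm"), stringsAsFactors = FALSE)
}

# greedy insert-absorb compact letter display
compact_letters <- function(groups, sig_pairs) {
  sets <- list(groups)
  for (i in seq_len(nrow(sig_pairs))) {
    a <- sig_pairs$group_a[i]; b <- sig_pairs$group_b[i]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else new_sets <- c(new_sets, list(s))
    }
    # absorb sets contained in another
    keep <- rep(TRUE, length(new_sets))
    for (j in seq_along(new_sets)) for (k in seq_along(new_sets)) {
      if (j != k && keep[j] && keep[k] &&
          all(new_sets[[j]] %in% new_sets[[k]]) &&
          !(all(new_sets[[k]] %in% new_sets[[j]]) && j < k)) keep[j] <- FALSE
    }
    sets <- unique(new_sets[keep])
    sets <- sets[vapply(sets, length, 0L) > 0]
  }
  letters_out <- setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets)) {
    for (gname in sets[[i]])
      letters_out[gname] <- paste0(letters_out[gname], letters[i])
  }
  letters_out
}

#' Kruskal-Wallis grouping with Dunn post hoc tests
#'
#' Compares a metric (e.g. test AUC or BIC) across model groups with a
#' Kruskal-Wallis one-way analysis of variance; all pairwise Dunn z tests
#' with Holm correction; and a compact letter display where groups sharing a
#' letter are statistically indistinguishable at `alpha`.
#'
#' @param value numeric metric values.
#' @param group group labels (e.g. "source_resolution"), one per value.
#' @param alpha significance level for the letter display (default 0.05).
#' @return a `comparison_result` list: `kw_h`, `kw_df`, `kw_p`, `dunn`
#'   (pairwise table), `letters` (named per group).
#' @export
compare_model_groups <- function(value, group, alpha = 0.05) {
  g <- factor(group)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(tapply(value, g, length) < 2)) stop("every group needs n >= 2")
  if (length(unique(value)) == 1) {
    kw_h <- 0; kw_df <- nlevels(g) - 1; kw_p <- 1
  } else {
    kw <- kruskal.test(value, g)
    kw_h <- unname(kw$statistic); kw_df <- unname(kw$parameter); kw_p <- kw$p.value
  }
  dn <- dunn_pairs(value, g)
  sig <- dn[dn$p_holm < alpha, , drop = FALSE]
  structure(list(kw_h = kw_h, kw_df = kw_df, kw_p = kw_p, dunn = dn,
                 letters = compact_letters(levels(g), sig)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> Kruskal-Wallis H(%d) = %.2f, p = %.3g\n",
              x$kw_df, x$kw_h, x$kw_p))
  cat("  letters:", paste(names(x$letters), x$letters, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Habitat overlap of predicted presence probability
#'
#' Bins predicted probabilities into 0-25 / 25-50 / 50-75 / 75-100 percent
#' (intervals closed on the right; 0 goes to the first bin) and reports, per
#' bin, the fraction of cells whose habitat class is in `suitable_classes`,
#' with mean and standard error across reefs.
#'
#' @param pred probability grid or named list of per-reef probability grids.
#' @param habitat class grid (integer/character codes) or matching list.
#' @param suitable_classes habitat codes counted as suitable.
#' @param breaks bin edges in percent (default `c(0, 25, 50, 75, 100)`).
#' @return data.frame: `bin`, `mean_fraction`, `se_fraction`, `n_reefs`,
#'   `n_cells`.
#' @export
habitat_overlap <- function(pred, habitat, suitable_classes,
                            breaks = c(0, 25, 50, 75, 100)) {
  if (length(suitable_classes) == 0) stop("suitable_classes must be non-empty")
  if (is_grid(pred)) pred <- list(reef = pred)
  if (is_grid(habitat)) habitat <- list(reef = habitat)
  if (length(pred) != length(habitat)) stop("pred and habitat lists differ in length")
  nb <- length(breaks) - 1
  labs <- paste0(breaks[-length(breaks)], "-", breaks[-1], "%")
  frac <- matrix(NA_real_, nrow = length(pred), ncol = nb)
  counts <- matrix(0, nrow = length(pred), ncol = nb)
  for (i in seq_along(pred)) {
    pg <- pred[[i]]; hg <- habitat[[i]]
    if (!grids_aligned(pg, hg)) stop("prediction and habitat grids misaligned")
    p <- as.vector(pg$values) * 100
    h <- as.vector(hg$values)
    ok <- !is.na(p) & !is.na(h)
    b <- cut(p[ok], breaks = breaks, include.lowest = TRUE, right = TRUE,
             labels = labs)
    suit <- h[ok] %in% suitable_classes
    for (j in seq_len(nb)) {
      sel <- b == labs[j]
      counts[i, j] <- sum(sel)
      if (any(sel)) frac[i, j] <- mean(suit[sel])
    }
  }
  mean_f <- apply(frac, 2, function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  se_f <- apply(frac, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else sd(v) / sqrt(length(v))
  })
  data.frame(bin = labs, mean_fraction = mean_f, se_fraction = se_f,
             n_reefs = apply(!is.na(frac), 2, sum),
             n_cells = colSums(counts), stringsAsFactors = FALSE)
}
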