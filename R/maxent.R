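# MaxEnt-style presence-background engine: feature-class expansion,
# per-feature regularisation scaled by a regularisation multiplier, fitting
# via the penalized-logistic (IWLR) equivalence, and raster prediction.

fc_levels <- c("L", "LQ", "LP", "LQP")

#' Feature-class specification
#'
#' The feature classes mirror MaxEnt's untransformed families: linear (`L`),
#' linear + quadratic (`LQ`), linear + pairwise products (`LP`), and all
#' three (`LQP`). With `p` base columns the expansions have `p`, `2p`,
#' `p + p(p-1)/2` and `2p + p(p-1)/2` columns respectively.
#'
#' @param fc one of `"L"`, `"LQ"`, `"LP"`, `"LQP"`.
#' @param base_columns character vector of predictor column names.
#' @return an object of class `feature_spec`.
#' @export
feature_spec <- function(fc, base_columns) {
  fc <- match.arg(fc, fc_levels)
  base_columns <- as.character(base_columns)
  if (length(base_columns) < 1) stop("at least one base column required")
  structure(list(fc = fc, base_columns = base_columns), class = "feature_spec")
}

# min-max ranges per base column; constant columns get range [v, v]
fit_scaling <- function(data, base_columns) {
  lapply(setNames(base_columns, base_columns), function(cn) {
    v <- data[[cn]]
    if (is.null(v)) stop("base column missing from data: ", cn)
    range(v, na.rm = TRUE)
  })
}

#' Expand predictors into a feature-class design matrix
#'
#' Base columns are min-max scaled to `[0, 1]` (ranges learned from the
#' training table unless `scaling` is supplied), then expanded per the
#' feature class: quadratic features are squared scaled values (named
#' `<col>^2`), product features pairwise products (named `<a>:<b>`). Constant
#' columns scale to 0 and are flagged zero-variance downstream.
#'
#' @param table a `feature_table` or data.frame holding the base columns.
#' @param spec a [feature_spec()].
#' @param scaling optional list of per-column `c(min, max)` ranges from a
#'   previous expansion (required to reproduce training scaling at predict
#'   time).
#' @return numeric design matrix with named columns; attributes `classes`
#'   (feature class per column: linear/quadratic/product) and `scaling`.
#' @export
expand_features <- function(table, spec, scaling = NULL) {
  stopifnot(inherits(spec, "feature_spec"))
  if (is.null(scaling)) scaling <- fit_scaling(table, spec$base_columns)
  p <- length(spec$base_columns)
  S <- sapply(spec$base_columns, function(cn) {
    r <- scaling[[cn]]
    v <- table[[cn]]
    if (is.null(v)) stop("base column missing from data: ", cn)
    if (!all(is.finite(v))) stop("non-finite values in base column ", cn)
    if (diff(r) == 0) rep(0, length(v)) else (v - r[1]) / (r[2] - r[1])
  })
  S <- matrix(S, ncol = p, dimnames = list(NULL, spec$base_columns))
  X <- S
  classes <- rep("linear", p)
  if (spec$fc %in% c("LQ", "LQP")) {
    Q <- S^2
    colnames(Q) <- paste0(spec$base_columns, "^2")
    X <- cbind(X, Q)
    classes <- c(classes, rep("quadratic", p))
  }
  if (spec$fc %in% c("LP", "LQP") && p >= 2) {
    pr <- utils::combn(p, 2)
    P <- S[, pr[1, ], drop = FALSE] * S[, pr[2, ], drop = FALSE]
    colnames(P) <- paste0(spec$base_columns[pr[1, ]], ":",
                          spec$base_columns[pr[2, ]])
    X <- cbind(X, P)
    classes <- c(classes, rep("product", ncol(P)))
  }
  attr(X, "classes") <- classes
  attr(X, "scaling") <- scaling
  X
}

# Published MaxEnt default regularisation schedule: per-class base values
# interpolated (clamped) over the presence count m. The per-feature penalty is
# rm * interp(class, m) * sd_j / sqrt(m).
maxent_reg_schedule <- list(
  linear = list(m = c(10, 30, 100), v = c(1.0, 0.2, 0.05)),
  quadratic = list(m = c(0, 10, 17, 30, 100), v = c(1.30, 0.8, 0.5, 0.25, 0.05)),
  product = list(m = c(0, 10, 17, 30, 100), v = c(2.6, 1.6, 0.9, 0.55, 0.05)))

reg_value <- function(class, m) {
  tb <- maxent_reg_schedule[[class]]
  if (is.null(tb)) stop("unknown feature class: ", class)
  approx(tb$m, tb$v, xout = m, rule = 2)$y
}

#' Fit a MaxEnt-style presence-background model
#'
#' Uses the infinitely-weighted logistic-regression equivalence: an
#' L1-penalized logistic regression of presence (1) vs background (0) on the
#' expanded features, with per-feature penalty
#' `lambda_j = rm * c(class_j, m) * sd_j / sqrt(m)` where `m` is the presence
#' count, `sd_j` the feature's sample standard deviation, and `c` the
#' published MaxEnt default schedule per feature class interpolated over `m`.
#' Zero-variance features are always excluded. The solver is coordinate
#' descent (glmnet) along a decreasing penalty path under the reference
#' implementation's 1:100 presence:background row weighting, taking the
#' coefficients at the target penalty.
#'
#' @param X design matrix from [expand_features()].
#' @param y 0/1 labels (1 = presence), both classes present.
#' @param rm regularisation multiplier, `> 0`.
#' @param spec the [feature_spec()] used to build `X` (stored for prediction).
#' @param seed optional seed recorded in the model metadata.
#' @return a `maxent_model`: coefficients (sparse; zeros retained), intercept,
#'   feature spec, scaling, penalties and training metadata.
#' @export
fit_maxent <- function(X, y, rm, spec = NULL, seed = NA_integer_) {
  if (rm <= 0) stop("`rm` must be > 0")
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L)) || length(unique(y)) < 2)
    stop("`y` must contain both presences (1) and background (0)")
  classes <- attr(X, "classes")
  if (is.null(classes)) stop("`X` must come from expand_features()")
  m <- sum(y == 1L)
  n <- nrow(X)
  sds <- apply(X, 2, sd)
  lam <- rm * vapply(classes, reg_value, 0, m = m) * sds / sqrt(m)
  keep <- sds > 0
  beta <- setNames(rep(0, ncol(X)), colnames(X))
  if (any(keep)) {
    Xk <- X[, keep, drop = FALSE]
    a <- lam[keep]
    one_col <- ncol(Xk) == 1
    if (one_col) { # glmnet needs >= 2 columns; a zero column stays at 0
      Xk <- cbind(Xk, `.dummy` = 0)
      a <- c(a, mean(a))
    }
    # infinitely-weighted logistic formulation a la the reference MaxEnt
    # implementation: background rows carry weight 100, and the glmnet
    # penalty path ends at mean(reg) * m / sum(w), which makes the
    # effective per-feature penalty m * a_j on the weighted sum-likelihood
    w <- ifelse(y == 1L, 1, 100)
    lambda_target <- sum(a) / length(a) * m / sum(w)
    fit <- glmnet::glmnet(
      Xk, y, family = "binomial", weights = w, standardize = FALSE,
      intercept = TRUE, penalty.factor = a,
      lambda = lambda_target * 10^seq(4, 0, length.out = 50),
      thresh = 1e-9, maxit = 1e5)
    cf <- as.numeric(coef(fit, s = lambda_target, exact = FALSE))
    bk <- cf[-1]
    if (one_col) bk <- bk[1]
    beta[keep] <- bk
    # the IWLR intercept is not identifiable for presence-background data;
    # recalibrate it by unweighted ML with the penalized slopes as offset so
    # that an all-zero model predicts the observed prevalence
    eta0 <- drop(X %*% beta)
    intercept <- qlogis(mean(y)) - mean(eta0)
    for (it in 1:100) {
      p <- plogis(intercept + eta0)
      step <- sum(y - p) / max(sum(p * (1 - p)), 1e-12)
      step <- max(min(step, 2), -2) # damped Newton; concave objective
      intercept <- intercept + step
      if (abs(step) < 1e-12) break
    }
  } else {
    intercept <- qlogis(mean(y))
  }
  structure(list(
    spec = spec, rm = rm, coefficients = beta, intercept = intercept,
    scaling = attr(X, "scaling"), classes = classes, penalties = lam,
    zero_variance = names(beta)[!keep],
    meta = list(n_presence = m, n_background = n - m, seed = seed,
                output_transform = "logistic")),
    class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf("<maxent_model> fc = %s, rm = %g; %d/%d nonzero features; n = %d presence / %d background\n",
              if (is.null(x$spec)) "?" else x$spec$fc, x$rm, nz,
              length(x$coefficients), x$meta$n_presence, x$meta$n_background))
  invisible(x)
}

model_linear_predictor <- function(model, newdata) {
  X <- expand_features(newdata, model$spec, scaling = model$scaling)
  drop(X %*% model$coefficients) + model$intercept
}

#' Predict occurrence probability
#'
#' Logistic transform of the fitted linear predictor. `newdata` may be a
#' data.frame holding the model's base columns (returns a vector) or a
#' `variable_stack` whose layer keys include them (returns a probability
#' grid; cells lacking any required layer value are nodata).
#'
#' @param object a `maxent_model`.
#' @param newdata data.frame or `variable_stack`.
#' @param ... unused.
#' @return numeric vector or [grid_create()] grid of probabilities in `[0, 1]`.
#' @export
predict.maxent_model <- function(object, newdata, ...) {
  if (is.null(object$spec)) stop("model carries no feature_spec; refit with `spec`")
  if (inherits(newdata, "variable_stack")) {
    keys <- object$spec$base_columns
    miss <- setdiff(keys, names(newdata$layers))
    if (length(miss) > 0) stop("stack is missing model feature(s): ",
                               paste(miss, collapse = ", "))
    # predict on the finest layer's lattice; coarser layers are sampled at
    # its cell centres (nearest cell), as in point extraction
    ref <- newdata$layers[[keys[which.min(vapply(newdata$layers[keys],
                                                 function(g) g$pixel_size, 0))]]]
    cc <- grid_centres(ref)
    xy <- expand.grid(y = cc$y, x = cc$x) # column-major over ref$values
    vals <- sapply(keys, function(k) {
      g <- newdata$layers[[k]]
      if (grids_aligned(g, ref)) as.vector(g$values)
      else grid_extract(g, xy$x, xy$y)
    })
    vals <- matrix(vals, ncol = length(keys), dimnames = list(NULL, keys))
    ok <- rowSums(is.na(vals)) == 0
    p <- rep(NA_real_, nrow(vals))
    if (any(ok)) {
      df <- as.data.frame(vals[ok, , drop = FALSE])
      p[ok] <- plogis(model_linear_predictor(object, df))
    }
    return(wrap_grid(ref, matrix(p, nrow(ref$values), ncol(ref$values))))
  }
  miss <- setdiff(object$spec$base_columns, names(newdata))
  if (length(miss) > 0) stop("newdata is missing model feature(s): ",
                             paste(miss, collapse = ", "))
  plogis(model_linear_predictor(object, newdata))
}

#' Select the FC-RM candidate by rank sum
#'
#' Candidates are ranked on mean test AUC (descending: higher is better) and
#' mean BIC (ascending: lower is better) with average ranks on ties; the
#' winner minimises `rank_auc + rank_bic`. Ties are broken by higher mean
#' AUC, then lower RM, then simpler feature class (`L < LQ < LP < LQP`).
#'
#' @param results data.frame with columns `fc`, `rm`, `mean_auc_test`,
#'   `mean_bic` (one row per candidate).
#' @return a `selection_table` data.frame with rank columns and a logical
#'   `winner` column (exactly one `TRUE`).
#' @export
select_parameters <- function(results) {
  need <- c("fc", "rm", "mean_auc_test", "mean_bic")
  if (!all(need %in% names(results)))
    stop("results must have columns: ", paste(need, collapse = ", "))
  if (anyNA(results[need])) stop("candidate metrics contain missing values")
  out <- results
  out$rank_auc <- rank(-out$mean_auc_test, ties.method = "average")
  out$rank_bic <- rank(out$mean_bic, ties.method = "average")
  out$rank_sum <- out$rank_auc + out$rank_bic
  ord <- order(out$rank_sum, -out$mean_auc_test, out$rm,
               match(out$fc, fc_levels))
  out$winner <- FALSE
  out$winner[ord[1]] <- TRUE
  class(out) <- c("selection_table", "data.frame")
  out
}
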