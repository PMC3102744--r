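# Stochastic gradient boosted regression trees for binary occurrence data:
# Bernoulli deviance with logit link, depth-limited trees fit stagewise to
# gradient residuals on a random bag of the data, tree count selected by
# k-fold cross-validated predictive deviance.

#' Fit a boosted regression tree occurrence model
#'
#' Stagewise additive logistic model: each stage fits one regression tree of
#' depth at most `tree_complexity` to the gradient residuals of the current
#' fit on a random `bag_fraction` subsample, and contributes its leaf values
#' shrunk by `learning_rate`. The number of trees is chosen by minimising the
#' k-fold cross-validated predictive deviance, evaluated every
#' `cv_eval_stride` trees (ties go to fewer trees); per-fold held-out AUC at
#' the selected size is reported alongside. Splits are found by exhaustive
#' search over midpoints of sorted unique values with first-best
#' tie-breaking in column order, and leaf values are a single Newton step —
#' all deterministic given the seed.
#'
#' @param formula model formula such as `present ~ .` (binary response).
#' @param data data frame holding the response and numeric predictors.
#' @param x,y alternative interface: numeric predictor matrix and 0/1 vector.
#' @param learning_rate per-tree shrinkage in (0, 0.1]; slow rates
#'   (0.0001--0.001) with thousands of trees suit survey-scale data, larger
#'   rates suit desk-scale experiments.
#' @param tree_complexity maximum tree depth; depth 1 (stumps) fits purely
#'   additive structure, depth d allows d-way interactions.
#' @param bag_fraction fraction of the training data subsampled (without
#'   replacement) at each stage; default 0.50.
#' @param max_trees largest tree count considered.
#' @param cv_folds folds for tree-count selection (default 10); ignored when
#'   `n_trees` is given.
#' @param cv_eval_stride trees between cross-validation deviance
#'   evaluations.
#' @param min_obs_leaf minimum observations per leaf (default 10; stabilises
#'   fits at low prevalence).
#' @param n_trees optional fixed tree count: skips cross-validated selection.
#' @param seed integer seed controlling bagging and fold assignment.
#' @return An object of class `brt` with components including `n_trees`
#'   (selected), `cv` (deviance curve, per-fold AUC) and `importance` inputs;
#'   see [variable_importance()], [partial_dependence()],
#'   [interaction_strength()] and the S3 methods.
#' @seealso [predict.brt()], [summary.brt()], [plot.brt()]
#' @export
brt <- function(formula = NULL, data = NULL, x = NULL, y = NULL,
                learning_rate = 0.01, tree_complexity = 3,
                bag_fraction = 0.5, max_trees = 1000, cv_folds = 10,
                cv_eval_stride = 50, min_obs_leaf = 10, n_trees = NULL,
                seed = 1) {
  if (!is.null(formula)) {
    mf <- stats::model.frame(formula, data)
    y <- stats::model.response(mf)
    x <- as.matrix(mf[, -1, drop = FALSE])
  } else {
    x <- as.matrix(x)
    if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  y <- as.numeric(y)
  if (learning_rate <= 0 || learning_rate > 0.1)
    stop("learning_rate must be in (0, 0.1]")
  if (tree_complexity < 1) stop("tree_complexity must be >= 1")
  if (bag_fraction <= 0 || bag_fraction > 1)
    stop("bag_fraction must be in (0, 1]")
  if (!all(is.finite(x))) stop("non-finite feature values")
  if (anyNA(y) || !all(y %in% c(0, 1))) stop("response must be 0/1")
  if (length(unique(y)) < 2) stop("response has a single class")
  if (is.null(n_trees) && cv_folds < 2) stop("cv_folds must be >= 2")

  schema <- colnames(x)
  n <- nrow(x)
  stride <- as.integer(cv_eval_stride)

  cv <- NULL
  if (is.null(n_trees)) {
    folds <- kfold_split(n, cv_folds, labels = y, seed = seed)
    n_strides <- max_trees %/% stride
    if (n_strides < 2)
      stop("max_trees must allow at least 2 cross-validation evaluations")
    dev_mat <- matrix(NA_real_, cv_folds, n_strides)
    valF_list <- vector("list", cv_folds)
    yval_list <- vector("list", cv_folds)
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      b0 <- stats::qlogis(mean(y[tr]))
      set.seed(seed + 101L * f)
      fit <- cpp_boost(x[tr, , drop = FALSE], y[tr], b0, learning_rate,
                       tree_complexity, min_obs_leaf, bag_fraction,
                       as.integer(n_strides * stride),
                       x[!tr, , drop = FALSE], y[!tr], stride)
      dev_mat[f, ] <- fit$val_dev
      valF_list[[f]] <- fit$val_F
      yval_list[[f]] <- y[!tr]
    }
    w <- as.vector(table(folds))
    mean_dev <- colSums(dev_mat * w) / sum(w)
    curve <- data.frame(trees = seq_len(n_strides) * stride,
                        deviance = mean_dev,
                        se = apply(dev_mat, 2, stats::sd) / sqrt(cv_folds))
    sel <- select_n_trees(curve)
    n_trees <- sel$n_trees
    s_idx <- sel$index
    fold_auc <- vapply(seq_len(cv_folds), function(f)
      roc_auc(stats::plogis(valF_list[[f]][, s_idx]), yval_list[[f]]),
      numeric(1))
    cv <- list(curve = curve, folds = folds,
               deviance = curve$deviance[s_idx], deviance_se = curve$se[s_idx],
               auc = fold_auc, auc_mean = mean(fold_auc),
               auc_se = stats::sd(fold_auc) / sqrt(cv_folds))
  }

  intercept <- stats::qlogis(mean(y))
  final_stride <- min(stride, as.integer(n_trees))
  set.seed(seed)
  fit <- cpp_boost(x, y, intercept, learning_rate, tree_complexity,
                   min_obs_leaf, bag_fraction, as.integer(n_trees),
                   matrix(numeric(0), 0, ncol(x)), numeric(0),
                   final_stride)
  structure(list(
    forest = fit[c("var", "split", "value", "left", "right", "offsets")],
    improvements = fit$improvements,
    intercept = intercept, learning_rate = learning_rate,
    tree_complexity = tree_complexity, bag_fraction = bag_fraction,
    min_obs_leaf = min_obs_leaf, n_trees = as.integer(n_trees),
    cv = cv, schema = schema, x = x, y = y, seed = seed,
    train_deviance = data.frame(trees = fit$stride_trees,
                                deviance = fit$train_dev)
  ), class = "brt")
}

#' Select the tree count from a cross-validated deviance curve
#'
#' The optimal number of trees minimises the mean cross-validated predictive
#' deviance; ties are broken toward fewer trees. A minimum at the largest
#' evaluated tree count triggers a warning that the bound was hit.
#'
#' @param curve data frame with columns `trees` and `deviance` (ascending
#'   `trees`).
#' @return `list(n_trees, index)`.
#' @export
select_n_trees <- function(curve) {
  if (nrow(curve) < 2) stop("need the deviance at >= 2 tree counts")
  i <- which.min(curve$deviance) # first minimum = fewest trees on ties
  if (i == nrow(curve))
    warning("CV deviance still decreasing at max_trees; the bound was hit")
  list(n_trees = curve$trees[i], index = i)
}

# sum of unshrunk leaf values of the first n trees (link contribution / lr)
forest_raw <- function(object, newx, n_trees = object$n_trees) {
  fo <- object$forest
  cpp_forest_sum(fo$var, fo$split, fo$value, fo$left, fo$right, fo$offsets,
                 as.integer(n_trees), newx)
}

check_schema <- function(object, newdata) {
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  missing <- setdiff(object$schema, colnames(newdata))
  if (length(missing))
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  newdata[, object$schema, drop = FALSE]
}

#' Predict from a boosted regression tree model
#'
#' Probability is the inverse logit of
#' `intercept + learning_rate * sum(leaf values of the first n_trees trees)`.
#'
#' @param object a [brt] model.
#' @param newdata matrix or data frame containing the training feature
#'   columns.
#' @param n_trees number of trees to use (default the selected count; 0 gives
#'   the training prevalence everywhere).
#' @param type `"response"` for probabilities, `"link"` for the logit.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.brt <- function(object, newdata, n_trees = object$n_trees,
                        type = c("response", "link"), ...) {
  type <- match.arg(type)
  newx <- check_schema(object, newdata)
  eta <- object$intercept +
    object$learning_rate * forest_raw(object, newx, n_trees)
  if (type == "link") eta else stats::plogis(eta)
}

#' Relative influence of each predictor in a BRT model
#'
#' Sum of the squared-error improvements of every split on each variable
#' across the first `n_trees` trees, rescaled so the most important variable
#' scores 100. Variables never split score 0.
#'
#' @param model a [brt] model.
#' @param n_trees trees to include (default the selected count).
#' @return Named numeric vector of importance scores, descending.
#' @export
variable_importance <- function(model, n_trees = model$n_trees) {
  stopifnot(inherits(model, "brt"), n_trees >= 1)
  raw <- colSums(model$improvements[seq_len(n_trees), , drop = FALSE])
  names(raw) <- model$schema
  mx <- max(raw)
  out <- if (mx > 0) 100 * raw / mx else raw
  sort(out, decreasing = TRUE)
}

# deterministic subsample of the training rows used to average partial
# dependence: evenly spaced in row order
pd_rows <- function(model, n_points) {
  n <- nrow(model$x)
  if (is.null(n_points) || n_points >= n) return(seq_len(n))
  unique(round(seq(1, n, length.out = n_points)))
}

#' Partial dependence of a BRT model on one or two predictors
#'
#' Friedman partial dependence: the mean model output on the logit scale over
#' the training data with the target variable(s) fixed at each grid value,
#' centered to mean zero. Positive values indicate conditions favouring
#' occurrence.
#'
#' @param model a [brt] model.
#' @param vars one or two predictor names.
#' @param grid optional list of grid vectors (one per variable); default is
#'   an equally spaced grid over the training range.
#' @param n_grid grid points per variable when `grid` is NULL.
#' @param n_points training rows averaged over (evenly spaced subsample;
#'   NULL = all rows).
#' @return Data frame: one column per variable plus `fit` (centered logit).
#' @export
partial_dependence <- function(model, vars, grid = NULL, n_grid = 50,
                               n_points = 200) {
  stopifnot(inherits(model, "brt"))
  bad <- setdiff(vars, model$schema)
  if (length(bad)) stop("unknown variable(s): ", paste(bad, collapse = ", "))
  if (!length(vars) %in% 1:2) stop("vars must name 1 or 2 predictors")
  if (is.null(grid)) {
    grid <- lapply(vars, function(v)
      seq(min(model$x[, v]), max(model$x[, v]), length.out = n_grid))
    names(grid) <- vars
  } else {
    if (!is.list(grid)) grid <- stats::setNames(list(grid), vars)
    if (any(lengths(grid) == 0)) stop("empty grid")
  }
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  base <- model$x[pd_rows(model, n_points), , drop = FALSE]
  nb <- nrow(base)
  big <- base[rep(seq_len(nb), times = nrow(combos)), , drop = FALSE]
  for (v in vars)
    big[, v] <- rep(combos[[v]], each = nb)
  eta <- model$intercept + model$learning_rate * forest_raw(model, big)
  fit <- colMeans(matrix(eta, nrow = nb))
  combos$fit <- fit - mean(fit)
  combos
}

#' Pairwise interaction strength in a BRT model
#'
#' Following the boosted-tree interaction diagnostic of the BRT working
#' guide: evaluate the model's two-way partial-dependence surface for a pair
#' of predictors on a grid, remove the additive (row + column main effects)
#' part, and report the variance of the residual departure from additivity,
#' scaled by 1000 for readability. Exactly 0 for purely additive models
#' (e.g. any depth-1 model).
#'
#' @param model a [brt] model.
#' @param vars a pair of predictor names, or NULL for all pairs.
#' @param n_grid grid points per variable.
#' @param n_points training rows averaged in the partial dependence.
#' @return For a pair, a single number (attribute `degenerate` flags a
#'   constant surface); for NULL, a symmetric named matrix over all pairs.
#' @export
interaction_strength <- function(model, vars = NULL, n_grid = 20,
                                 n_points = 100) {
  stopifnot(inherits(model, "brt"))
  if (is.null(vars)) {
    p <- length(model$schema)
    out <- matrix(0, p, p, dimnames = list(model$schema, model$schema))
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      s <- interaction_strength(model, c(model$schema[i], model$schema[j]),
                                n_grid = n_grid, n_points = n_points)
      out[i, j] <- out[j, i] <- as.numeric(s)
    }
    return(out)
  }
  stopifnot(length(vars) == 2)
  pd <- partial_dependence(model, vars, n_grid = n_grid, n_points = n_points)
  m <- matrix(pd$fit, nrow = length(unique(pd[[1]])))
  if (max(m) - min(m) < 1e-12) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  resid <- sweep(sweep(m, 1, rowMeans(m)), 2, colMeans(m)) + mean(m)
  stat <- mean(resid^2) * 1000
  attr(stat, "degenerate") <- FALSE
  stat
}

#' @export
print.brt <- function(x, ...) {
  cat(sprintf("Boosted regression trees: %d trees (lr %g, tc %d, bag %g)\n",
              x$n_trees, x$learning_rate, x$tree_complexity, x$bag_fraction))
  cat(sprintf("  %d obs x %d predictors, prevalence %.3f\n",
              nrow(x$x), length(x$schema), mean(x$y)))
  if (!is.null(x$cv))
    cat(sprintf("  CV deviance %.4f (SE %.4f), CV AUC %.3f (SE %.3f)\n",
                x$cv$deviance, x$cv$deviance_se, x$cv$auc_mean, x$cv$auc_se))
  invisible(x)
}

#' Summary of a BRT model
#'
#' @param object a [brt] model.
#' @param ... unused.
#' @return A list of class `summary.brt`: selected settings, cross-validation
#'   results and the variable importance table.
#' @export
summary.brt <- function(object, ...) {
  out <- list(
    n_trees = object$n_trees, learning_rate = object$learning_rate,
    tree_complexity = object$tree_complexity,
    bag_fraction = object$bag_fraction,
    prevalence = mean(object$y),
    cv = object$cv,
    importance = variable_importance(object)
  )
  class(out) <- "summary.brt"
  out
}

#' @export
print.summary.brt <- function(x, ...) {
  cat(sprintf("BRT: nt %d, lr %g, tc %d, bag %g, prevalence %.3f\n",
              x$n_trees, x$learning_rate, x$tree_complexity, x$bag_fraction,
              x$prevalence))
  if (!is.null(x$cv)) {
    cat(sprintf("CV deviance %.4f (SE %.4f)\n", x$cv$deviance, x$cv$deviance_se))
    cat(sprintf("CV AUC %.3f (SE %.3f) [%s]\n", x$cv$auc_mean, x$cv$auc_se,
                hosmer_class(x$cv$auc_mean)))
  }
  cat("Variable importance (max = 100):\n")
  print(round(x$importance, 1))
  invisible(x)
}

#' Partial-dependence plots for the most influential predictors
#'
#' @param x a [brt] model.
#' @param vars predictors to plot (default the top 4 by importance).
#' @param n_grid grid points per curve.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.brt <- function(x, vars = NULL, n_grid = 50, ...) {
  if (is.null(vars)) {
    imp <- variable_importance(x)
    vars <- names(imp)[seq_len(min(4, length(imp)))]
    labs <- sprintf("%s (%.0f)", vars, imp[vars])
  } else labs <- vars
  op <- graphics::par(mfrow = c(ceiling(length(vars) / 2),
                                min(2, length(vars))))
  on.exit(graphics::par(op))
  for (i in seq_along(vars)) {
    pd <- partial_dependence(x, vars[i], n_grid = n_grid)
    plot(pd[[1]], pd$fit, type = "l", xlab = labs[i],
         ylab = "fitted function", ...)
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}
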