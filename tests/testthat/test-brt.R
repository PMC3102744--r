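# hand-built forests with known arithmetic, closed-form limits, and
# recovery checks on simulated responses

# assemble a brt object from a list of stumps:
# each stump: list(var (1-based), split, vL, vR)
hand_brt <- function(stumps, intercept, lr, schema, x = NULL, y = NULL) {
  var <- integer(0); split <- numeric(0); value <- numeric(0)
  left <- integer(0); right <- integer(0); offsets <- integer(0)
  for (s in stumps) {
    o <- length(var)
    offsets <- c(offsets, o)
    var <- c(var, s$var - 1L, -1L, -1L)
    split <- c(split, s$split, 0, 0)
    value <- c(value, 0, s$vL, s$vR)
    left <- c(left, o + 1L, -1L, -1L)
    right <- c(right, o + 2L, -1L, -1L)
  }
  offsets <- c(offsets, length(var))
  structure(list(
    forest = list(var = var, split = split, value = value,
                  left = left, right = right, offsets = offsets),
    improvements = matrix(0, length(stumps), length(schema)),
    intercept = intercept, learning_rate = lr, tree_complexity = 1L,
    n_trees = length(stumps), schema = schema, x = x, y = y, cv = NULL
  ), class = "brt")
}

sim_xy <- function(n, seed, f) {
  set.seed(seed)
  x <- cbind(x1 = runif(n, -2, 2), x2 = runif(n, -2, 2),
             x3 = runif(n, -2, 2))
  p <- stats::plogis(f(x))
  list(x = x, y = stats::rbinom(n, 1, p))
}

test_that("a vanishing learning rate leaves predictions at the base rate", {
  d <- sim_xy(200, 1, function(x) x[, 1])
  fit <- brt(x = d$x, y = d$y, learning_rate = 1e-9, n_trees = 10, seed = 1)
  expect_equal(unname(predict(fit, d$x)), rep(mean(d$y), 200),
               tolerance = 1e-6)
})

test_that("a perfectly separating binary feature drives deviance to zero", {
  x <- cbind(a = rep(c(0, 1), each = 20), b = 0)
  y <- x[, "a"]
  fit <- brt(x = x, y = y, learning_rate = 0.1, tree_complexity = 1,
             bag_fraction = 1, n_trees = 1500, cv_eval_stride = 100,
             seed = 2)
  expect_lt(utils::tail(fit$train_deviance$deviance, 1), 0.01)
})

test_that("tree-count selection takes the deviance minimum, ties to fewer", {
  u <- data.frame(trees = c(50, 100, 150), deviance = c(3, 1, 2))
  expect_equal(select_n_trees(u)$n_trees, 100)
  tie <- data.frame(trees = c(50, 100, 150), deviance = c(2, 1, 1))
  expect_equal(select_n_trees(tie)$n_trees, 100)
  mono <- data.frame(trees = c(50, 100), deviance = c(2, 1))
  expect_warning(select_n_trees(mono), "bound")
  expect_error(select_n_trees(data.frame(trees = 50, deviance = 1)), ">= 2")
})

test_that("prediction is the stagewise sum of shrunk leaf values", {
  m <- hand_brt(list(list(var = 1L, split = 0.5, vL = -1, vR = 2),
                     list(var = 2L, split = 1.5, vL = 0.5, vR = -0.5)),
                intercept = 0.3, lr = 0.1, schema = c("f1", "f2"))
  X <- rbind(c(0, 1), c(1, 2), c(0.7, 0))
  colnames(X) <- c("f1", "f2")
  eta <- 0.3 + 0.1 * c(-1 + 0.5, 2 - 0.5, 2 + 0.5)
  expect_equal(predict(m, X, type = "link"), eta)
  expect_equal(predict(m, X), stats::plogis(eta))
  expect_error(predict(m, X[, 1, drop = FALSE]), "f2")
})

test_that("zero trees predict the training prevalence; outputs stay in (0,1)", {
  d <- sim_xy(150, 3, function(x) 0.5 * x[, 2])
  fit <- brt(x = d$x, y = d$y, learning_rate = 0.05, n_trees = 40, seed = 3)
  expect_equal(unname(predict(fit, d$x, n_trees = 0)),
               rep(mean(d$y), 150))
  p <- predict(fit, d$x)
  expect_true(all(p > 0 & p < 1))
})

test_that("fits are reproducible under a fixed seed and config", {
  d <- sim_xy(250, 4, function(x) x[, 1] - x[, 3])
  f1 <- brt(x = d$x, y = d$y, learning_rate = 0.05, max_trees = 100,
            cv_folds = 4, cv_eval_stride = 25, seed = 9)
  f2 <- brt(x = d$x, y = d$y, learning_rate = 0.05, max_trees = 100,
            cv_folds = 4, cv_eval_stride = 25, seed = 9)
  expect_identical(f1$forest, f2$forest)
  expect_identical(f1$cv$curve, f2$cv$curve)
  expect_identical(predict(f1, d$x), predict(f2, d$x))
})

test_that("training deviance is non-increasing without bagging", {
  d <- sim_xy(300, 5, function(x) x[, 1] + x[, 2]^2)
  fit <- brt(x = d$x, y = d$y, learning_rate = 0.1, bag_fraction = 1,
             n_trees = 80, cv_eval_stride = 5, seed = 6)
  expect_true(all(diff(fit$train_deviance$deviance) <= 1e-12))
})

test_that("importance rescaling: top predictor 100, unused predictors 0", {
  m <- hand_brt(list(list(var = 1L, split = 0, vL = 0, vR = 0),
                     list(var = 2L, split = 0, vL = 0, vR = 0)),
                intercept = 0, lr = 0.1, schema = c("v1", "v2"))
  m$improvements <- rbind(c(9, 0), c(0, 1))
  imp <- variable_importance(m)
  expect_equal(unname(imp["v1"]), 100)
  expect_equal(unname(imp["v2"]), 100 / 9, tolerance = 1e-9)

  d <- sim_xy(300, 7, function(x) 2 * x[, 1])
  x <- cbind(d$x[, 1, drop = FALSE], dead = 5)  # a constant, unusable feature
  fit <- brt(x = x, y = d$y, learning_rate = 0.05, n_trees = 60, seed = 8)
  imp <- variable_importance(fit)
  expect_equal(max(imp), 100)
  expect_equal(unname(imp["dead"]), 0)
  # monotone rescaling of an unused predictor changes nothing
  x2 <- x; x2[, "dead"] <- exp(x2[, "dead"])
  fit2 <- brt(x = x2, y = d$y, learning_rate = 0.05, n_trees = 60, seed = 8)
  expect_equal(variable_importance(fit2), imp)
})

test_that("partial dependence: flat for unused vars, a step for one stump", {
  m <- hand_brt(list(list(var = 1L, split = 0.5, vL = -2, vR = 3)),
                intercept = 1, lr = 0.1, schema = c("f1", "f2"),
                x = cbind(f1 = runif(50), f2 = runif(50)))
  pd2 <- partial_dependence(m, "f2", n_grid = 11)
  expect_equal(pd2$fit, rep(0, 11))
  pd1 <- partial_dependence(m, "f1", grid = list(f1 = c(0, 1)))
  # two levels equal to the shrunk leaf values, centered
  expect_equal(pd1$fit, c(0.1 * -2, 0.1 * 3) - 0.1 * 0.5)
})

test_that("interaction statistic: zero for stumps, maximal for the true pair", {
  d <- sim_xy(600, 10, function(x) 1.5 * x[, 1] * x[, 2])
  stump <- brt(x = d$x, y = d$y, learning_rate = 0.1, tree_complexity = 1,
               n_trees = 150, seed = 11)
  for (pair in list(c("x1", "x2"), c("x1", "x3"), c("x2", "x3"))) {
    s <- interaction_strength(stump, pair, n_grid = 10)
    expect_lt(as.numeric(s), 1e-10)
  }
  deep <- brt(x = d$x, y = d$y, learning_rate = 0.1, tree_complexity = 2,
              n_trees = 300, seed = 12)
  mat <- interaction_strength(deep, n_grid = 12, n_points = 150)
  expect_equal(mat, t(mat))
  expect_equal(sort(c(mat[upper.tri(mat)]), decreasing = TRUE)[1],
               mat["x1", "x2"])
})

test_that("degenerate inputs are rejected with clear errors", {
  x <- matrix(rnorm(40), 20, 2)
  expect_error(brt(x = x, y = rep(1, 20), n_trees = 5), "single class")
  xx <- x; xx[3, 1] <- Inf
  expect_error(brt(x = xx, y = rep(c(0, 1), 10), n_trees = 5), "finite")
  expect_error(brt(x = x, y = rep(c(0, 1), 10), learning_rate = 0.5),
               "learning_rate")
})
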