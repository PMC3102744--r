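# Presence-only maximum-entropy distribution model: the Gibbs distribution
# over background cells that maximises entropy subject to (L1-relaxed)
# constraints tying fitted feature expectations to their presence-sample
# means; equivalently an L1-penalised maximum-likelihood fit.

#' Expand raw predictors into MaxEnt features
#'
#' Builds the feature matrix for a given set of feature classes: linear
#' terms, squares (`quadratic`) and pairwise products (`product`), each
#' standardised by the background mean and standard deviation.
#' Zero-variance features are dropped with a warning. When `transform` is
#' supplied the stored expansion and standardisation are applied instead
#' (for presence or prediction data).
#'
#' @param x matrix or data frame of raw predictor values.
#' @param classes subset of `c("linear", "quadratic", "product")`.
#' @param transform a transform attribute from a previous call (background).
#' @return Standardised feature matrix with attribute `transform`.
#' @export
build_features <- function(x, classes = c("linear", "quadratic", "product"),
                           transform = NULL) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("raw predictor values must be finite")
  if (is.null(transform)) {
    classes <- match.arg(classes, c("linear", "quadratic", "product", "hinge"),
                         several.ok = TRUE)
    nm <- colnames(x)
    terms <- list()
    if ("linear" %in% classes)
      for (v in nm) terms[[v]] <- list(type = "linear", v1 = v)
    if ("quadratic" %in% classes)
      for (v in nm) terms[[paste0(v, "^2")]] <- list(type = "quadratic", v1 = v)
    if ("product" %in% classes && length(nm) > 1) {
      for (i in seq_len(length(nm) - 1)) for (j in (i + 1):length(nm)) {
        terms[[paste0(nm[i], ":", nm[j])]] <-
          list(type = "product", v1 = nm[i], v2 = nm[j])
      }
    }
    E <- eval_terms(x, terms)
    ctr <- colMeans(E)
    scl <- apply(E, 2, stats::sd)
    keep <- scl > 1e-12
    if (!all(keep))
      warning("dropping zero-variance feature(s): ",
              paste(names(terms)[!keep], collapse = ", "))
    E <- E[, keep, drop = FALSE]
    transform <- list(terms = terms[keep], center = ctr[keep],
                      scale = scl[keep], raw_names = nm, classes = classes)
  } else {
    missing <- setdiff(transform$raw_names, colnames(x))
    if (length(missing))
      stop("missing raw predictor(s): ", paste(missing, collapse = ", "))
    x <- x[, transform$raw_names, drop = FALSE]
    E <- eval_terms(x, transform$terms)
  }
  out <- sweep(sweep(E, 2, transform$center), 2, transform$scale, "/")
  attr(out, "transform") <- transform
  out
}

eval_terms <- function(x, terms) {
  if (!length(terms))
    return(matrix(numeric(0), nrow(x), 0))
  E <- vapply(terms, function(tm) {
    switch(tm$type,
           linear = x[, tm$v1],
           quadratic = x[, tm$v1]^2,
           product = x[, tm$v1] * x[, tm$v2])
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) E <- matrix(E, 1, dimnames = list(NULL, names(terms)))
  E
}

logsumexp <- function(v) { M <- max(v); M + log(sum(exp(v - M))) }

# coordinate-wise proximal Newton for the L1-penalised maxent objective
# minimise F(l) = -a.l + logsumexp(B l) + sum(beta |l|)
# Sweeps alternate between the active set (nonzero weights) and full passes;
# iteration stops on the KKT subgradient conditions, not objective change,
# so the relaxed feature-expectation box constraints hold at the solution.
maxent_solve <- function(a, B, beta, max_iter, tol, lambda0 = NULL) {
  J <- length(a)
  lam <- if (is.null(lambda0)) numeric(J) else lambda0
  eta <- drop(B %*% lam)
  B2 <- B * B
  Fval <- -sum(a * lam) + logsumexp(eta) + sum(beta * abs(lam))
  kkt <- Inf
  it <- 0
  repeat {
    it <- it + 1
    Fprev <- Fval
    full <- (it %% 5 == 1L) || !any(lam != 0)
    js <- if (full) seq_len(J) else which(lam != 0)
    for (j in js) {
      w <- exp(eta - max(eta)); q <- w / sum(w)
      bq <- sum(B[, j] * q)
      grad <- bq - a[j]
      hess <- max(sum(B2[, j] * q) - bq^2, 1e-8)
      z <- lam[j] - grad / hess
      new <- sign(z) * max(0, abs(z) - beta[j] / hess)
      dl <- new - lam[j]
      if (dl == 0) next
      # damped update: halve the step until the penalised objective does not
      # increase (safeguards the per-coordinate Newton approximation)
      repeat {
        cand <- lam[j] + dl
        eta_c <- eta + dl * B[, j]
        Fc <- -(sum(a * lam) - a[j] * lam[j] + a[j] * cand) +
          logsumexp(eta_c) +
          sum(beta * abs(lam)) - beta[j] * abs(lam[j]) + beta[j] * abs(cand)
        if (Fc <= Fval + 1e-12 || abs(dl) < 1e-14) break
        dl <- dl / 2
      }
      if (Fc <= Fval + 1e-12 && abs(dl) >= 1e-14) {
        lam[j] <- cand
        eta <- eta_c
        Fval <- Fc
      }
    }
    if (full) {
      # KKT violation of the subgradient conditions
      w <- exp(eta - max(eta)); q <- w / sum(w)
      g <- drop(crossprod(B, q)) - a
      kkt <- max(ifelse(lam != 0, abs(g + beta * sign(lam)),
                        pmax(0, abs(g) - beta)))
      if (kkt < 1e-8) break
      if (abs(Fprev - Fval) < tol * (abs(Fprev) + 1e-10) &&
          kkt < 1e-6 && it > 2) break
      # complete stagnation of a full sweep: no further progress possible
      if (abs(Fprev - Fval) < 1e-15 * (abs(Fprev) + 1) && it > 5) break
    }
    if (it >= max_iter) break
  }
  list(lambda = lam, eta = eta, objective = Fval, iterations = it, kkt = kkt)
}

#' Fit a maximum-entropy species distribution model
#'
#' Finds the Gibbs distribution `q(x) = exp(lambda . f(x)) / Z` over the
#' background cells maximising the penalised mean log-likelihood of the
#' presence sample, with an L1 penalty `sum(beta_j |lambda_j|)`,
#' `beta_j = regularization_multiplier * s_j / sqrt(m)` (`s_j` the background
#' feature standard deviation, `m` the presence count). At the optimum each
#' fitted feature expectation lies within `beta_j` of its presence-sample
#' mean — the entropy-maximisation constraints in their relaxed form. The
#' optimiser is coordinate-wise proximal Newton; the contract is the KKT
#' optimum, not the algorithm.
#'
#' @param presence matrix/data frame of raw predictors at presence sites
#'   (at least 5 rows).
#' @param background matrix/data frame of raw predictors at background
#'   cells (presence cells may and should be included).
#' @param feature_classes subset of `c("linear", "quadratic", "product")`
#'   (hinge features are not fitted by default; smooth classes keep the
#'   problem small and convex).
#' @param regularization_multiplier scales all penalties (default 1).
#' @param max_iterations coordinate-descent sweeps (default 2000).
#' @param convergence_tol relative objective-change tolerance (default
#'   1e-9).
#' @param lambda_init optional starting weights (testing concavity from
#'   different starts).
#' @return An object of class `maxent`: weights `lambda`, the feature
#'   `transform`, penalties `beta`, log-partition `log_z`, background
#'   `entropy`, presence and fitted feature means, the regularised training
#'   `gain`, and convergence diagnostics.
#' @seealso [predict.maxent()], [jackknife_importance()],
#'   [sample_background()]
#' @export
maxent <- function(presence, background,
                   feature_classes = c("linear", "quadratic", "product"),
                   regularization_multiplier = 1, max_iterations = 2000,
                   convergence_tol = 1e-9, lambda_init = NULL) {
  presence <- as.matrix(presence); background <- as.matrix(background)
  if (nrow(presence) < 5) stop("need at least 5 presence records")
  fb <- build_features(background, feature_classes)
  tf <- attr(fb, "transform")
  fp <- build_features(presence, transform = tf)
  m <- nrow(fp)
  s <- apply(fb, 2, stats::sd)
  beta <- regularization_multiplier * s / sqrt(m)
  a <- colMeans(fp)
  if (ncol(fb) == 0) {
    # no informative features: the unconstrained maximum-entropy solution is
    # the uniform distribution over the background
    sol <- list(lambda = numeric(0), eta = rep(0, nrow(fb)), objective = 0,
                iterations = 0L, kkt = 0)
  } else {
    sol <- maxent_solve(a, fb, beta, max_iterations, convergence_tol,
                        lambda_init)
  }
  if (sol$kkt > 1e-3)
    warning(sprintf(
      "maxent did not converge in %d sweeps (KKT violation %.3g)",
      sol$iterations, sol$kkt))
  log_z <- logsumexp(sol$eta)
  q <- exp(sol$eta - log_z)
  entropy <- -sum(q * log(pmax(q, 1e-300)))
  gain <- sum(a * sol$lambda) - log_z + log(nrow(fb)) -
    sum(beta * abs(sol$lambda))
  lam <- sol$lambda
  names(lam) <- colnames(fb)
  structure(list(
    lambda = lam,
    transform = tf, beta = beta, log_z = log_z, entropy = entropy,
    presence_means = a, fitted_means = drop(crossprod(fb, q)),
    gain = gain, objective = sol$objective, iterations = sol$iterations,
    kkt = sol$kkt, m = m, n_background = nrow(fb),
    feature_classes = feature_classes,
    regularization_multiplier = regularization_multiplier
  ), class = "maxent")
}

#' Predict from a maximum-entropy model
#'
#' `raw` is the Gibbs probability `exp(lambda . f(x)) / Z` (sums to 1 over
#' the exact training background); `logistic` is the standard MaxEnt
#' logistic output `plogis(H + log raw)` with `H` the fitted background
#' entropy (tau = 0.5: a cell with typical background suitability scores
#' 0.5); `link` is the linear predictor `lambda . f(x) - log Z`. Habitat
#' suitability maps are `100 * logistic`.
#'
#' @param object a [maxent] model.
#' @param newdata matrix/data frame of raw predictor columns.
#' @param type `"logistic"`, `"raw"` or `"link"`.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.maxent <- function(object, newdata,
                           type = c("logistic", "raw", "link"), ...) {
  type <- match.arg(type)
  f <- build_features(as.matrix(newdata), transform = object$transform)
  link <- drop(f %*% object$lambda) - object$log_z
  switch(type,
         link = link,
         raw = exp(link),
         logistic = stats::plogis(object$entropy + link))
}

#' Uniform random background sample from a predictor stack
#'
#' Seeded sample without replacement of cells valid in every layer; if the
#' request exceeds the valid-cell count the whole valid set is returned.
#'
#' @param stack a `predictor_stack`.
#' @param n_background cells to draw (default 10000).
#' @param seed integer seed.
#' @return Matrix of raw predictor rows (one per cell) with a `cells`
#'   attribute giving `row`, `col`, `x`, `y`.
#' @export
sample_background <- function(stack, n_background = 10000, seed = 1) {
  stopifnot(inherits(stack, "predictor_stack"))
  vals <- sapply(stack$layers, function(g) as.vector(g$values))
  ok <- which(stats::complete.cases(vals))
  if (!length(ok)) stop("no valid cells in the stack")
  set.seed(seed)
  pick <- if (n_background >= length(ok)) ok else sort(sample(ok, n_background))
  ref <- stack$layers[[1]]
  nr <- nrow(ref$values)
  row <- ((pick - 1L) %% nr) + 1L
  col <- ((pick - 1L) %/% nr) + 1L
  out <- vals[pick, , drop = FALSE]
  colnames(out) <- names(stack$layers)
  attr(out, "cells") <- data.frame(
    row = row, col = col,
    x = ref$origin[1] + (col - 0.5) * ref$cell_size_m,
    y = ref$origin[2] - (row - 0.5) * ref$cell_size_m)
  out
}

#' Jackknife importance of each raw predictor
#'
#' For every raw predictor, fits the model using only that predictor's
#' features (`gain_alone`) and with that predictor's features removed
#' (`gain_drop`), reporting regularised training gains relative to the null
#' (uniform) model. A predictor whose removal barely lowers the gain is
#' redundant; one with the highest gain alone carries the most standalone
#' information.
#'
#' @inheritParams maxent
#' @param ... passed to [maxent()].
#' @return Data frame `predictor, gain_alone, gain_drop`, with the
#'   full-model gain in attribute `full_gain`.
#' @export
jackknife_importance <- function(presence, background, ...) {
  presence <- as.matrix(presence); background <- as.matrix(background)
  nm <- colnames(presence)
  if (length(nm) < 2) stop("need at least 2 raw predictors")
  full <- maxent(presence, background, ...)
  res <- lapply(nm, function(v) {
    alone <- maxent(presence[, v, drop = FALSE],
                    background[, v, drop = FALSE], ...)
    drop_ <- maxent(presence[, setdiff(nm, v), drop = FALSE],
                    background[, setdiff(nm, v), drop = FALSE], ...)
    c(gain_alone = alone$gain, gain_drop = drop_$gain)
  })
  out <- data.frame(predictor = nm, do.call(rbind, res))
  attr(out, "full_gain") <- full$gain
  out
}

#' @export
print.maxent <- function(x, ...) {
  nz <- sum(x$lambda != 0)
  cat(sprintf("MaxEnt model: %d presences, %d background cells\n",
              x$m, x$n_background))
  cat(sprintf("  %d features (%s), %d nonzero weights\n",
              length(x$lambda), paste(x$feature_classes, collapse = "+"), nz))
  cat(sprintf("  regularised training gain %.4f, entropy %.4f (uniform %.4f)\n",
              x$gain, x$entropy, log(x$n_background)))
  invisible(x)
}

#' Summary of a MaxEnt model
#'
#' @param object a [maxent] model.
#' @param ... unused.
#' @return List of class `summary.maxent` with the nonzero weights and fit
#'   diagnostics.
#' @export
summary.maxent <- function(object, ...) {
  w <- object$lambda[object$lambda != 0]
  out <- list(weights = sort(w, decreasing = TRUE), gain = object$gain,
              entropy = object$entropy, m = object$m,
              n_background = object$n_background, kkt = object$kkt,
              iterations = object$iterations)
  class(out) <- "summary.maxent"
  out
}

#' @export
print.summary.maxent <- function(x, ...) {
  cat(sprintf("MaxEnt: gain %.4f, entropy %.4f, %d sweeps (KKT %.2g)\n",
              x$gain, x$entropy, x$iterations, x$kkt))
  cat("Nonzero feature weights:\n")
  print(round(x$weights, 4))
  invisible(x)
}
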