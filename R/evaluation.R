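# Model and map assessment: ROC AUC (observed-absence and pseudo-absence
# variants), stratified k-fold machinery, Hosmer-Lemeshow performance bands
# and threshold-based map accuracy against independent survey sites.

#' ROC area under the curve
#'
#' Mann-Whitney formulation with midrank tie handling; equals the
#' trapezoidal area under the empirical ROC curve. 0.5 is chance-level
#' discrimination, 1 is perfect.
#'
#' @param scores numeric prediction scores (any monotone scale).
#' @param labels 0/1 (or logical) observed classes; both classes must be
#'   present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Pseudo-absence ROC AUC for presence-only models
#'
#' AUC of the presence scores against seeded random draws from the
#' background scores, used in place of observed absences; reported with the
#' Monte-Carlo standard error over draws. With a single exhaustive draw this
#' reduces exactly to [roc_auc()] against the whole background.
#'
#' @param presence_scores scores at presence sites.
#' @param background_scores scores at background (pseudo-absence) cells.
#' @param n_absences pseudo-absences per draw (default: the whole
#'   background).
#' @param n_draws number of Monte-Carlo draws.
#' @param seed integer seed.
#' @return `list(auc, se, draws)`.
#' @export
pseudo_absence_auc <- function(presence_scores, background_scores,
                               n_absences = length(background_scores),
                               n_draws = 1, seed = 1) {
  if (!length(presence_scores) || !length(background_scores))
    stop("score sets must be nonempty")
  n_absences <- min(n_absences, length(background_scores))
  set.seed(seed)
  draws <- vapply(seq_len(n_draws), function(d) {
    ab <- if (n_absences == length(background_scores)) background_scores
          else sample(background_scores, n_absences)
    roc_auc(c(presence_scores, ab),
            c(rep(1, length(presence_scores)), rep(0, n_absences)))
  }, numeric(1))
  list(auc = mean(draws),
       se = if (n_draws > 1) stats::sd(draws) / sqrt(n_draws) else 0,
       draws = draws)
}

#' Seeded k-fold assignment, optionally stratified
#'
#' Partitions `1:n` into `k` folds of size differing by at most one. With
#' `labels`, assignment is stratified so every fold receives its share of
#' each class — essential at low prevalence, where unstratified folds can be
#' presence-free and leave the AUC undefined.
#'
#' @param n number of observations.
#' @param k number of folds.
#' @param labels optional class labels for stratification; every class must
#'   have at least `k` members.
#' @param seed integer seed.
#' @return Integer vector of fold ids in `1:k`.
#' @export
kfold_split <- function(n, k, labels = NULL, seed = 1) {
  if (k > n) stop("k must not exceed n")
  set.seed(seed)
  fold <- integer(n)
  if (is.null(labels)) {
    fold[sample.int(n)] <- rep_len(seq_len(k), n)
  } else {
    labels <- as.factor(labels)
    pos <- 0L
    for (lv in levels(labels)) {
      ix <- which(labels == lv)
      if (length(ix) < k)
        stop(sprintf(
          "class '%s' has %d members, fewer than %d folds; use a smaller k",
          lv, length(ix), k))
      ix <- ix[sample.int(length(ix))]
      fold[ix] <- ((pos + seq_along(ix) - 1L) %% k) + 1L
      pos <- pos + length(ix)
    }
  }
  fold
}

#' Hosmer-Lemeshow discrimination band for an AUC value
#'
#' 0.7--0.8 is an acceptable prediction, 0.8--0.9 excellent, above 0.9
#' outstanding; below 0.7 fails. Boundary values fall in the lower band.
#'
#' @param auc AUC in `[0, 1]`.
#' @return One of `"fail"`, `"acceptable"`, `"excellent"`, `"outstanding"`.
#' @export
hosmer_class <- function(auc) {
  stopifnot(auc >= 0, auc <= 1)
  if (auc <= 0.7) "fail"
  else if (auc <= 0.8) "acceptable"
  else if (auc <= 0.9) "excellent"
  else "outstanding"
}

#' Threshold-based map accuracy at independent presence sites
#'
#' Converts a 0--100 habitat-suitability map to binary (strictly greater
#' than `threshold_pct` = suitable) and scores the percentage of independent
#' presence sites falling on suitable cells. Only sightings are scored —
#' absences at validation sites are not — so this measures the map's ability
#' to capture where the species was actually seen. Sites on nodata cells are
#' excluded and counted.
#'
#' @param suitability a [raster_grid] on the 0--100 scale.
#' @param sites data frame of validation sites with `x`, `y` (and optionally
#'   `present`, in which case only rows with `present == 1` are used).
#' @param threshold_pct suitability threshold (default 10).
#' @return `list(map_accuracy_pct, misclassified_pct, n_presence_sites,
#'   n_excluded, threshold_pct)`.
#' @export
map_accuracy <- function(suitability, sites, threshold_pct = 10) {
  stopifnot(inherits(suitability, "raster_grid"))
  if ("present" %in% names(sites)) sites <- sites[sites$present == 1, ]
  rc <- xy_to_rowcol(suitability, sites$x, sites$y)
  if (anyNA(rc)) stop("site(s) outside the raster extent")
  vals <- suitability$values[rc]
  usable <- !is.na(vals)
  if (!any(usable)) stop("no usable presence sites (all nodata)")
  correct <- 100 * mean(vals[usable] > threshold_pct)
  list(map_accuracy_pct = correct, misclassified_pct = 100 - correct,
       n_presence_sites = sum(usable), n_excluded = sum(!usable),
       threshold_pct = threshold_pct)
}

#' Cross-validated pseudo-absence AUC for a presence-only model
#'
#' Partitions the presence records into k folds; each fold's model is fit on
#' the remaining presences (the background is shared) and scored by the AUC
#' of the held-out presences against the background.
#'
#' @param presence data frame/matrix of raw predictors at presence sites.
#' @param background data frame/matrix of raw predictors at background
#'   cells.
#' @param k folds (default 10).
#' @param seed integer seed.
#' @param ... passed to [maxent()].
#' @return `list(auc, auc_mean, auc_se)` with per-fold AUCs.
#' @export
cv_maxent <- function(presence, background, k = 10, seed = 1, ...) {
  presence <- as.matrix(presence)
  m <- nrow(presence)
  if (m < k) stop("fewer presences than folds")
  folds <- kfold_split(m, k, seed = seed)
  aucs <- vapply(seq_len(k), function(f) {
    fit <- maxent(presence[folds != f, , drop = FALSE], background, ...)
    sp <- predict(fit, presence[folds == f, , drop = FALSE], type = "link")
    sb <- predict(fit, background, type = "link")
    pseudo_absence_auc(sp, sb)$auc
  }, numeric(1))
  list(auc = aucs, auc_mean = mean(aucs),
       auc_se = stats::sd(aucs) / sqrt(k))
}
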