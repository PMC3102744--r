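# Synthetic seascapes with known ground truth: a cross-shelf depth ramp plus
# Gaussian patch-reef bumps plus white noise, a stratified-random survey
# design over hard/soft bottom, and Bernoulli species occurrences driven by a
# specified logit response (linear + step-threshold + interaction terms).

#' Parameters of a synthetic shelf seascape
#'
#' The surface is a linear cross-shelf depth ramp (shore at the western edge,
#' shelf edge at the eastern edge) with Gaussian patch-reef bumps rising from
#' it and white vertical noise, emulating a LiDAR-style bathymetric grid of a
#' shallow insular shelf.
#'
#' @param extent_cells `c(rows, cols)`; the cross-shelf axis runs along
#'   columns.
#' @param cell_size_m cell edge in meters (default 4, a typical bathymetric
#'   LiDAR product resolution).
#' @param shelf_depth_range `c(min, max)` depth in meters at the two ends of
#'   the ramp (default 1--49 m, the depth window such LiDAR can map).
#' @param n_reef_patches number of Gaussian patch reefs.
#' @param patch_amplitude_m maximum vertical relief of a patch (m).
#' @param patch_width_m horizontal patch scale (m); the Gaussian sigma is
#'   half this value.
#' @param noise_sd_m standard deviation of white vertical noise (m).
#' @param bank_amplitude_m standard deviation (m) of broad-scale seabed
#'   relief (mid-shelf banks and depressions, a sum of randomly oriented
#'   long waves): this keeps depth from being a mere proxy for cross-shelf
#'   position, as on real shelves (default 4). The relief is tapered toward
#'   the shallow nearshore.
#' @param bank_wavelength_m characteristic wavelength (m) of the bank
#'   relief (default 1500).
#' @param shore_undulation_m alongshore amplitude (m) of shoreline
#'   embayments: the shallow end of the profile swings landward/seaward by
#'   this much (default 300).
#' @param shelf_undulation_m alongshore amplitude (m) of the sinuous shelf
#'   rim, out of phase with the shoreline so the two rims (and hence the two
#'   distance predictors) are not mirror images (default 200).
#' @param undulation_wavelength_m alongshore wavelength (m) of both
#'   undulations (default 500).
#' @param seed integer seed; identical parameters and seed give bit-identical
#'   surfaces.
#' @return A list of class `seascape_params`.
#' @export
seascape_params <- function(extent_cells = c(250, 700), cell_size_m = 4,
                            shelf_depth_range = c(1, 49),
                            n_reef_patches = 40, patch_amplitude_m = 3,
                            patch_width_m = 50, noise_sd_m = 0.1,
                            bank_amplitude_m = 4, bank_wavelength_m = 1500,
                            shore_undulation_m = 300,
                            shelf_undulation_m = 200,
                            undulation_wavelength_m = 500, seed = 1) {
  stopifnot(length(extent_cells) == 2, all(extent_cells >= 1),
            cell_size_m > 0, length(shelf_depth_range) == 2,
            n_reef_patches >= 0, patch_amplitude_m >= 0,
            patch_width_m > 0, noise_sd_m >= 0,
            bank_amplitude_m >= 0, bank_wavelength_m > 0,
            shore_undulation_m >= 0, shelf_undulation_m >= 0,
            undulation_wavelength_m > 0)
  if (shelf_depth_range[1] >= shelf_depth_range[2])
    stop("min depth must be smaller than max depth")
  structure(list(extent_cells = as.integer(extent_cells),
                 cell_size_m = cell_size_m,
                 shelf_depth_range = shelf_depth_range,
                 n_reef_patches = as.integer(n_reef_patches),
                 patch_amplitude_m = patch_amplitude_m,
                 patch_width_m = patch_width_m, noise_sd_m = noise_sd_m,
                 bank_amplitude_m = bank_amplitude_m,
                 bank_wavelength_m = bank_wavelength_m,
                 shore_undulation_m = shore_undulation_m,
                 shelf_undulation_m = shelf_undulation_m,
                 undulation_wavelength_m = undulation_wavelength_m,
                 seed = as.integer(seed)),
            class = "seascape_params")
}

#' Generate a synthetic bathymetric surface
#'
#' Depth (positive down, meters) on a regular grid: a cross-shelf ramp from
#' the shallow western edge to the deep eastern shelf edge, with alongshore
#' undulation of the shoreline (embayments and headlands) and, out of phase,
#' of the shelf rim; minus Gaussian patch-reef bumps; plus white noise;
#' floored just below the shallow end so depth stays positive. Column means
#' still increase strictly seaward before the patch/noise perturbations.
#' The pre-noise surface (ramp + patches) and the bare undulated ramp are
#' kept as attributes as ground truth for stratification.
#'
#' @param params a [seascape_params()].
#' @return A [raster_grid] of depth with attributes `pre_noise` (matrix),
#'   `ramp` (matrix) and `params`.
#' @examples
#' b <- generate_bathymetry(seascape_params(extent_cells = c(40, 80)))
#' b
#' @export
generate_bathymetry <- function(params) {
  stopifnot(inherits(params, "seascape_params"))
  nr <- params$extent_cells[1]; nc <- params$extent_cells[2]
  if (nr < 8 || nc < 8) stop("degenerate extent: need at least 8x8 cells")
  cs <- params$cell_size_m
  rng <- params$shelf_depth_range
  set.seed(params$seed)
  # effective cross-shelf coordinate: the profile is shifted alongshore by
  # the shoreline undulation (decaying seaward) and the shelf-rim
  # undulation (decaying landward), out of phase with one another
  yrow <- (seq_len(nr) - 0.5) * cs
  w_shore <- params$shore_undulation_m / cs *
    sin(2 * pi * yrow / params$undulation_wavelength_m)
  w_shelf <- params$shelf_undulation_m / cs *
    sin(2 * pi * yrow / params$undulation_wavelength_m + pi / 2)
  tcol <- (seq_len(nc) - 1) / (nc - 1)
  c_eff <- outer(w_shore, (1 - tcol)^2) + outer(w_shelf, tcol^2)
  c_eff <- sweep(-c_eff, 2, seq_len(nc), "+")
  ramp <- rng[1] + (c_eff - 1) / (nc - 1) * (rng[2] - rng[1])
  # broad-scale banks/depressions: randomly oriented long cosine waves,
  # tapered toward the shallow nearshore so the coast stays coherent
  base <- ramp
  if (params$bank_amplitude_m > 0) {
    K <- 8L
    th <- stats::runif(K, 0, 2 * pi)
    wl <- params$bank_wavelength_m * stats::runif(K, 0.7, 1.4)
    ph <- stats::runif(K, 0, 2 * pi)
    xc <- (seq_len(nc) - 0.5) * cs
    banks <- matrix(0, nr, nc)
    for (k in seq_len(K)) {
      kx <- 2 * pi * cos(th[k]) / wl[k]
      ky <- 2 * pi * sin(th[k]) / wl[k]
      banks <- banks + outer(ky * yrow, kx * xc, "+") |> (\(m) cos(m + ph[k]))()
    }
    banks <- banks * params$bank_amplitude_m / sqrt(K / 2)
    base <- base + banks * sqrt(pmax(ramp, 0) / rng[2])
  }
  depth <- base
  sigma <- params$patch_width_m / 2 / cs   # in cells
  if (params$n_reef_patches > 0) {
    cr <- stats::runif(params$n_reef_patches, 1, nr)
    cc <- stats::runif(params$n_reef_patches, 1, nc)
    amp <- stats::runif(params$n_reef_patches, 0.5, 1) * params$patch_amplitude_m
    w <- ceiling(4 * sigma)
    for (pk in seq_len(params$n_reef_patches)) {
      rs <- max(1, floor(cr[pk] - w)):min(nr, ceiling(cr[pk] + w))
      cls <- max(1, floor(cc[pk] - w)):min(nc, ceiling(cc[pk] + w))
      d2 <- outer((rs - cr[pk])^2, (cls - cc[pk])^2, "+")
      depth[rs, cls] <- depth[rs, cls] - amp[pk] * exp(-d2 / (2 * sigma^2))
    }
  }
  pre_noise <- depth
  if (params$noise_sd_m > 0)
    depth <- depth + matrix(stats::rnorm(nr * nc, 0, params$noise_sd_m), nr, nc)
  floor_d <- 0.1 * rng[1]
  depth <- pmax(depth, floor_d)
  pre_noise <- pmax(pre_noise, floor_d)
  g <- raster_grid(depth, cs)
  attr(g, "pre_noise") <- pre_noise
  attr(g, "ramp") <- pmax(base, floor_d)
  attr(g, "params") <- params
  g
}

#' Hardbottom/softbottom strata of a synthetic seascape
#'
#' Strata mirror a benthic habitat map: hardbottom where the rugosity of the
#' true (pre-noise) surface exceeds, cell by cell, the rugosity of the bare
#' (patch-free) seabed — i.e. where patch reefs and their flanks add
#' roughness — softbottom elsewhere.
#'
#' @param bathy a bathymetry [raster_grid] from [generate_bathymetry()].
#' @return A [raster_grid] with 1 = hardbottom, 0 = softbottom.
#' @export
seascape_strata <- function(bathy) {
  pre <- attr(bathy, "pre_noise")
  ramp <- attr(bathy, "ramp")
  if (is.null(pre) || is.null(ramp))
    stop("bathymetry lacks ground-truth attributes; supply strata explicitly")
  rug <- compute_rugosity(grid_like(bathy, pre))$values
  # cellwise baseline: the rugosity the bare (patch-free) seabed already has
  baseline <- compute_rugosity(grid_like(bathy, ramp))$values
  hard <- !is.na(rug) & !is.na(baseline) & rug > baseline * (1 + 1e-4)
  grid_like(bathy, matrix(as.numeric(hard), nrow(bathy$values)))
}

#' Shoreline and shelf-edge masks from bathymetry
#'
#' Contour-band masks: the shoreline mask holds the cells at the shallow
#' boundary (depth at or above the shore contour would lie just seaward of
#' them), the shelf mask the cells along the deep shelf-edge contour. Both
#' are binary, nonempty, aligned to the input, and disjoint on a monotone
#' shelf.
#'
#' @param bathy a depth [raster_grid].
#' @param shelf_edge_depth depth (m) of the shelf-edge contour (default 45).
#' @param shore_depth depth (m) of the shoreline contour; default is the
#'   minimum depth plus 2 percent of the depth range.
#' @return `list(shoreline = , shelf = )` of binary [raster_grid]s.
#' @export
make_masks <- function(bathy, shelf_edge_depth = 45, shore_depth = NULL) {
  stopifnot(inherits(bathy, "raster_grid"))
  v <- bathy$values
  rngv <- range(v, na.rm = TRUE)
  if (is.null(shore_depth))
    shore_depth <- rngv[1] + 0.02 * diff(rngv)
  contour_band <- function(level, side) {
    if (level < rngv[1] || level > rngv[2])
      stop(sprintf("contour at %g m is absent from the grid (depth range %g-%g m)",
                   level, rngv[1], rngv[2]))
    nb <- neigh3(v)
    if (side == "shallow") {
      onside <- !is.na(v) & v <= level
      crosses <- Reduce(`|`, lapply(nb, function(m) !is.na(m) & m > level))
    } else {
      onside <- !is.na(v) & v >= level
      crosses <- Reduce(`|`, lapply(nb, function(m) !is.na(m) & m < level))
    }
    band <- onside & crosses
    if (!any(band))
      stop(sprintf("contour at %g m is absent from the grid (depth range %g-%g m)",
                   level, rngv[1], rngv[2]))
    grid_like(bathy, matrix(as.numeric(band), nrow(v)))
  }
  list(shoreline = contour_band(shore_depth, "shallow"),
       shelf = contour_band(shelf_edge_depth, "deep"))
}

#' Stratified-random survey design
#'
#' Sites are placed at cell centers, drawn uniformly without replacement
#' within each stratum (hardbottom/softbottom), mirroring a
#' stratified-random underwater visual survey design.
#'
#' @param bathy a bathymetry [raster_grid].
#' @param n_sites total number of sites.
#' @param allocation fractions per stratum, `c(hard, soft)`; must sum to 1.
#' @param strata optional stratum [raster_grid] (1 = hard, 0 = soft);
#'   defaults to [seascape_strata()] of `bathy`.
#' @param seed integer seed.
#' @return data frame `site_id, x, y, row, col, stratum`.
#' @export
sample_survey_sites <- function(bathy, n_sites, allocation = c(0.5, 0.5),
                                strata = NULL, seed = 1) {
  stopifnot(inherits(bathy, "raster_grid"), n_sites >= 1)
  if (abs(sum(allocation) - 1) > 1e-8) stop("allocation must sum to 1")
  if (is.null(strata)) strata <- seascape_strata(bathy)
  check_aligned(list(bathy = bathy, strata = strata))
  sv <- strata$values
  valid <- which(!is.na(bathy$values) & !is.na(sv))
  n_hard <- round(n_sites * allocation[1])
  n_per <- c(hard = n_hard, soft = n_sites - n_hard)
  pools <- list(hard = valid[sv[valid] == 1], soft = valid[sv[valid] == 0])
  set.seed(seed)
  picks <- lapply(c("hard", "soft"), function(s) {
    need <- n_per[[s]]
    pool <- pools[[s]]
    if (need > 0 && length(pool) == 0)
      stop(sprintf("stratum '%s' is empty", s))
    if (need > length(pool))
      stop(sprintf("stratum '%s' has only %d cells for %d sites",
                   s, length(pool), need))
    sample(pool, need)
  })
  cells <- c(picks[[1]], picks[[2]])
  stratum <- rep(c("hard", "soft"), times = c(n_per[["hard"]], n_per[["soft"]]))
  nr <- nrow(bathy$values)
  row <- ((cells - 1L) %% nr) + 1L
  col <- ((cells - 1L) %/% nr) + 1L
  data.frame(
    site_id = seq_along(cells),
    x = bathy$origin[1] + (col - 0.5) * bathy$cell_size_m,
    y = bathy$origin[2] - (row - 0.5) * bathy$cell_size_m,
    row = row, col = col, stratum = stratum
  )
}

#' Specify a ground-truth species response
#'
#' Occurrence probability is the logistic of
#' `intercept + sum(linear) + sum(steps) + sum(interactions)` evaluated on
#' raw predictor values: linear terms are `coef * x`; step terms jump by
#' `jump` logits where `x > location` (an ecological threshold); interaction
#' terms are `coef * x1 * x2`.
#'
#' @param intercept baseline logit.
#' @param linear named numeric vector of linear coefficients (names =
#'   predictor layers).
#' @param steps named list, each element `c(location = , jump = )`.
#' @param interactions list of `list(vars = c(a, b), coef = )`.
#' @param target_prevalence optional fraction in (0, 1); when set, the
#'   intercept is solved so the mean occurrence probability over the
#'   simulated sites matches it.
#' @return A list of class `species_response`.
#' @export
species_response <- function(intercept = 0, linear = NULL, steps = NULL,
                             interactions = NULL, target_prevalence = NULL) {
  if (!is.null(target_prevalence) &&
      (target_prevalence <= 0 || target_prevalence >= 1))
    stop("target_prevalence must be in (0, 1)")
  structure(list(intercept = intercept, linear = linear, steps = steps,
                 interactions = interactions,
                 target_prevalence = target_prevalence),
            class = "species_response")
}

response_predictors <- function(response) {
  unique(c(names(response$linear), names(response$steps),
           unlist(lapply(response$interactions, `[[`, "vars"))))
}

# logit contribution of everything except the intercept
response_eta0 <- function(response, X) {
  eta <- rep(0, nrow(X))
  for (nm in names(response$linear))
    eta <- eta + response$linear[[nm]] * X[, nm]
  for (nm in names(response$steps)) {
    st <- response$steps[[nm]]
    eta <- eta + st[["jump"]] * (X[, nm] > st[["location"]])
  }
  for (it in response$interactions)
    eta <- eta + it$coef * X[, it$vars[1]] * X[, it$vars[2]]
  eta
}

#' Simulate species occurrences over a survey
#'
#' Extracts the predictor stack at the survey sites, evaluates the
#' ground-truth logit response, optionally solves the intercept so the
#' expected prevalence matches `target_prevalence` (monotone root finding),
#' and draws Bernoulli occurrences. True probabilities are retained so
#' downstream models can be checked against ground truth.
#'
#' @param stack a `predictor_stack`.
#' @param sites data frame from [sample_survey_sites()].
#' @param response a [species_response()].
#' @param seed integer seed for the Bernoulli draws.
#' @return A data frame of class `survey_set`: site columns, `present`,
#'   `true_prob`, and one column per predictor layer. Sites on nodata cells
#'   are dropped (count in attribute `n_excluded`).
#' @export
simulate_species <- function(stack, sites, response, seed = 1) {
  stopifnot(inherits(stack, "predictor_stack"),
            inherits(response, "species_response"))
  need <- response_predictors(response)
  unknown <- setdiff(need, names(stack$layers))
  if (length(unknown))
    stop("unknown predictor(s) in response: ", paste(unknown, collapse = ", "))
  X <- extract_features(stack, sites)
  kept <- attr(X, "kept")
  sites <- sites[kept, , drop = FALSE]
  eta0 <- response_eta0(response, X)
  intercept <- response$intercept
  if (!is.null(response$target_prevalence)) {
    f <- function(c0) mean(stats::plogis(c0 + eta0)) - response$target_prevalence
    intercept <- stats::uniroot(f, c(-60, 60), tol = 1e-10)$root
  }
  p <- stats::plogis(intercept + eta0)
  set.seed(seed)
  present <- stats::rbinom(length(p), 1, p)
  out <- cbind(
    sites[, c("site_id", "x", "y", "stratum")],
    data.frame(present = present, true_prob = p),
    as.data.frame(X)
  )
  rownames(out) <- NULL
  attr(out, "n_excluded") <- attr(X, "n_excluded")
  attr(out, "predictors") <- colnames(X)
  attr(out, "intercept") <- intercept
  class(out) <- c("survey_set", "data.frame")
  out
}

#' Write a survey to CSV
#'
#' Columns `site_id, x, y, stratum, present, true_prob` (plus predictors when
#' `features = TRUE`).
#'
#' @param survey a `survey_set` data frame.
#' @param path output file.
#' @param features include the predictor columns (default TRUE).
#' @return `path`, invisibly.
#' @export
write_survey_csv <- function(survey, path, features = TRUE) {
  keep <- c("site_id", "x", "y", "stratum", "present", "true_prob")
  if (features) keep <- c(keep, attr(survey, "predictors"))
  utils::write.csv(as.data.frame(survey)[, intersect(keep, names(survey))],
                   path, row.names = FALSE)
  invisible(path)
}
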