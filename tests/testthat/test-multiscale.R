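test_that("circular kernel footprints match their definitions", {
  k <- circular_kernel(5, 4)
  expect_equal(dim(k), c(3, 3))
  expect_equal(sum(k), 5)
  expect_true(k[2, 2] && k[1, 2] && k[3, 2] && k[2, 1] && k[2, 3])
  expect_false(k[1, 1])
  # sub-cell radius degenerates to the focal cell
  expect_equal(circular_kernel(2, 4), matrix(TRUE, 1, 1))
  # large radius approximates the disc area within 3%
  k300 <- circular_kernel(300, 4)
  expect_lt(abs(sum(k300) - pi * 300^2 / 16) / (pi * 300^2 / 16), 0.03)
  # quarter-turn and reflection symmetry
  expect_identical(k300, t(k300))
  expect_identical(k300, k300[nrow(k300):1, ])
})

test_that("focal mean reproduces direct summation and handles nodata", {
  set.seed(7)
  v <- matrix(rnorm(81, 10), 9, 9)
  v[c(5, 20, 40)] <- NA
  g <- raster_grid(v, 4)
  k <- circular_kernel(5, 4)
  expect_equal(focal_mean(g, k, 0.4)$values,
               oracle_focal_mean(v, k, 0.4), tolerance = 1e-9)
  # constant field is a fixed point at every radius
  cg <- raster_grid(matrix(3.5, 12, 12), 4)
  for (r in c(5, 10, 20))
    expect_equal(focal_mean(cg, circular_kernel(r, 4), 0.1)$values,
                 matrix(3.5, 12, 12), tolerance = 1e-9)
  # single-cell kernel is the identity
  expect_equal(focal_mean(g, circular_kernel(2, 4))$values, v)
  expect_error(focal_mean(g, matrix(FALSE, 1, 1)), "empty")
})

test_that("aspect focal mean averages on the circle, not the line", {
  k <- matrix(TRUE, 1, 3)
  # {350, 10} equally weighted average to 0, not 180
  g <- raster_grid(matrix(c(350, 10, NA), 1, 3), 4)
  out <- focal_mean_aspect(g, k, min_valid_fraction = 0.5)
  ang <- out$values[1, 2]
  expect_lt(min(ang, 360 - ang), 1e-6)
  uni <- raster_grid(matrix(90, 5, 5), 4)
  expect_equal(focal_mean_aspect(uni, circular_kernel(5, 4), 0.5)$values,
               matrix(90, 5, 5), tolerance = 1e-8)
  # opposing bearings cancel: no preferred direction -> nodata
  opp <- raster_grid(matrix(c(0, 180, NA), 1, 3), 4)
  expect_true(is.na(focal_mean_aspect(opp, k, 0.5)$values[1, 2]))
})

test_that("distance surface equals the exhaustive min-over-mask scan", {
  set.seed(17)
  for (rep in 1:3) {
    m <- matrix(0, 12, 12)
    m[sample(144, 5)] <- 1
    g <- raster_grid(m, 4)
    d <- distance_surface(g)
    expect_equal(d$values, oracle_distance(m, 4), tolerance = 1e-9)
  }
  # adjacency and interior values
  m <- matrix(0, 6, 6); m[3, 3] <- 1
  d <- distance_surface(raster_grid(m, 4))
  expect_equal(d$values[3, 4], 4)
  expect_equal(d$values[3, 3], 0)
  expect_error(distance_surface(raster_grid(matrix(0, 4, 4), 4)), "empty")
})

test_that("distance surfaces satisfy 8-neighbour triangle consistency", {
  set.seed(19)
  m <- matrix(0, 20, 20)
  m[sample(400, 8)] <- 1
  d <- distance_surface(raster_grid(m, 4))$values
  lim <- 4 * sqrt(2) + 1e-9
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    sh <- reefscape:::shift_mat(d, di, dj)
    expect_true(all(abs(d - sh) <= lim, na.rm = TRUE))
  }
})

test_that("predictor stacks carry the contracted layers, aligned", {
  p <- seascape_params(extent_cells = c(40, 90), n_reef_patches = 6,
                       noise_sd_m = 0.05, seed = 5)
  b <- generate_bathymetry(p)
  masks <- make_masks(b, 45)
  morph <- compute_morphometrics(b)
  s25 <- build_stack(morph, masks, radius_m = 25)
  expect_named(s25$layers,
               c("depth", "slope", "aspect", "slope_of_slope",
                 "plan_curvature", "rugosity", "dist_to_shore",
                 "dist_to_shelf"))
  stacks <- build_stacks(morph, masks, scale_config(radii_m = c(5, 25, 50)))
  # distance layers are scale-independent
  expect_identical(stacks$r5$layers$dist_to_shelf$values,
                   stacks$r50$layers$dist_to_shelf$values)
  expect_identical(stacks$r5$layers$dist_to_shore$values,
                   stacks$r25$layers$dist_to_shore$values)
  expect_true(all(stacks$r5$layers$dist_to_shore$values >= 0))
  # misalignment is caught and attributed
  bad <- masks
  bad$shelf <- raster_grid(bad$shelf$values[1:30, ], 4)
  expect_error(build_stack(morph, bad, radius_m = 5), "aligned")
})

test_that("flat terrain yields zero-slope, unit-rugosity focal layers", {
  flat <- raster_grid(matrix(10, 30, 30), 4)
  morph <- compute_morphometrics(flat)
  mask <- matrix(0, 30, 30); mask[, 1] <- 1
  mask2 <- matrix(0, 30, 30); mask2[, 30] <- 1
  st <- build_stack(morph, radius_m = 25,
                    distances = list(
                      dist_to_shore = distance_surface(raster_grid(mask, 4)),
                      dist_to_shelf = distance_surface(raster_grid(mask2, 4))))
  inner <- function(m) m[10:20, 10:20]
  expect_equal(inner(st$layers$slope$values), matrix(0, 11, 11))
  expect_equal(inner(st$layers$slope_of_slope$values), matrix(0, 11, 11))
  expect_equal(inner(st$layers$plan_curvature$values), matrix(0, 11, 11))
  expect_equal(inner(st$layers$rugosity$values), matrix(1, 11, 11))
  expect_true(all(is.na(st$layers$aspect$values)))
})

test_that("focal smoothing never increases variance on random fields", {
  set.seed(23)
  v <- matrix(rnorm(50 * 50), 50, 50)
  g <- raster_grid(v, 4)
  vars <- vapply(c(5, 25, 50, 100), function(r) {
    stats::var(as.vector(focal_mean(g, circular_kernel(r, 4), 0.5)$values),
               na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(vars) < 0))
})

test_that("feature extraction is nearest-cell with nodata exclusion", {
  p <- seascape_params(extent_cells = c(30, 60), n_reef_patches = 4,
                       noise_sd_m = 0, bank_amplitude_m = 0,
                       shore_undulation_m = 0, shelf_undulation_m = 0,
                       seed = 9)
  b <- generate_bathymetry(p)
  masks <- make_masks(b, 45)
  st <- build_stack(compute_morphometrics(b), masks, radius_m = 5)
  sites <- data.frame(x = c(100.0, 2.0), y = c(60.0, 118.0))
  X <- extract_features(st, sites)
  # first site sits at the center of cell (row 25, col 25)
  rc <- reefscape:::xy_to_rowcol(b, 100, 60)
  expect_equal(unname(X[1, "depth"]), st$layers$depth$values[rc])
  # the second site lies on the border where focal layers are nodata
  expect_equal(attr(X, "n_excluded"), 1)
  expect_equal(dim(X), c(1, 8))
  expect_error(extract_features(st, data.frame(x = -5, y = 10)), "extent")
})
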