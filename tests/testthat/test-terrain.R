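# planes and random grids with known closed forms or brute-force oracles

plane <- function(gx, gn, n = 9, cell = 4) {
  # z increases eastward by gx per meter, northward by gn per meter;
  # matrix row 1 is north
  outer(seq_len(n), seq_len(n),
        function(i, j) gx * j * cell - gn * i * cell)
}

test_that("slope is exact on flat and inclined planes", {
  flat <- raster_grid(matrix(5, 9, 9), 4)
  s <- compute_slope(flat)
  expect_equal(s$values[2:8, 2:8], matrix(0, 7, 7))
  g1 <- raster_grid(plane(1, 0), 4)
  expect_equal(compute_slope(g1)$values[5, 5], 45)
  expect_true(all(is.na(compute_slope(g1)$values[1, ])))
})

test_that("slope and aspect match the per-cell Horn oracle on random grids", {
  set.seed(11)
  for (rep in 1:3) {
    z <- matrix(rnorm(49, sd = 2), 7, 7)
    g <- raster_grid(z, 4)
    o <- oracle_horn(z, 4)
    expect_equal(compute_slope(g)$values, o$slope, tolerance = 1e-9)
    expect_equal(compute_aspect(g)$values, o$aspect, tolerance = 1e-9)
  }
})

test_that("aspect follows the compass convention and is nodata when flat", {
  east_dip <- raster_grid(plane(-1, 0), 4)   # z falls toward east
  expect_equal(compute_aspect(east_dip)$values[5, 5], 90)
  north_dip <- raster_grid(plane(0, -1), 4)  # z falls toward north
  expect_equal(compute_aspect(north_dip)$values[5, 5], 0)
  flat <- raster_grid(matrix(1, 9, 9), 4)
  expect_true(all(is.na(compute_aspect(flat)$values)))
})

test_that("rotating the grid a quarter turn rotates aspect by 90 degrees", {
  set.seed(3)
  z <- outer(1:9, 1:9, function(i, j)
    sin(i / 2) + cos(j / 3)) + matrix(rnorm(81, sd = 0.05), 9, 9)
  a1 <- compute_aspect(raster_grid(z, 4))$values
  # rotate surface 90 degrees clockwise: new[i,j] = old[n+1-j, i]
  zr <- t(z)[, nrow(z):1]
  a2 <- compute_aspect(raster_grid(zr, 4))$values
  n <- nrow(z)
  for (i in 3:(n - 2)) for (j in 3:(n - 2)) {
    expect_equal(a2[j, n + 1 - i] %% 360, (a1[i, j] + 90) %% 360,
                 tolerance = 1e-8)
  }
})

test_that("rugosity is 1 on flat terrain and 1/cos(theta) on planes", {
  flat <- raster_grid(matrix(2, 9, 9), 4)
  expect_equal(compute_rugosity(flat)$values[2:8, 2:8], matrix(1, 7, 7))
  for (gr in c(0.25, 1, 2)) {
    g <- raster_grid(plane(gr, 0), 4)
    expect_equal(compute_rugosity(g)$values[5, 5], 1 / cos(atan(gr)),
                 tolerance = 1e-6)
  }
})

test_that("rugosity matches the independent Heron-triangulation oracle", {
  set.seed(21)
  z <- matrix(rnorm(49, sd = 3), 7, 7)
  g <- raster_grid(z, 4)
  expect_equal(compute_rugosity(g)$values, oracle_rugosity(z, 4),
               tolerance = 1e-9)
  expect_true(all(compute_rugosity(g)$values >= 1, na.rm = TRUE))
})

test_that("slope of slope is zero on planes and equals double application", {
  g <- raster_grid(plane(0.5, 0.3), 4)
  ss <- compute_slope_of_slope(g)
  expect_equal(ss$values[3:7, 3:7], matrix(0, 5, 5), tolerance = 1e-9)
  # Gaussian bump: composition oracle
  z <- outer(-5:5, -5:5, function(i, j) 10 * exp(-(i^2 + j^2) / 8))
  gb <- raster_grid(z, 4)
  direct <- compute_slope_of_slope(gb)
  manual <- compute_slope(compute_slope(gb))
  expect_identical(direct$values, manual$values)
  slope1 <- compute_slope(gb)$values
  o <- oracle_horn(slope1, 4)
  expect_equal(direct$values, o$slope, tolerance = 1e-9)
})

test_that("plan curvature: planes flat, bumps convex-negative, bowl analytic", {
  g <- raster_grid(plane(1, 2), 4)
  expect_equal(compute_plan_curvature(g)$values[3:7, 3:7],
               matrix(0, 5, 5), tolerance = 1e-9)
  # convex Gaussian bump: flanks must be negative per the sign convention
  z <- outer(-6:6, -6:6, function(i, j) 8 * exp(-(i^2 + j^2) / 10))
  pc <- compute_plan_curvature(raster_grid(z, 2))$values
  expect_lt(pc[7, 10], 0)
  expect_lt(pc[4, 7], 0)
  # quadratic bowl z = x^2 + y^2: transverse curvature is exactly 2 1/m
  zb <- outer(-4:4, -4:4, function(i, j) i^2 + j^2)
  pb <- compute_plan_curvature(raster_grid(zb, 1))$values
  expect_equal(pb[3, 5], 2, tolerance = 1e-9)  # off-center flank cell
  expect_equal(pb[7, 7], 2, tolerance = 1e-9)
})

test_that("compute_morphometrics equals its component operators and aligns", {
  set.seed(31)
  z <- matrix(rnorm(100, 20, 3), 10, 10)
  g <- raster_grid(z, 4, origin = c(50, 90))
  m <- compute_morphometrics(g)
  expect_named(m, c("depth", "slope", "aspect", "slope_of_slope",
                    "plan_curvature", "rugosity"))
  expect_identical(m$depth$values, z)
  expect_identical(m$slope$values, compute_slope(g)$values)
  expect_identical(m$aspect$values, compute_aspect(g)$values)
  expect_identical(m$rugosity$values, compute_rugosity(g)$values)
  expect_identical(m$plan_curvature$values, compute_plan_curvature(g)$values)
  for (l in m) {
    expect_equal(dim(l$values), c(10, 10))
    expect_equal(l$origin, c(50, 90))
    expect_equal(l$cell_size_m, 4)
  }
})

test_that("adding a constant to depth changes only the depth layer", {
  set.seed(41)
  z <- matrix(rnorm(64, 10), 8, 8)
  m1 <- compute_morphometrics(raster_grid(z, 4))
  m2 <- compute_morphometrics(raster_grid(z + 7.5, 4))
  expect_equal(m2$depth$values, z + 7.5)
  for (nm in c("slope", "aspect", "slope_of_slope", "plan_curvature",
               "rugosity"))
    expect_equal(m1[[nm]]$values, m2[[nm]]$values, tolerance = 1e-9)
})

test_that("doubling elevations maps plane slope theta to atan(2 tan theta)", {
  for (gr in c(0.2, 0.7, 1.5)) {
    s1 <- compute_slope(raster_grid(plane(gr, 0), 4))$values[5, 5]
    s2 <- compute_slope(raster_grid(2 * plane(gr, 0), 4))$values[5, 5]
    expect_equal(s2, atan(2 * tan(s1 * pi / 180)) * 180 / pi,
                 tolerance = 1e-9)
  }
})

test_that("operators are nodata-closed: masked regions never leak values", {
  set.seed(51)
  z <- matrix(rnorm(121, 15), 11, 11)
  z[5, 6] <- NA
  g <- raster_grid(z, 4)
  for (op in list(compute_slope, compute_aspect, compute_rugosity,
                  compute_plan_curvature)) {
    out <- op(g)$values
    # every cell whose 3x3 support touches the hole must be nodata
    expect_true(all(is.na(out[4:6, 5:7])))
  }
  ss <- compute_slope_of_slope(g)$values
  expect_true(all(is.na(ss[3:7, 4:8])))
  expect_error(compute_slope(raster_grid(matrix(NA_real_, 5, 5), 4)),
               "valid")
  expect_error(compute_slope(raster_grid(matrix(1, 2, 2), 4)), "3x3")
})
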