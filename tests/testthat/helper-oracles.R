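# Independent brute-force oracles for the terrain and focal operators.
# These deliberately re-derive every quantity cell by cell with explicit
# loops, sharing no code with the package implementations.

# Horn slope/aspect by direct per-cell evaluation; returns degrees
oracle_horn <- function(z, cell) {
  nr <- nrow(z); nc <- ncol(z)
  slope <- matrix(NA_real_, nr, nc)
  aspect <- matrix(NA_real_, nr, nc)
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    w <- z[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (anyNA(w)) next
    # rows of w run north -> south, columns west -> east
    dzdx <- ((w[1, 3] + 2 * w[2, 3] + w[3, 3]) -
             (w[1, 1] + 2 * w[2, 1] + w[3, 1])) / (8 * cell)
    dzdn <- ((w[1, 1] + 2 * w[1, 2] + w[1, 3]) -
             (w[3, 1] + 2 * w[3, 2] + w[3, 3])) / (8 * cell)
    slope[i, j] <- atan(sqrt(dzdx^2 + dzdn^2)) * 180 / pi
    if (dzdx != 0 || dzdn != 0)
      aspect[i, j] <- (atan2(-dzdx, -dzdn) * 180 / pi) %% 360
  }
  list(slope = slope, aspect = aspect)
}

# Jenness-style rugosity: 8 triangles between consecutive half-way edge
# points, areas via Heron's formula (different route than the cross product)
oracle_rugosity <- function(z, cell) {
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_real_, nr, nc)
  # neighbour (drow, dcol) offsets in cyclic compass order starting north
  off <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
              c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  heron <- function(a, b, c) {
    s <- (a + b + c) / 2
    sqrt(max(s * (s - a) * (s - b) * (s - c), 0))
  }
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    w <- z[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (anyNA(w)) next
    z0 <- z[i, j]
    pts <- lapply(off, function(o) {
      zk <- z[i + o[1], j + o[2]]
      # (x east, y north, z up): matrix row +1 is one cell south
      c(o[2] * cell / 2, -o[1] * cell / 2, (zk - z0) / 2)
    })
    area <- 0
    for (k in 1:8) {
      p1 <- pts[[k]]; p2 <- pts[[(k %% 8) + 1]]
      a <- sqrt(sum(p1^2))
      b <- sqrt(sum(p2^2))
      cc <- sqrt(sum((p1 - p2)^2))
      area <- area + heron(a, b, cc)
    }
    out[i, j] <- area / cell^2
  }
  out
}

# focal mean by explicit summation over kernel offsets
oracle_focal_mean <- function(v, kernel, min_valid_fraction) {
  nr <- nrow(v); nc <- ncol(v)
  kr <- (nrow(kernel) - 1) / 2; kc <- (ncol(kernel) - 1) / 2
  out <- matrix(NA_real_, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    if (is.na(v[i, j])) next
    vals <- c()
    for (di in -kr:kr) for (dj in -kc:kc) {
      if (!kernel[di + kr + 1, dj + kc + 1]) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && !is.na(v[ii, jj]))
        vals <- c(vals, v[ii, jj])
    }
    if (length(vals) / sum(kernel) >= min_valid_fraction)
      out[i, j] <- mean(vals)
  }
  out
}

# exhaustive min-over-mask-cells Euclidean distance scan
oracle_distance <- function(mask, cell) {
  nr <- nrow(mask); nc <- ncol(mask)
  tgt <- which(mask == 1, arr.ind = TRUE)
  out <- matrix(NA_real_, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    out[i, j] <- cell * sqrt(min((tgt[, 1] - i)^2 + (tgt[, 2] - j)^2))
  }
  out
}

# 8-connected component count of a binary matrix (flood fill)
component_count <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  k <- 0L
  for (s in which(m == 1)) {
    if (lab[s] > 0L) next
    k <- k + 1L
    queue <- s
    lab[s] <- k
    nr <- nrow(m)
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      i <- ((cur - 1L) %% nr) + 1L; j <- ((cur - 1L) %/% nr) + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > nr || jj < 1 || jj > ncol(m)) next
        id <- (jj - 1L) * nr + ii
        if (m[id] == 1 && lab[id] == 0L) { lab[id] <- k; queue <- c(queue, id) }
      }
    }
  }
  k
}

# shared moderately structured seascape fixture for model-level tests:
# a species with a strong cross-shelf step and a topography effect
make_structured_case <- function(n_sites = 1000, seed = 42,
                                 extent = c(200, 1500), radius = 25) {
  p <- seascape_params(extent_cells = extent, n_reef_patches = 120,
                       patch_amplitude_m = 6, patch_width_m = 40,
                       noise_sd_m = 0.1, bank_amplitude_m = 6,
                       undulation_wavelength_m = 400, seed = seed)
  b <- generate_bathymetry(p)
  masks <- make_masks(b, 45)
  morph <- compute_morphometrics(b)
  stack <- build_stack(morph, masks, radius_m = radius)
  sites <- sample_survey_sites(b, n_sites, seed = seed + 1)
  resp <- species_response(
    steps = list(dist_to_shelf = c(location = 2000, jump = -8)),
    linear = c(slope_of_slope = 0.6),
    target_prevalence = 0.08)
  survey <- simulate_species(stack, sites, resp, seed = seed + 2)
  X <- as.matrix(as.data.frame(survey)[, attr(survey, "predictors")])
  list(bathy = b, masks = masks, stack = stack, sites = sites,
       response = resp, survey = survey, X = X, y = survey$present)
}
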