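two_site_model <- function() {
  site_model(label = 1:2, role = c("CA", "CA"),
             coords = rbind(c(0, 0, 0), c(10, 0, 0)), domain_ranges = list())
}

block_gamma <- function(off) {
  g <- diag(6)
  g[1:3, 4:6] <- off
  g[4:6, 1:3] <- t(off)
  g
}

test_that("cross-correlation maps attain their analytic extremes", {
  sm <- two_site_model()
  co <- ref_coords(sm)
  expect_equal(dccm(covariance_model(block_gamma(diag(3)), co, sm))$matrix[1, 2], 1)
  expect_equal(dccm(covariance_model(block_gamma(-diag(3)), co, sm))$matrix[1, 2], -1)
  expect_equal(dccm(covariance_model(block_gamma(matrix(0, 3, 3)), co, sm))$matrix[1, 2], 0)
  # coupled but orthogonal displacements are invisible to the DCCM
  rot90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3)
  expect_equal(dccm(covariance_model(block_gamma(rot90), co, sm))$matrix[1, 2],
               1 / 3)  # only the z-z component survives the trace
})

test_that("zero-fluctuation sites are reported by label", {
  sm <- two_site_model()
  g <- diag(c(1, 1, 1, 0, 0, 0))
  expect_error(dccm(covariance_model(g, ref_coords(sm), sm)), "2")
})

test_that("covariance estimators differ only by the n/(n-1) factor", {
  sm <- helix_model(6)
  set.seed(31)
  co <- array(rnorm(6 * 3 * 40, sd = 0.5), dim = c(6, 3, 40)) +
    array(ref_coords(sm), dim = c(6, 3, 40))
  e <- ensemble(co, sm)
  ml <- covariance(e, align = FALSE, estimator = "ml")
  ub <- covariance(e, align = FALSE, estimator = "unbiased")
  expect_equal(ub$gamma, ml$gamma * 40 / 39, tolerance = 1e-12)
  expect_error(covariance(subset_ensemble(e, 1:6), align = FALSE), NA)
})

test_that("principal components are orthonormal and ordered by variance", {
  sm <- helix_model(8)
  set.seed(32)
  co <- array(rnorm(8 * 3 * 60, sd = 0.3), dim = c(8, 3, 60)) +
    array(ref_coords(sm), dim = c(8, 3, 60))
  cov <- covariance(ensemble(co, sm), align = FALSE)
  tab <- pca(cov, 10)
  V <- attr(tab, "vectors")
  expect_equal(crossprod(V), diag(10), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(tab$eigenvalue) <= 1e-12))
  expect_equal(pca(cov, 24)$cumulative_fraction[24], 1, tolerance = 1e-8)
  expect_error(pca(cov, 25), "exceeds")
})

test_that("projection recovers a scripted collective coordinate", {
  sm <- two_site_model()
  v <- rep(1 / sqrt(6), 6)                    # unit 6-vector
  a <- seq(-2, 2, length.out = 9)             # scripted amplitudes
  mu <- ref_coords(sm)
  gamma <- mean(a^2) * outer(v, v)
  cov <- covariance_model(gamma, mu, sm)
  xyz <- sweep(outer(a, v), 2, as.vector(t(mu)), "+")
  e <- ensemble(xyz_to_frames(xyz), sm)
  p <- project(e, cov, 1, align = FALSE)
  # eigenvector sign is arbitrary
  expect_equal(abs(p$values), abs(a), tolerance = 1e-10)
  expect_equal(p$variance_fraction, 1, tolerance = 1e-12)
})

test_that("projected variance equals the covariance eigenvalue", {
  sm <- helix_model(7)
  set.seed(33)
  co <- array(rnorm(7 * 3 * 80, sd = 0.4), dim = c(7, 3, 80)) +
    array(ref_coords(sm), dim = c(7, 3, 80))
  e <- ensemble(co, sm)
  cov <- covariance(e, align = FALSE)
  p <- project(e, cov, 1, align = FALSE)
  expect_equal(p$variance, cov$evalues[1], tolerance = 1e-8)
})

test_that("cosine content is exact on half-period harmonics", {
  n <- 400
  t <- (seq_len(n) - 0.5) / n
  expect_equal(cosine_content(cos(pi * t)), 1, tolerance = 1e-12)
  expect_equal(cosine_content(cos(2 * pi * t)), 0, tolerance = 1e-12)
  expect_equal(cosine_content(cos(2 * pi * t), k = 2), 1, tolerance = 1e-12)
  expect_error(cosine_content(rep(3, 10)), "zero-variance")
  expect_error(cosine_content(1), "at least 2")
})

test_that("diffusive sampling scores high cosine content on PC1", {
  # the classic convergence diagnostic: PC1 of an unconverged random walk
  # looks like a half-period cosine
  sm <- helix_model(15)
  set.seed(34)
  steps <- array(rnorm(15 * 3 * 300, sd = 0.1), dim = c(15, 3, 300))
  co <- array(ref_coords(sm), dim = c(15, 3, 300)) +
    aperm(apply(steps, c(1, 2), cumsum), c(2, 3, 1))
  e <- ensemble(co, sm)
  cov <- covariance(e, align = FALSE)
  walk <- project(e, cov, 1, align = FALSE)$cosine_content
  expect_gt(walk, 0.5)
  # well-sampled harmonic fluctuations score low
  set.seed(35)
  co2 <- array(rnorm(15 * 3 * 300, sd = 0.1), dim = c(15, 3, 300)) +
    array(ref_coords(sm), dim = c(15, 3, 300))
  iid <- project(ensemble(co2, sm), covariance(ensemble(co2, sm), align = FALSE),
                 1, align = FALSE)$cosine_content
  expect_lt(iid, 0.1)
})

test_that("uniform occupancy yields a flat zero free-energy surface", {
  x <- rep(1:4, each = 4)
  y <- rep(1:4, times = 4)
  fel <- free_energy_landscape(x, y, n_bins = 4)
  expect_true(all(fel$free_energy[!fel$mask] == 0))
  expect_false(any(fel$mask))
  expect_identical(sum(fel$counts), 16L)
})

test_that("free energy reflects log population ratios and masks empty bins", {
  x <- c(rep(0, 30), rep(10, 10))
  y <- rep(0, 40)
  fel <- free_energy_landscape(x, y, n_bins = 4, kT = 2)
  occ <- sort(fel$free_energy[!fel$mask])
  expect_equal(occ, c(0, 2 * log(3)), tolerance = 1e-12)
  expect_identical(sum(fel$mask), 14L)
})

test_that("watershed basin detection separates, merges and thresholds", {
  fe <- matrix(2, 5, 5)
  fe[2, 2] <- 0; fe[2, 3] <- 0.5; fe[4, 4] <- 0.7
  surf <- structure(list(x_edges = 0:5, y_edges = 0:5, free_energy = fe,
                         mask = matrix(FALSE, 5, 5), kT = 1,
                         counts = matrix(1L, 5, 5)),
                    class = "free_energy_surface")
  b <- detect_basins(surf)
  expect_identical(nrow(b), 2L)
  expect_equal(b$min_free_energy, c(0, 0.7))
  asg <- attr(b, "assignment")
  expect_identical(asg[2, 2], 1L)
  expect_identical(asg[2, 3], 1L)
  expect_identical(asg[4, 4], 2L)
  # a barrier of 2 - 0.7 = 1.3 is below a 1.5 persistence threshold
  expect_identical(nrow(detect_basins(surf, merge_barrier = 1.5)), 1L)
  # minima shallower than the seeding threshold never found basins
  expect_identical(nrow(detect_basins(surf, depth_threshold = 0.5)), 1L)
})

test_that("a flat surface is reported as one degenerate basin", {
  fe <- matrix(0, 3, 3)
  surf <- structure(list(x_edges = 0:3, y_edges = 0:3, free_energy = fe,
                         mask = matrix(FALSE, 3, 3), kT = 1,
                         counts = matrix(1L, 3, 3)),
                    class = "free_energy_surface")
  b <- detect_basins(surf)
  expect_identical(nrow(b), 1L)
  expect_true(attr(b, "degenerate"))
})

test_that("porcupine arrows are the scaled eigenvector segments", {
  sm <- two_site_model()
  v <- c(1, 0, 0, 0, 0, 0)       # only site 1 moves, along x
  cov <- covariance_model(4 * outer(v, v) + 1e-6 * diag(6), ref_coords(sm), sm)
  arr <- porcupine_vectors(cov, 1, scale = 5)
  expect_identical(arr$site, 1L)
  expect_equal(abs(arr$dx), 5, tolerance = 1e-4)
  expect_equal(arr$length, 5, tolerance = 1e-4)
  expect_identical(nrow(porcupine_vectors(cov, 1, scale = 5, min_length = 6)), 0L)

  path <- withr::local_tempfile(fileext = ".pdb")
  write_porcupine_pdb(arr, path)
  lines <- readLines(path)
  expect_identical(sum(grepl("^MODEL", lines)), 2L)
  tail_xyz <- as.numeric(c(substr(lines[2], 31, 38), substr(lines[2], 39, 46),
                           substr(lines[2], 47, 54)))
  tip_xyz <- as.numeric(c(substr(lines[5], 31, 38), substr(lines[5], 39, 46),
                          substr(lines[5], 47, 54)))
  expect_equal(tip_xyz - tail_xyz, c(arr$dx, arr$dy, arr$dz), tolerance = 1e-3)
})

test_that("map differences require matching shapes and orderings", {
  sm <- two_site_model()
  a <- dccm(covariance_model(block_gamma(diag(3)), ref_coords(sm), sm))
  b <- dccm(covariance_model(block_gamma(-diag(3)), ref_coords(sm), sm))
  d <- map_difference(a, b)
  expect_equal(d[1, 2], 2)
  expect_equal(diag(d), c(0, 0), ignore_attr = TRUE)
  expect_error(map_difference(a$matrix, matrix(0, 3, 3)), "shape")
  m2 <- a$matrix
  dimnames(m2) <- list(c("CA:2", "CA:1"), c("CA:2", "CA:1"))
  expect_error(map_difference(a$matrix, m2), "ordering")
})
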