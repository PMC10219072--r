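test_that("superposition recovers a known rigid transform", {
  set.seed(21)
  A <- matrix(rnorm(30, sd = 8), 10, 3)
  R <- rand_rotation()
  t0 <- c(3, -7, 2)
  B <- sweep(A %*% t(R), 2, t0, "+")
  fit <- superpose(A, B)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(fit$coords, B, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
})

test_that("superposition never resorts to an improper rotation", {
  set.seed(22)
  A <- matrix(rnorm(24, sd = 5), 8, 3)
  mirrored <- A %*% diag(c(-1, 1, 1))   # chirality flipped
  fit <- superpose(A, mirrored)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_gt(fit$rmsd, 0.1)
})

test_that("degenerate fit sets are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "collinear")
  expect_error(superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
})

test_that("RMSD is zero against the frame that defines the reference", {
  sm <- helix_model(10)
  co <- array(0, dim = c(10, 3, 3))
  set.seed(23)
  for (i in 1:3) co[, , i] <- ref_coords(sm) + rnorm(30, sd = i - 1)
  e <- ensemble(co, sm)
  rs <- rmsd_series(e)
  expect_equal(rs$value[1], 0, tolerance = 1e-10)
  expect_true(all(diff(rs$value) > 0))
})

test_that("rigid tumbling leaves no residual fluctuation after alignment", {
  sm <- helix_model(12)
  base <- ref_coords(sm)
  co <- array(0, dim = c(12, 3, 8))
  set.seed(24)
  for (i in 1:8)
    co[, , i] <- sweep(base %*% t(rand_rotation()), 2, rnorm(3, sd = 10), "+")
  e <- ensemble(co, sm)
  r <- rmsf(e, align_first = TRUE)
  expect_lt(max(r$rmsf), 1e-8)
  # without alignment the tumbling dominates
  expect_gt(max(rmsf(e, align_first = FALSE)$rmsf), 1)
})

test_that("radius of gyration matches hand-computed geometries", {
  sq <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0))
  expect_equal(radius_of_gyration(sq), sqrt(2), tolerance = 1e-12)
  # mass weighting pulls Rg toward the heavy site
  co <- rbind(c(0, 0, 0), c(10, 0, 0))
  expect_equal(radius_of_gyration(co), 5, tolerance = 1e-12)
  expect_equal(radius_of_gyration(co, mass = c(3, 1)),
               sqrt((3 * 2.5^2 + 1 * 7.5^2) / 4), tolerance = 1e-12)
  expect_error(radius_of_gyration(co, mass = c(0, 0)), "mass")
})

test_that("the H-bond criterion is inclusive at both thresholds", {
  hb <- function(d, ang_deg) {
    a <- ang_deg * pi / 180
    detect_hbond(c(0, 0, 0), c(cos(a), sin(a), 0), c(d, 0, 0))
  }
  expect_true(hb(3.5, 30))     # both limits exactly met
  expect_true(hb(2.8, 0))
  expect_false(hb(3.51, 0))
  expect_false(hb(2.8, 30.5))
  expect_error(detect_hbond(c(0, 0, 0), c(0, 0, 0), c(3, 0, 0)), "coincide")
  expect_error(hbond_criterion(d_max = -1))
})

test_that("occupancy equals the scripted bonded fraction", {
  e <- script_hbond_trace(160, 0.35, seed = 8)
  rec <- hbond_occupancy(e, 1, 2, 3)
  expect_identical(rec$occupancy, mean(attr(e, "bonded")))
  expect_identical(rec$per_frame, attr(e, "bonded"))
  expect_identical(rec$occupancy, round(0.35 * 160) / 160)
})

test_that("salt-bridge scan reports pairs by occupancy threshold", {
  sm <- site_model(label = c(1, 2, 3), role = rep("CA", 3),
                   coords = rbind(c(0, 0, 0), c(3, 0, 0), c(20, 0, 0)),
                   domain_ranges = list())
  n <- 10L
  co <- array(0, dim = c(3, 3, n))
  for (i in seq_len(n)) {
    co[1, , i] <- c(0, 0, 0)
    co[2, , i] <- c(if (i <= 6) 3.5 else 8, 0, 0)  # 60% within 4.0 A
    co[3, , i] <- c(20, 0, 0)
  }
  e <- ensemble(co, sm)
  recs <- salt_bridge_scan(e, basic_labels = 1, acidic_labels = c(2, 3))
  expect_length(recs, 1L)
  expect_identical(recs[[1]]$occupancy, 0.6)
  all_pairs <- attr(recs, "all_pairs")
  expect_identical(nrow(all_pairs), 2L)
  expect_identical(all_pairs$occupancy, c(0.6, 0))
  expect_error(salt_bridge_scan(e, integer(0), 2), "non-empty")
})

test_that("distance series distinguish centroid and closest-approach modes", {
  sm <- site_model(label = 1:4, role = rep("CA", 4),
                   coords = rbind(c(0, 0, 0), c(2, 0, 0),
                                  c(10, 0, 0), c(14, 0, 0)),
                   domain_ranges = list(A = c(1, 2), B = c(3, 4)))
  e <- ensemble(array(ref_coords(sm), dim = c(4, 3, 2)), sm)
  cen <- distance_series(e, "A", "B", mode = "centroid")
  expect_equal(cen$value, rep(11, 2), tolerance = 1e-12)
  mn <- distance_series(e, "A", "B", mode = "min")
  expect_equal(mn$value, rep(8, 2), tolerance = 1e-12)
})

test_that("moving averages are centred, length-preserving and exact", {
  x <- c(1, 2, 3, 4, 5)
  expect_identical(moving_average(x, 1), x)
  m3 <- moving_average(x, 3)
  expect_equal(m3, c(1.5, 2, 3, 4, 4.5))   # shrinking edge windows
  expect_equal(moving_average(rep(7, 20), 6), rep(7, 20))
  # a linear ramp is invariant in the interior under a centred window
  r <- moving_average(1:10, 5)
  expect_equal(r[3:8], 3:8)
  expect_error(moving_average(x, 9), "exceeds")
})

test_that("iterative mean alignment is idempotent on aligned data", {
  sm <- helix_model(9)
  set.seed(26)
  co <- array(rnorm(9 * 3 * 6, sd = 0.2), dim = c(9, 3, 6)) +
    array(ref_coords(sm), dim = c(9, 3, 6))
  e <- align_ensemble(ensemble(co, sm))
  e2 <- align_ensemble(e)
  expect_equal(e2$coords, e$coords, tolerance = 1e-8)
  expect_true(e$aligned)
})
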