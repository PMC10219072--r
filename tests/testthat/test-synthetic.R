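test_that("the synthetic reference reproduces the coarse architecture", {
  spec <- synthetic_spec()
  sm <- make_reference(spec)
  expect_s3_class(sm, "site_model")
  expect_identical(nrow(sm), 354L)
  expect_identical(sum(sm$role == "CA"), 326L)
  expect_identical(sum(sm$role == "P"), 28L)
  expect_identical(range(sm$label[sm$role == "CA"]), c(10L, 335L))
  counts <- table(sm$domain)
  expect_identical(as.integer(counts[c("LYASE", "D", "C", "N", "LINKER", "DNA")]),
                   c(78L, 61L, 110L, 75L, 2L, 28L))

  co <- ref_coords(sm)
  ca <- co[sm$role == "CA", ]
  bond_ca <- sqrt(rowSums((ca[-1, ] - ca[-nrow(ca), ])^2))
  expect_equal(bond_ca, rep(spec$ca_bond, nrow(ca) - 1), tolerance = 1e-8)
  p <- co[sm$role == "P", ]
  bond_p <- sqrt(rowSums((p[-1, ] - p[-nrow(p), ])^2))
  expect_equal(bond_p, rep(spec$p_bond, nrow(p) - 1), tolerance = 1e-8)
})

test_that("self-avoidance keeps non-bonded sites separated", {
  sm <- make_reference(synthetic_spec(seed = 5L))
  co <- ref_coords(sm)
  d <- as.matrix(dist(co))
  diag(d) <- Inf
  # bonded neighbours along each chain may sit at the bond length;
  # every other pair must respect the 3.0 A exclusion
  chain_pairs <- cbind(seq_len(nrow(co) - 1L), seq_len(nrow(co) - 1L) + 1L)
  d[chain_pairs] <- Inf
  d[chain_pairs[, 2:1]] <- Inf
  expect_gte(min(d), 3.0)
})

test_that("reference generation is seed-deterministic", {
  a <- make_reference(synthetic_spec(seed = 9L))
  b <- make_reference(synthetic_spec(seed = 9L))
  c <- make_reference(synthetic_spec(seed = 10L))
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(ref_coords(a), ref_coords(c))))
})

test_that("seeded generators do not disturb the caller's RNG stream", {
  set.seed(321)
  before <- rnorm(1)
  set.seed(321)
  invisible(make_reference(synthetic_spec(n_protein_sites = 20L,
                                          n_dna_sites = 0L,
                                          domain_ranges = list())))
  after <- rnorm(1)
  expect_identical(before, after)
})

test_that("contact rewiring edits exactly the listed pairs", {
  sm <- make_reference(synthetic_spec())
  contacts <- contacts_from_coords(ref_coords(sm), 12)
  lock <- perturbation_spec(removed_contacts = list(),
                            added_contacts = list(c(44, 335)))
  wt <- apply_perturbation(contacts, lock, sm)
  expect_identical(nrow(wt), nrow(contacts) + 1L)

  ph <- apply_perturbation(wt, perturbation_spec(), sm)
  i44 <- site_index(sm, 44); i335 <- site_index(sm, 335); i149 <- site_index(sm, 149)
  key <- paste(ph$a, ph$b)
  expect_false(paste(min(i44, i335), max(i44, i335)) %in% key)
  expect_true(paste(min(i44, i149), max(i44, i149)) %in% key)
  expect_identical(nrow(ph), nrow(wt))

  expect_error(apply_perturbation(
    contacts, perturbation_spec(removed_contacts = list(c(44, 335)),
                                added_contacts = list()), sm),
    "not present")

  # re-adding an existing contact only rescales its spring
  soft <- apply_perturbation(
    ph, perturbation_spec(removed_contacts = list(),
                          added_contacts = list(c(44, 149)),
                          spring_scale = 0.25), sm)
  expect_identical(nrow(soft), nrow(ph))
  expect_identical(soft$scale[soft$a == min(i44, i149) &
                                soft$b == max(i44, i149)], 0.25)
})

test_that("elastic-network sampling anchors at the reference and is seeded", {
  sm <- helix_model(30)
  anm <- build_anm(sm, cutoff = 8)
  rigid <- sample_anm_ensemble(anm, 5, kT = 0, seed = 1)
  expect_equal(rigid$coords[, , 3], ref_coords(sm), ignore_attr = TRUE)

  e1 <- sample_anm_ensemble(anm, 200, kT = 0.5, seed = 7)
  e2 <- sample_anm_ensemble(anm, 200, kT = 0.5, seed = 7)
  e3 <- sample_anm_ensemble(anm, 200, kT = 0.5, seed = 8)
  expect_identical(e1$coords, e2$coords)
  expect_false(identical(e1$coords, e3$coords))
  mean_dev <- apply(e1$coords, c(1, 2), mean) - ref_coords(sm)
  expect_lt(max(abs(mean_dev)), 0.5)
})

test_that("the open state swings the lyase toward the catalytic core rigidly", {
  sm <- make_reference(synthetic_spec())
  open <- open_state_coords(sm)
  closed <- ref_coords(sm)
  idx_ly <- select_sites(sm, "LYASE")
  idx_c <- select_sites(sm, "C")
  gap <- function(co) sqrt(sum((colMeans(co[idx_ly, , drop = FALSE]) -
                                  colMeans(co[idx_c, , drop = FALSE]))^2))
  expect_lt(gap(open), gap(closed) - 3)
  # only the rotated selection moves
  still <- setdiff(seq_len(nrow(sm)), idx_ly)
  expect_identical(open[still, ], closed[still, ])
  # the swing is rigid: internal lyase geometry is preserved
  expect_equal(as.vector(dist(open[idx_ly, ])),
               as.vector(dist(closed[idx_ly, ])), tolerance = 1e-9)
})

test_that("two-basin mixtures record their ground-truth assignments", {
  sm <- helix_model(12)
  ref1 <- ref_coords(sm)
  ref2 <- ref1 + matrix(rep(c(30, 0, 0), each = 12), 12, 3)
  e <- sample_two_state(list(ref1, ref2), sm, weights = c(0.7, 0.3),
                        jitter = 0.2, n_frames = 400, seed = 2)
  basin <- attr(e, "basin")
  expect_identical(length(basin), 400L)
  # each frame sits nearest the reference it was drawn from
  for (i in c(1, 100, 400)) {
    d1 <- sum((e$coords[, , i] - ref1)^2)
    d2 <- sum((e$coords[, , i] - ref2)^2)
    expect_identical(basin[i], if (d1 < d2) 1L else 2L)
  }
  expect_lt(abs(mean(basin == 2) - 0.3), 0.1)
})

test_that("ANM two-basin mixtures preserve within-basin fluctuations", {
  sm <- helix_model(20)
  anm <- build_anm(sm, cutoff = 8)
  ref1 <- ref_coords(sm)
  ref2 <- ref1 + matrix(rep(c(40, 0, 0), each = 20), 20, 3)
  e <- sample_two_state_anm(anm, list(ref1, ref2), weights = c(0.5, 0.5),
                            n_frames = 500, kT = 0.2, seed = 3)
  basin <- attr(e, "basin")
  # re-anchoring is exact: subtracting the basin reference leaves pure
  # elastic fluctuations, identical in law across basins
  fl <- sample_anm_ensemble(anm, 500, kT = 0.2, seed = 3)
  for (i in c(2, 250, 500))
    expect_equal(e$coords[, , i] - (if (basin[i] == 1L) ref1 else ref2),
                 fl$coords[, , i] - ref1, tolerance = 1e-12,
                 ignore_attr = TRUE)
})

test_that("scripted hydrogen-bond traces have exact bonded counts", {
  e <- script_hbond_trace(200, 0.25, seed = 6)
  bonded <- attr(e, "bonded")
  expect_identical(sum(bonded), 50L)
  expect_error(
    script_hbond_trace(10, 0.5,
                       geometry_in = rbind(c(0, 0, 0), c(1, 0, 0),
                                           c(4.5, 0, 0))),
    "does not satisfy")
  expect_error(
    script_hbond_trace(10, 0.5,
                       geometry_out = rbind(c(0, 0, 0), c(1, 0, 0),
                                            c(3.2, 0.4, 0))),
    "satisfies")
})
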