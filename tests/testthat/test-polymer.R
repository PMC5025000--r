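test_that("bending energy matches the discrete worm-like-chain form", {
  rod <- straight_chain(10, 1)
  expect_equal(bending_energy(rod, g = 2), -2 * 8)

  # all right angles: every cosine vanishes
  expect_equal(bending_energy(zigzag_chain(12), g = 3.7), 0)

  # random chain vs angle-by-angle brute force
  set.seed(11)
  co <- matrix(rnorm(15), 5, 3)
  g <- 1.3
  brute <- 0
  for (i in 2:4) {
    u <- co[i, ] - co[i - 1, ]
    v <- co[i + 1, ] - co[i, ]
    brute <- brute - g * sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  }
  expect_equal(bending_energy(co, g), brute, tolerance = 1e-12)

  expect_error(bending_energy(matrix(0, 2, 3), 1), "at least 3")
})

test_that("bp <-> bead mapping follows N = B * 0.34 / d with rounding", {
  p <- dna_params()
  expect_equal(beads_for_bp(13000, p), 990)
  expect_equal(bp_for_beads(40000, p), round(40000 * 4.465 / 0.34))
  expect_equal(round(p$d / p$rise_per_bp), 13)  # one bead ~ 13 bp
  # round trip is stable to within one bead's worth of bp
  expect_lt(abs(bp_for_beads(beads_for_bp(10000, p), p) - 10000),
            p$d / p$rise_per_bp)
  expect_error(beads_for_bp(-5, p), "positive")
  expect_error(bp_for_beads(0, p), "positive")
})

test_that("freely jointed walks have the ideal-chain end-to-end statistics", {
  w1 <- generate_random_walk(1, step = 2.5, seed = 1)
  expect_equal(nrow(w1$coords), 2)
  expect_equal(sqrt(sum(diff(w1$coords)^2)), 2.5, tolerance = 1e-12)

  # <R_ee^2> = n * step^2 within 3 standard errors
  n_seg <- 30; n_walks <- 10000
  r2 <- vapply(seq_len(n_walks), function(k) {
    co <- knotdna:::random_walk_coords(n_seg, 1, seed = k)
    sum((co[n_seg + 1, ] - co[1, ])^2)
  }, 0)
  se <- stats::sd(r2) / sqrt(n_walks)
  expect_lt(abs(mean(r2) - n_seg), 3 * se)

  # deterministic given the seed
  expect_identical(generate_random_walk(50, seed = 7)$coords,
                   generate_random_walk(50, seed = 7)$coords)
})

test_that("radius of gyration equals its definition", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1)
  set.seed(4)
  co <- matrix(rnorm(60), 20, 3)
  ctr <- colMeans(co)
  brute <- sqrt(mean(rowSums(t(t(co) - ctr)^2)))
  expect_equal(radius_of_gyration(co), brute, tolerance = 1e-12)
})

test_that("persistence length closed form behaves as the theory demands", {
  # high-precision reference values (30-digit arithmetic oracle)
  expect_equal(persistence_length(1, 1), 0.861000611041113, tolerance = 1e-12)
  expect_equal(persistence_length(11.673, 4.465), 49.8541252774926,
               tolerance = 1e-12)
  # strictly proportional to d
  expect_equal(persistence_length(3, 7), 7 * persistence_length(3, 1))
  # monotonically increasing in g
  g <- seq(0.5, 20, by = 0.5)
  expect_true(all(diff(persistence_length(g, 1)) > 0))
  # large-g asymptote l_p -> g * d
  expect_equal(persistence_length(100, 1) / 100, 1, tolerance = 0.01)
  expect_error(persistence_length(0, 1), "must be > 0")
})

test_that("chain invariants are enforced", {
  ch <- straight_chain(20, 2)
  expect_true(validate_chain(ch))
  bad <- ch
  bad$coords[5, ] <- bad$coords[5, ] + 0.1
  expect_error(validate_chain(bad), "bond-length")
  # a chain folded back onto itself violates the hard-sphere constraint
  fold <- dna_chain(rbind(c(0, 0, 0), c(1, 0, 0), c(0.1, 0.05, 0)),
                    bond_length = 1)
  expect_error(suppressWarnings(validate_chain(fold)))
})

test_that("resample_chain yields exact bond lengths on arbitrary backbones", {
  arc <- open_trefoil_arc(300) * 10
  ch <- resample_chain(arc, bond_length = 1)
  bl <- sqrt(rowSums(diff(ch$coords)^2))
  expect_true(all(abs(bl - 1) < 1e-9))
  expect_gt(nrow(ch$coords), 50)
})
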