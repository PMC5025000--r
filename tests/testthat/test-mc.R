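test_that("sampling is deterministic given the seed", {
  p <- model_params(5, 2)
  e1 <- sample_ensemble(p, 40, 5, seed = 123)
  e2 <- sample_ensemble(p, 40, 5, seed = 123)
  expect_identical(lapply(e1, `[[`, "coords"), lapply(e2, `[[`, "coords"))
  e3 <- sample_ensemble(p, 40, 5, seed = 124)
  expect_false(identical(e1[[1]]$coords, e3[[1]]$coords))
})

test_that("every emitted conformation satisfies the chain invariants", {
  p <- model_params(8, 1.5)
  ens <- sample_ensemble(p, 60, 25, seed = 5)
  for (ch in ens) expect_true(validate_chain(ch))
  # stored energies equal an independent recomputation
  U <- attr(ens, "energy")
  recomputed <- vapply(ens, bending_energy, 0, g = p$g)
  expect_equal(U, recomputed, tolerance = 1e-9)
})

test_that("move mix must be a proper distribution, fixed for the run", {
  expect_error(move_set(pivot = 0.9), "sum to 1")
  expect_error(move_set(pivot = -0.1, crankshaft = 0.8), "sum to 1")
  acc <- attr(sample_ensemble(model_params(2, 1), 30, 3, seed = 1),
              "acceptance")
  expect_named(acc, c("pivot", "crankshaft", "mos_inversion",
                      "mos_reflection", "mos_interchange"))
})

test_that("ideal-chain angles follow the Boltzmann distribution", {
  # g = 0: isotropic bond directions, <cos theta> = 0
  e0 <- sample_ensemble(model_params(0, 1), 100, 150, seed = 2, ideal = TRUE)
  cos0 <- unlist(lapply(e0, bond_angle_cosines))
  frame_means <- vapply(e0, function(ch) mean(bond_angle_cosines(ch)), 0)
  se0 <- stats::sd(frame_means) / sqrt(length(frame_means))
  expect_lt(abs(mean(cos0)), 3 * se0)

  # g = 3: p(u) ~ exp(g u) on u = cos(theta) in [-1, 1]; Kolmogorov-Smirnov
  # against the exact CDF
  g <- 3
  e3 <- sample_ensemble(model_params(g, 1), 150, 150, seed = 3, ideal = TRUE,
                        sampling_interval = 4)
  u <- unlist(lapply(e3, bond_angle_cosines))
  cdf <- function(q) (exp(g * q) - exp(-g)) / (exp(g) - exp(-g))
  ks <- suppressWarnings(stats::ks.test(u, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("bond correlations of the ideal chain decay at the predicted rate", {
  for (g in c(2, 4, 10)) {
    ens <- sample_ensemble(model_params(g, 1), 120, 200, seed = 11 + g,
                           ideal = TRUE, sampling_interval = 3)
    bc <- bond_correlation(ens, max_lag = 3)
    lang <- 1 / tanh(g) - 1 / g
    expect_equal(bc$correlation[1], lang, tolerance = 0.02)
    expect_equal(bc$correlation[2], lang^2, tolerance = 0.04)
    # measured persistence length vs the closed form, within 5%
    lp_measured <- -1 / log(bc$correlation[1])
    expect_equal(lp_measured, persistence_length(g, 1), tolerance = 0.05)
  }
})

test_that("excluded volume is never violated and rods stay unknotted", {
  p <- model_params(30, 1)  # very stiff short chain: a fluctuating rod
  r <- estimate_knotting_probability(p, 40, n_samples = 50, seed = 6)
  expect_equal(r$p_knot, 0)
})

test_that("two-start ergodicity: knotted and straight starts converge", {
  p <- model_params(2, 1)
  n <- NULL
  knotted0 <- knotted_start_chain(100)
  n <- nrow(knotted0$coords)
  expect_true(validate_chain(knotted0))
  expect_equal(analyze_chain(knotted0$coords)$knot_label, "3_1")

  r_straight <- estimate_knotting_probability(p, n, n_samples = 150,
                                              burn_in = 150, seed = 21)
  r_knotted <- estimate_knotting_probability(p, n, n_samples = 150,
                                             burn_in = 150, seed = 22,
                                             start = knotted0)
  se <- sqrt(r_straight$se^2 + r_knotted$se^2)
  expect_lt(abs(r_straight$p_knot - r_knotted$p_knot), 3 * max(se, 0.02))
})

test_that("knotting probability estimates carry sensible uncertainties", {
  # ideal flexible chain: knots are common, so the estimate is informative
  p <- model_params(0, 1)
  r <- estimate_knotting_probability(p, 150, n_samples = 120, seed = 8,
                                     ideal = TRUE)
  expect_true(r$p_knot > 0 && r$p_knot < 1)
  expect_gt(r$se, 0)
  expect_equal(r$p_knot + r$p_unknot, 1)
  expect_lte(r$p_complex + r$p_trefoil, r$p_knot + 1e-12)
  expect_equal(sum(r$counts[[1]]), r$n_samples)
})
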