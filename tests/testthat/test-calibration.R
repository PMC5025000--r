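# analytic stand-in surface: a smooth P(N, g) fitted through noise-free
# loess, so calibration machinery can be tested without MC.  The N part is
# deliberately NOT a pure power law: with P = A(N) B(g) and A a power law,
# g and d are exactly degenerate through N_i = B_i 0.34 / d (the physical
# regime at small knotting probabilities); curvature in A identifies d.
analytic_surface <- function(n_range = c(250, 1000), g_range = c(6.5, 14),
                             n_count = 12, g_count = 12,
                             f = function(n, g)
                               (0.02 * n / 1000 + 0.15 * (n / 1000)^2) *
                               (1.5 - g / 14)) {
  dat <- tidyr::expand_grid(
    n_beads = seq(n_range[1], n_range[2], length.out = n_count),
    g = seq(g_range[1], g_range[2], length.out = g_count))
  dat$p_knot <- f(dat$n_beads, dat$g)
  probability_surface(dat, span = 0.5)
}

test_that("surface construction reproduces constant and nodal values", {
  dat <- tidyr::expand_grid(n_beads = seq(100, 500, length.out = 8),
                            g = seq(2, 10, length.out = 8))
  dat$p_knot <- 0.3
  surf <- probability_surface(dat)
  probe <- surface_probability(surf, c(150, 300, 450), c(3, 6, 9))
  expect_true(all(abs(probe - 0.3) < 0.01))
  expect_warning(surface_probability(surf, 1000, 5), "outside")
})

test_that("the calibration error function is the least-squares form", {
  surf <- analytic_surface()
  targets <- calibration_targets(bp = c(8000, 12000), p_knot = c(0.05, 0.10),
                                 sigma = c(0.01, 0.01))
  g <- 9; d <- 4.8
  # independent arithmetic: map lengths to beads, evaluate, square, sum
  n_i <- targets$bp * 0.34 / d
  p_hat <- surface_probability(surf, n_i, rep(g, 2), warn_extrapolation = FALSE)
  expect_equal(calibration_error(g, d, surf, targets),
               sum((p_hat - targets$p_knot)^2), tolerance = 1e-12)
  expect_gte(calibration_error(g, d, surf, targets), 0)

  # targets taken exactly from the surface give (near) zero error
  exact <- calibration_targets(bp = c(8000, 12000), p_knot = p_hat)
  expect_lt(calibration_error(g, d, surf, exact), 1e-12)

  # a target outside the hull is reported by name
  far <- calibration_targets(bp = 1e6, p_knot = 0.5)
  expect_error(calibration_error(g, d, surf, far), "1000000|1e\\+06")
})

test_that("parameter fitting recovers a known optimum on a smooth surface", {
  surf <- analytic_surface()
  g0 <- 10; d0 <- 5
  bp <- c(6618, 9191, 11765)
  p0 <- surface_probability(surf, bp * 0.34 / d0, rep(g0, 3),
                            warn_extrapolation = FALSE)
  targets <- calibration_targets(bp = bp, p_knot = p0, sigma = 0.002)
  fit <- fit_parameters(surf, targets, seed = 42)
  expect_s3_class(fit, "calibration_result")
  expect_lt(fit$error, 1e-8)
  expect_lt(abs(fit$g - g0) / g0, 0.05)
  expect_lt(abs(fit$d - d0) / d0, 0.05)
  expect_equal(fit$l_p_nm, persistence_length(fit$g, fit$d))
  # fitted point lies inside the searched box
  expect_true(fit$g >= surf$g_range[1] && fit$g <= surf$g_range[2])
  # error is the minimum over the trace
  expect_equal(fit$error, min(fit$trace$error))

  td <- tidy(fit)
  expect_equal(td$term, c("g", "d"))
  gl <- glance(fit)
  expect_equal(gl$n_targets, 3L)
})

test_that("a single-target fit is flagged as under-determined", {
  surf <- analytic_surface()
  one <- calibration_targets(bp = 9000, p_knot = 0.06)
  expect_warning(fit <- fit_parameters(surf, one, seed = 1),
                 "under-determined")
  expect_true(fit$under_determined)
})

test_that("synthesized targets are reproducible and honest at sigma = 0", {
  lengths <- c(2500, 4000)  # small chains keep the check fast
  t1 <- synthesize_targets(4, 2, lengths, noise_sd = 0, seed = 31,
                           n_samples = 60, burn_in = 50)
  t2 <- synthesize_targets(4, 2, lengths, noise_sd = 0, seed = 31,
                           n_samples = 60, burn_in = 50)
  expect_identical(t1$p_knot, t2$p_knot)
  # sigma = 0: targets equal the simulated probabilities exactly
  p_direct <- vapply(seq_along(lengths), function(k)
    estimate_knotting_probability(
      model_params(4, 1),
      n_beads = beads_for_bp(lengths[k], model_params(4, 2)),
      n_samples = 60, burn_in = 50, seed = 31 + 1000L * k)$p_knot, 0)
  expect_identical(t1$p_knot, p_direct)
  # noise is seed-reproducible and changes with the seed
  n1 <- synthesize_targets(4, 2, lengths, noise_sd = 0.01, seed = 31,
                           n_samples = 60, burn_in = 50)
  n2 <- synthesize_targets(4, 2, lengths, noise_sd = 0.01, seed = 32,
                           n_samples = 60, burn_in = 50)
  expect_false(identical(n1$p_knot, n2$p_knot))
  expect_true(all(n1$p_knot >= 0 & n1$p_knot <= 1))
})

test_that("the error surface is finite and continuous over the box", {
  surf <- analytic_surface()
  targets <- calibration_targets(bp = c(8000, 12000), p_knot = c(0.05, 0.1))
  gs <- seq(6.6, 13.9, length.out = 7)
  ds <- seq(4.2, 8.5, length.out = 7)
  E <- outer(gs, ds, Vectorize(function(g, d)
    calibration_error(g, d, surf, targets, rise_per_bp = 0.34)))
  expect_true(all(is.finite(E)))
  # bounded finite differences (no jumps at the loess cell boundaries)
  expect_lt(max(abs(diff(E))), 0.1)
})
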