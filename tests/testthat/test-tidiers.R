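test_that("tidiers and autoplots cover the fitted objects", {
  dat <- tidyr::expand_grid(n_beads = seq(100, 500, length.out = 6),
                            g = seq(4, 12, length.out = 6))
  dat$p_knot <- 0.1 * dat$n_beads / 500
  surf <- probability_surface(dat)

  td <- tidy(surf)
  expect_true(all(c("n_beads", "g", "p_knot", "p_fit") %in% names(td)))
  gl <- glance(surf)
  expect_equal(gl$n_nodes, 36L)
  expect_lt(gl$rmse, 0.01)

  expect_s3_class(autoplot(surf), "ggplot")

  targets <- calibration_targets(bp = c(300, 500) / 0.34 * 2,
                                 p_knot = c(0.04, 0.08))
  # direct-start fit exercises the calibration_result tidiers
  fit <- suppressWarnings(fit_parameters(surf, targets, start = c(8, 3)))
  expect_equal(tidy(fit)$term, c("g", "d"))
  expect_s3_class(glance(fit), "tbl_df")

  cv <- tibble::tibble(bp = c(1000, 2000), p_knot = c(0.1, 0.2),
                       se = c(0.01, 0.01), p_unknot = c(0.9, 0.8))
  class(cv) <- c("knotting_curve", class(cv))
  attr(cv, "B0") <- NA_real_
  expect_s3_class(autoplot(cv), "ggplot")

  sizes <- knot_size_stats(tibble::tibble(
    knot_label = "3_1", size_beads = c(100L, 110L, 120L, 110L)))
  expect_s3_class(plot_knot_sizes(sizes), "ggplot")
})
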