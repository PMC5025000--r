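test_that("triangle closure sends added vertices far outside the chain", {
  set.seed(2)
  co <- knotdna:::random_walk_coords(80, 1, seed = 3)  # 81 beads
  cc <- close_chain(co)
  expect_s3_class(cc, "closed_curve")
  expect_equal(nrow(cc$coords), nrow(co) + 3)
  com <- colMeans(co)
  rfar <- 10 * max(sqrt(rowSums(t(t(co) - com)^2)))
  added <- cc$coords[nrow(co) + 1:3, ]
  expect_true(all(sqrt(rowSums(t(t(added) - com)^2)) >= rfar * (1 - 1e-9)))

  # a straight rod closes to the unknot
  expect_equal(analyze_chain(straight_chain(30)$coords)$knot_label, "0_1")
  # an open trefoil arc with an outward gap closes to the trefoil, matching
  # the analysis of the native closed torus-knot curve
  expect_equal(analyze_chain(open_trefoil_arc(200))$knot_label, "3_1")
  native <- alexander_determinants(closed_curve(torus_knot_curve(200)))
  expect_equal(unname(native[c("det1", "det2")]), c(3, 7))
})

test_that("curve reduction preserves the knot type and reaches fixed points", {
  # planar convex polygon collapses to a triangle
  t <- seq(0, 2 * pi, length.out = 101)[1:100]
  poly <- closed_curve(cbind(cos(t), sin(t), 0))
  red <- simplify_curve(poly)
  expect_equal(nrow(red$coords), 3)

  # determinants identical before and after reduction on a dense trefoil
  tre <- closed_curve(torus_knot_curve(500))
  before <- alexander_determinants(tre, simplify = FALSE)
  after <- alexander_determinants(simplify_curve(tre), simplify = FALSE)
  expect_equal(before[c("det1", "det2")], after[c("det1", "det2")])

  # idempotent after convergence
  twice <- simplify_curve(simplify_curve(tre))
  expect_equal(nrow(twice$coords), nrow(simplify_curve(tre)$coords))
})

test_that("Alexander determinants match the closed-form knot polynomials", {
  tri <- closed_curve(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_equal(unname(alexander_determinants(tri)[1:2]), c(1, 1))
  expect_equal(unname(alexander_determinants(
    closed_curve(torus_knot_curve(200)))[1:2]), c(3, 7))
  expect_equal(unname(alexander_determinants(
    closed_curve(figure_eight_curve(300)))[1:2]), c(5, 11))
  # (2,5)-torus knot = 5_1
  expect_equal(unname(alexander_determinants(
    closed_curve(torus_knot_curve(400, p = 2, q = 5)))[1:2]), c(5, 31))
})

test_that("determinants are invariant across independent projections", {
  curves <- list(torus_knot_curve(150), figure_eight_curve(250),
                 connected_sum(torus_knot_curve(150), torus_knot_curve(150)))
  for (cv in curves) {
    res <- vapply(1:5, function(s)
      alexander_determinants(closed_curve(cv), seed = s)[1:2], numeric(2))
    expect_equal(unname(res[, 2:5]), unname(res[, rep(1, 4)]))
  }
})

test_that("connected sums multiply the factors' determinants", {
  t1 <- torus_knot_curve(150)
  f1 <- figure_eight_curve(250)
  cases <- list(
    list(connected_sum(t1, t1), c(9, 49)),                      # 3_1#3_1
    list(connected_sum(t1, f1), c(15, 77)),                     # 3_1#4_1
    list(connected_sum(connected_sum(t1, t1), t1), c(27, 343))  # 3x trefoil
  )
  for (cs in cases) {
    d <- alexander_determinants(closed_curve(cs[[1]]))
    expect_equal(unname(d[1:2]), cs[[2]])
  }
})

test_that("the identification table resolves all labels in scope", {
  tab <- knot_table()
  # no two labels share a determinant pair
  expect_equal(anyDuplicated(paste(tab$det1, tab$det2)), 0L)
  expect_equal(identify_knot(1, 1), "0_1")
  expect_equal(identify_knot(3, 7), "3_1")
  expect_equal(identify_knot(5, 11), "4_1")
  # 3_1#3_1 is separated from 6_1 (both have determinant 9 at t = -1)
  expect_equal(identify_knot(9, 49), "3_1#3_1")
  expect_equal(identify_knot(9, 5), "6_1")
  expect_equal(identify_knot(15, 77), "3_1#4_1")
  expect_equal(identify_knot(1234, 5678), "other")
  # overflow sentinel never maps to the unknot
  expect_equal(identify_knot(-1, -1), "other")
})

test_that("end trimming localizes a spliced trefoil", {
  st <- spliced_trefoil_chain(n_knot = 150, n_arm = 120)
  loc <- locate_knot(st$chain)
  expect_true(loc$knotted)
  expect_gte(loc$a, st$region[1] - 10)
  expect_lte(loc$b, st$region[2] + 10)
  # the localized interval, analysed in isolation, carries the same label
  seg <- st$chain$coords[loc$a:loc$b, ]
  expect_equal(analyze_chain(seg)$knot_label, "3_1")

  # unknotted rod: an explicit no-knot result, not an error
  expect_false(locate_knot(straight_chain(30))$knotted)

  # analyze_chain(locate = TRUE) reports size and diameter consistently
  rec <- analyze_chain(st$chain, params = dna_params(), locate = TRUE)
  expect_equal(rec$knot_label, "3_1")
  expect_equal(rec$size_beads, rec$b - rec$a + 1L)
  expect_equal(rec$diameter_nm, 2 * rec$rg_nm)
})

test_that("knot size statistics normalize, smooth and find the mode", {
  one <- tibble::tibble(knot_label = "3_1", size_beads = 230L,
                        diameter_nm = NA_real_)
  s1 <- knot_size_stats(one)
  expect_equal(s1$mode_size, 230)
  expect_equal(sum(s1$sizes$prob), 1)

  set.seed(9)
  sizes <- pmax(10L, as.integer(rnorm(400, 100, 15)))
  rec <- tibble::tibble(knot_label = "3_1", size_beads = sizes,
                        diameter_nm = rnorm(400, 50, 4))
  st <- knot_size_stats(rec, window = 5)
  expect_equal(sum(st$sizes$prob_smooth), 1, tolerance = 1e-12)
  # independent oracle: histogram + running average recomputed by hand
  grid <- seq(min(sizes), max(sizes))
  counts <- vapply(grid, function(s) sum(sizes == s), 0)
  sm <- vapply(seq_along(counts), function(i) {
    lo <- max(1, i - 2); hi <- min(length(counts), i + 2)
    mean(counts[lo:hi])
  }, 0)
  expect_equal(st$mode_size, grid[which.max(sm)])
  expect_true(is.finite(st$mode_diameter))

  empty <- knot_size_stats(rec[0, ])
  expect_equal(nrow(empty$sizes), 0)
  expect_true(is.na(empty$mode_size))
})

test_that("unknotting length interpolates the 1/e crossing log-linearly", {
  cv <- tibble::tibble(bp = c(1e5, 3e5), p_unknot = c(0.60, 0.25))
  b0 <- estimate_unknotting_length(cv)
  # independent closed form: log-linear interpolation
  expected <- 1e5 + (log(exp(-1)) - log(0.6)) * 2e5 / (log(0.25) - log(0.6))
  expect_equal(b0, expected, tolerance = 1e-12)
  expect_gt(b0, 1e5); expect_lt(b0, 3e5)

  withexact <- tibble::tibble(bp = c(1e5, 2e5, 3e5),
                              p_unknot = c(0.6, exp(-1), 0.2))
  expect_equal(estimate_unknotting_length(withexact), 2e5)

  expect_error(estimate_unknotting_length(
    tibble::tibble(bp = c(1e5, 2e5), p_unknot = c(0.9, 0.8))), "bracket")
})

test_that("COM-triangle and direct closures give near-identical knotting", {
  n_walks <- 500
  com <- dir <- logical(n_walks)
  for (w in seq_len(n_walks)) {
    co <- knotdna:::random_walk_coords(200, 1, seed = 5000 + w)
    com[w] <- com_closure_knotted(co, seed = w)
    dir[w] <- direct_closure_knotted(co, seed = w)
  }
  expect_lt(abs(mean(com) - mean(dir)), 0.02 + 1e-9)
})
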