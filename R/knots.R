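#' Closed curves
#'
#' A `closed_curve` is an ordered polygon in 3-space whose last vertex
#' connects back to the first. It is the object on which knot invariants are
#' defined; open chains are converted to closed curves by [close_chain()].
#'
#' @param coords N x 3 matrix of vertices.
#' @param provenance Either `"native"` (the curve was constructed closed) or
#'   `"closure"` (it came from closing an open chain).
#' @param n_added Number of vertices added by the closure construction.
#' @return An object of class `closed_curve`.
#' @export
closed_curve <- function(coords, provenance = c("native", "closure"),
                         n_added = 0L) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  provenance <- match.arg(provenance)
  if (nrow(coords) < 3) stop("a closed curve needs >= 3 vertices", call. = FALSE)
  if (any(rowSums((coords - coords[c(2:nrow(coords), 1), ])^2) == 0))
    stop("consecutive vertices must be distinct", call. = FALSE)
  structure(list(coords = coords, provenance = provenance,
                 n_added = as.integer(n_added)),
            class = "closed_curve")
}

#' @export
print.closed_curve <- function(x, ...) {
  cat(sprintf("<closed_curve> %d vertices (%s%s)\n", nrow(x$coords),
              x$provenance,
              if (x$n_added > 0) sprintf(", %d added by closure", x$n_added) else ""))
  invisible(x)
}

#' Close an open chain by the centre-of-mass triangle construction
#'
#' Both terminal beads are extended along the ray from the chain's centre of
#' mass through the respective bead, out to a radius of 10 times the largest
#' bead-to-centre distance; the two far points are then joined through a
#' triangle apex placed at twice that radius along the bisector of the two
#' ray directions. All added vertices therefore lie far outside the sphere
#' bounding the chain, and the added segments cannot thread through the
#' original chain volume.
#'
#' @param chain A [dna_chain()] or an N x 3 coordinate matrix (open chain).
#' @return A [closed_curve()] with three added vertices.
#' @export
close_chain <- function(chain) {
  co <- if (inherits(chain, "dna_chain")) chain$coords else as.matrix(chain)
  if (nrow(co) < 3) stop("closure requires at least 3 beads", call. = FALSE)
  closed_curve(close_chain_cpp(co), provenance = "closure", n_added = 3L)
}

#' Topology-preserving curve reduction
#'
#' Iteratively deletes a vertex whenever the triangle spanned by it and its
#' two neighbours is not crossed by any other segment of the polygon
#' (Koniaris-Muthukumar elision). The knot type is invariant under each
#' deletion; the reduction makes the crossing diagram, and hence the
#' Alexander determinant computation, tractable for long chains. Unknots
#' typically collapse to a triangle.
#'
#' @param curve A [closed_curve()].
#' @return A reduced [closed_curve()].
#' @export
simplify_curve <- function(curve) {
  stopifnot(inherits(curve, "closed_curve"))
  out <- simplify_closed_cpp(curve$coords)
  closed_curve(out, provenance = curve$provenance,
               n_added = min(curve$n_added, nrow(out)))
}

#' Alexander polynomial determinants of a closed curve
#'
#' Projects the curve along a random generic direction, builds the crossing
#' diagram with under/over assignments, assembles the Alexander matrix,
#' deletes one row and column, and evaluates the absolute determinant at
#' t = -1 and t = -2. The matrix determinant equals the Alexander polynomial
#' up to a unit `+/- t^k`; at t = -1 that unit has modulus one, and at
#' t = -2 the spurious power of two is divided out (the value at t = 1 is
#' odd, so the odd part is well defined). Evaluation at two points is needed
#' because single-point determinants collide (e.g. the figure-eight knot and
#' the 5_1 torus knot share |Delta(-1)| = 5). Near-degenerate projections
#' are re-drawn automatically.
#'
#' @param curve A [closed_curve()] (simplify first for long curves), or a
#'   coordinate matrix interpreted as a closed polygon.
#' @param seed Integer seed for the projection directions.
#' @param simplify Reduce the curve before projecting (recommended).
#' @return Named numeric vector with elements `det1` (= |Delta(-1)|),
#'   `det2` (odd part of |Delta(-2)|) and `n_crossings` of the diagram used.
#' @examples
#' alexander_determinants(closed_curve(torus_knot_curve(200)))  # 3, 7
#' @export
alexander_determinants <- function(curve, seed = 1L, simplify = TRUE) {
  co <- if (inherits(curve, "closed_curve")) curve$coords else as.matrix(curve)
  if (simplify) co <- simplify_closed_cpp(co)
  r <- alexander_cpp(co, as.integer(seed))
  c(det1 = r$det1, det2 = r$det2, n_crossings = r$n_crossings)
}

# --------------------------------------------------------------------------
# knot identification table

# Alexander polynomial coefficients (ascending powers, integer normalization
# with nonzero constant term) for prime knots up to 7 crossings
alexander_coeffs <- list(
  "0_1" = c(1),
  "3_1" = c(1, -1, 1),
  "4_1" = c(-1, 3, -1),
  "5_1" = c(1, -1, 1, -1, 1),
  "5_2" = c(2, -3, 2),
  "6_1" = c(2, -5, 2),
  "6_2" = c(-1, 3, -3, 3, -1),
  "6_3" = c(1, -3, 5, -3, 1),
  "7_1" = c(1, -1, 1, -1, 1, -1, 1),
  "7_2" = c(3, -5, 3),
  "7_3" = c(2, -3, 3, -3, 2),
  "7_4" = c(4, -7, 4),
  "7_5" = c(2, -4, 5, -4, 2),
  "7_6" = c(1, -5, 7, -5, 1),
  "7_7" = c(1, -5, 9, -5, 1)
)

poly_eval <- function(coef, t) sum(coef * t^(seq_along(coef) - 1))
odd_part <- function(x) {
  x <- abs(x)
  while (x > 0 && x %% 2 == 0) x <- x / 2
  x
}
det_pair <- function(coef) {
  c(abs(poly_eval(coef, -1)), odd_part(poly_eval(coef, -2)))
}

#' Knot identification table
#'
#' The lookup from Alexander determinant pairs to knot labels shipped with
#' the package: prime knots up to seven crossings plus the composite knots
#' that dominate long-DNA knot spectra (3_1#3_1, 3_1#4_1, 3_1#3_1#3_1,
#' 4_1#4_1, 3_1#5_1, 3_1#5_2). Composite determinants are the products of
#' their factors' determinants at both evaluation points. The table cannot
#' distinguish a composite from the 8-crossing prime that shares its
#' polynomial (e.g. 3_1#3_1 and 8_20), but 7-crossing primes are already
#' vanishingly rare in the ensembles studied, so this ambiguity is accepted.
#'
#' @return A tibble with columns `label`, `det1`, `det2`, `composite`.
#' @export
knot_table <- function() {
  primes <- tibble::tibble(
    label = names(alexander_coeffs),
    det1 = vapply(alexander_coeffs, function(cf) det_pair(cf)[1], 0),
    det2 = vapply(alexander_coeffs, function(cf) det_pair(cf)[2], 0),
    composite = FALSE
  )
  comp_spec <- list(
    "3_1#3_1" = c("3_1", "3_1"),
    "3_1#4_1" = c("3_1", "4_1"),
    "3_1#3_1#3_1" = c("3_1", "3_1", "3_1"),
    "4_1#4_1" = c("4_1", "4_1"),
    "3_1#5_1" = c("3_1", "5_1"),
    "3_1#5_2" = c("3_1", "5_2")
  )
  comps <- tibble::tibble(
    label = names(comp_spec),
    det1 = vapply(comp_spec, function(f)
      prod(vapply(f, function(k) det_pair(alexander_coeffs[[k]])[1], 0)), 0),
    det2 = vapply(comp_spec, function(f)
      prod(vapply(f, function(k) det_pair(alexander_coeffs[[k]])[2], 0)), 0),
    composite = TRUE
  )
  dplyr::bind_rows(primes, comps)
}

#' Identify a knot from its determinant pair
#'
#' Vectorized lookup of `(det1, det2)` against [knot_table()]. Pairs not in
#' the table give `"other"`; negative determinants (numerical overflow in a
#' very complex diagram) also give `"other"`, never the unknot.
#'
#' @param det1,det2 Numeric vectors of determinants as returned by
#'   [alexander_determinants()].
#' @return Character vector of knot labels (`"0_1"` for the unknot).
#' @export
identify_knot <- function(det1, det2) {
  tab <- knot_table()
  key <- paste(det1, det2)
  lab <- tab$label[match(key, paste(tab$det1, tab$det2))]
  lab[is.na(lab)] <- "other"
  lab[det1 < 0 | det2 < 0] <- "other"
  lab
}

# complex = anything beyond the unknot and the single trefoil
is_complex_label <- function(label) !(label %in% c("0_1", "3_1"))

# --------------------------------------------------------------------------
# per-chain analysis

#' Analyze the knot state of an open chain
#'
#' Closes the chain with the centre-of-mass triangle construction, reduces
#' it, evaluates the Alexander determinants, and identifies the knot type.
#' With `locate = TRUE` the knotted region is additionally localized by end
#' trimming and its size and geometry are reported.
#'
#' @param chain A [dna_chain()] or coordinate matrix (open chain).
#' @param params Optional [model_params()]; if supplied, knot sizes are also
#'   reported in base pairs.
#' @param seed Integer seed for projection directions.
#' @param locate Localize the knotted region (slower: one full analysis per
#'   trimmed bead).
#' @return A one-row tibble: `knot_label`, `det1`, `det2`, and (if located)
#'   `a`, `b` (1-based inclusive bead range), `size_beads`, `size_bp`,
#'   `rg_nm`, `diameter_nm` (diameter = 2 * radius of gyration of the
#'   knotted contour).
#' @export
analyze_chain <- function(chain, params = NULL, seed = 1L, locate = FALSE) {
  co <- if (inherits(chain, "dna_chain")) chain$coords else as.matrix(chain)
  r <- analyze_open_cpp(co, as.integer(seed))
  label <- identify_knot(r$det1, r$det2)
  out <- tibble::tibble(knot_label = label, det1 = r$det1, det2 = r$det2,
                        a = NA_integer_, b = NA_integer_,
                        size_beads = NA_integer_, size_bp = NA_integer_,
                        rg_nm = NA_real_, diameter_nm = NA_real_)
  if (locate && label != "0_1") {
    ab <- locate_knot_cpp(co, as.integer(seed))
    if (ab[1] >= 0) {
      a <- ab[1] + 1L; b <- ab[2] + 1L  # to 1-based inclusive
      seg <- co[a:b, , drop = FALSE]
      rg <- radius_of_gyration(seg)
      out$a <- a; out$b <- b
      out$size_beads <- b - a + 1L
      if (!is.null(params)) out$size_bp <- bp_for_beads(b - a + 1L, params)
      out$rg_nm <- rg
      out$diameter_nm <- 2 * rg
    }
  }
  out
}

#' Locate the knotted region of an open chain by end trimming
#'
#' Beads are removed one at a time from the first end; after each removal the
#' remainder is re-closed (with its own centre of mass) and re-analysed. The
#' bead whose removal first unknots the chain marks that boundary. The same
#' procedure is then applied from the other terminus to the retained chain.
#'
#' @inheritParams analyze_chain
#' @return A list with `knotted` (logical), and when knotted the 1-based
#'   inclusive bead range `a`, `b` plus `size_beads`.
#' @export
locate_knot <- function(chain, seed = 1L) {
  co <- if (inherits(chain, "dna_chain")) chain$coords else as.matrix(chain)
  ab <- locate_knot_cpp(co, as.integer(seed))
  if (ab[1] < 0) return(list(knotted = FALSE, a = NA_integer_, b = NA_integer_,
                             size_beads = NA_integer_))
  list(knotted = TRUE, a = ab[1] + 1L, b = ab[2] + 1L,
       size_beads = ab[2] - ab[1] + 1L)
}

#' Knot size statistics for an ensemble of knot records
#'
#' Conditional distributions of trefoil contour length and diameter, given
#' that a chain carries a trefoil. The raw histogram over bead counts is
#' smoothed by a two-sided running average; probabilities are normalized so
#' each distribution integrates to one over its domain.
#'
#' @param records A tibble of per-chain records as produced by
#'   [analyze_chain()] (needs `knot_label` and `size_beads`; `diameter_nm`
#'   optional).
#' @param window Odd width of the two-sided running-average smoother (beads).
#' @param label Knot type to condition on.
#' @return A list with `sizes` (tibble: `size_beads`, `prob`, `prob_smooth`),
#'   `mode_size` (argmax of the smoothed size distribution), `diameters`
#'   (tibble or NULL) and `mode_diameter`.
#' @export
knot_size_stats <- function(records, window = 11, label = "3_1") {
  stopifnot(window %% 2 == 1)
  rec <- dplyr::filter(records, .data$knot_label == label,
                       !is.na(.data$size_beads))
  if (nrow(rec) == 0)
    return(list(sizes = tibble::tibble(size_beads = integer(), prob = numeric(),
                                       prob_smooth = numeric()),
                mode_size = NA_real_, diameters = NULL,
                mode_diameter = NA_real_))
  rng <- range(rec$size_beads)
  grid <- seq(rng[1], rng[2])
  counts <- tabulate(rec$size_beads - rng[1] + 1L, nbins = length(grid))
  prob <- counts / sum(counts)
  prob_smooth <- running_mean(prob, window)
  prob_smooth <- prob_smooth / sum(prob_smooth)
  sizes <- tibble::tibble(size_beads = grid, prob = prob,
                          prob_smooth = prob_smooth)
  mode_size <- grid[which.max(prob_smooth)]
  diameters <- NULL
  mode_diameter <- NA_real_
  if ("diameter_nm" %in% names(rec) && any(!is.na(rec$diameter_nm))) {
    dvals <- rec$diameter_nm[!is.na(rec$diameter_nm)]
    dd <- stats::density(dvals)
    diameters <- tibble::tibble(diameter_nm = dd$x, density = dd$y)
    mode_diameter <- dd$x[which.max(dd$y)]
  }
  list(sizes = sizes, mode_size = mode_size, diameters = diameters,
       mode_diameter = mode_diameter)
}

# two-sided running average with shrinking window at the edges
running_mean <- function(x, window) {
  h <- (window - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    mean(x[lo:hi])
  }, 0)
}

#' Unknotting length from a probability series
#'
#' The unknotting length B0 is the chain length (in bp) at which the
#' probability of the unknot equals 1/e. It is found by log-linear
#' interpolation of `p_unknot` between the two lengths bracketing the
#' crossing.
#'
#' @param curve A data frame with columns `bp` and `p_unknot`.
#' @return B0 in base pairs.
#' @export
estimate_unknotting_length <- function(curve) {
  stopifnot(all(c("bp", "p_unknot") %in% names(curve)))
  cv <- dplyr::arrange(dplyr::as_tibble(curve), .data$bp)
  target <- exp(-1)
  hit <- which(cv$p_unknot == target)
  if (length(hit) > 0) return(cv$bp[hit[1]])
  above <- cv$p_unknot > target
  k <- which(above[-length(above)] & !above[-1])
  if (length(k) == 0)
    stop("the series does not bracket the 1/e crossing", call. = FALSE)
  k <- k[1]
  p1 <- cv$p_unknot[k]; p2 <- cv$p_unknot[k + 1]
  b1 <- cv$bp[k]; b2 <- cv$bp[k + 1]
  b1 + (log(target) - log(p1)) * (b2 - b1) / (log(p2) - log(p1))
}
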