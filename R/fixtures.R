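#' Parametric knot fixtures
#'
#' Closed and open polygonal curves with known knot type, used as ground
#' truth for the topological machinery: the (2,3)-torus knot (trefoil), the
#' figure-eight curve, connected sums, and an open trefoil spliced between
#' straight arms for knot-localization tests.
#'
#' @param n Number of vertices.
#' @param p,q Torus-knot winding numbers (coprime); `(2, 3)` is the trefoil.
#' @param scale Overall size scale factor.
#' @return An N x 3 coordinate matrix (a closed polygon: last vertex connects
#'   back to the first).
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
torus_knot_curve <- function(n = 200, p = 2, q = 3, scale = 1) {
  stopifnot(n >= 3)
  t <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  scale * cbind((2 + cos(q * t)) * cos(p * t),
                (2 + cos(q * t)) * sin(p * t),
                sin(q * t))
}

#' @rdname fixtures
#' @export
figure_eight_curve <- function(n = 300, scale = 1) {
  stopifnot(n >= 3)
  t <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  scale * cbind((2 + cos(2 * t)) * cos(3 * t),
                (2 + cos(2 * t)) * sin(3 * t),
                sin(4 * t))
}

# open arc of a parametric closed curve, with a gap of parameter width `gap`
# centred at t = 0 (the gap faces the +x side for both families above)
open_curve_arc <- function(fn, n, gap) {
  t <- seq(gap / 2, 2 * pi - gap / 2, length.out = n)
  fn(t)
}

#' Open trefoil arc
#'
#' A (2,3)-torus-knot curve with a small outward-facing gap; closing it with
#' the centre-of-mass triangle closure recovers the trefoil.
#'
#' @param n Number of vertices.
#' @param gap Angular width of the removed parameter interval.
#' @return An N x 3 coordinate matrix (open polyline).
#' @export
open_trefoil_arc <- function(n = 200, gap = 0.25) {
  open_curve_arc(function(t) cbind((2 + cos(3 * t)) * cos(2 * t),
                                   (2 + cos(3 * t)) * sin(2 * t),
                                   sin(3 * t)), n, gap)
}

#' Connected sum of two closed knot curves
#'
#' Joins two closed polygons into one closed curve carrying the connected-sum
#' knot type. Each factor is opened at its vertex of maximal x; the second is
#' flipped to face the first and shifted along +x so the two joining segments
#' cannot entangle with either factor.
#'
#' @param a,b Closed-polygon coordinate matrices.
#' @param separation Gap between the two factors along x.
#' @return A closed-polygon coordinate matrix.
#' @examples
#' tt <- connected_sum(torus_knot_curve(150), torus_knot_curve(150))
#' alexander_determinants(closed_curve(tt))  # 9, 49: the granny knot 3_1#3_1
#' @export
connected_sum <- function(a, b, separation = 4) {
  a <- rotate_gap_to_x(a)
  b <- rotate_gap_to_x(b)
  shift <- max(a[, 1]) - min(-b[, 1]) + separation
  b2 <- cbind(-b[, 1] + shift, -b[, 2], b[, 3])
  rbind(a, b2)
}

# reorder a closed polygon so it starts just after its max-x vertex (the
# opening used by connected_sum faces +x)
rotate_gap_to_x <- function(v) {
  i <- which.max(v[, 1])
  if (i < nrow(v)) v <- rbind(v[(i + 1):nrow(v), , drop = FALSE],
                              v[seq_len(i), , drop = FALSE])
  v
}

#' Spliced-trefoil test chain
#'
#' An open chain consisting of a straight arm, a tight open trefoil, and a
#' second straight arm, rescaled to unit bond lengths. The knotted region is
#' the trefoil segment by construction, which makes the chain a ground-truth
#' fixture for [locate_knot()].
#'
#' @param n_knot Beads in the trefoil section.
#' @param n_arm Beads in each straight arm.
#' @return A list with `chain` (a [dna_chain()]) and the 1-based index range
#'   `region = c(first, last)` of the spliced trefoil section.
#' @export
spliced_trefoil_chain <- function(n_knot = 150, n_arm = 120) {
  arc <- open_trefoil_arc(n_knot, gap = 0.6)
  # resample to roughly uniform spacing, then scale to unit bonds
  seg <- sqrt(rowSums(diff(arc)^2))
  arc <- arc / mean(seg)
  ein <- arc[1, ]; eout <- arc[nrow(arc), ]
  din <- ein - arc[2, ]; din <- din / sqrt(sum(din^2))
  dout <- eout - arc[nrow(arc) - 1, ]; dout <- dout / sqrt(sum(dout^2))
  arm_in <- t(sapply(rev(seq_len(n_arm)), function(k) ein + k * din))
  arm_out <- t(sapply(seq_len(n_arm), function(k) eout + k * dout))
  co <- rbind(arm_in, arc, arm_out)
  # normalize bonds to constant length (straight arms already are)
  chain <- dna_chain(co, bond_length = mean(sqrt(rowSums(diff(co)^2))),
                     bead_diameter = 0)
  list(chain = chain, region = c(n_arm + 1, n_arm + n_knot))
}
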