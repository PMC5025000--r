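# shared fixtures for the test suite (built in code, never stored)

# planar zig-zag with all bond angles of 90 degrees
zigzag_chain <- function(n) {
  co <- matrix(0, n, 3)
  for (i in 2:n) {
    step <- if (i %% 2 == 0) c(1, 0, 0) else c(0, 1, 0)
    co[i, ] <- co[i - 1, ] + step
  }
  co
}

# a knotted, self-avoiding, unit-bond open chain: a scaled-up trefoil arc
# resampled at exact unit chords (strand separations are several bond
# lengths, so the hard-sphere constraint holds)
knotted_start_chain <- function(target_beads = 100) {
  arc <- open_trefoil_arc(400, gap = 0.4)
  len <- sum(sqrt(rowSums(diff(arc)^2)))
  arc <- arc * (target_beads / len)
  resample_chain(arc, bond_length = 1)
}

# direct end-to-end closure: interpret the open coordinates as a closed
# polygon (last vertex joined straight back to the first)
direct_closure_knotted <- function(co, seed) {
  d <- alexander_determinants(co, seed = seed)
  !(d[["det1"]] == 1 && d[["det2"]] == 1)
}

com_closure_knotted <- function(co, seed) {
  r <- analyze_chain(co, seed = seed)
  r$knot_label != "0_1"
}
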