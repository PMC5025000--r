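---
title: "Knot statistics in coarse-grained dsDNA: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knot statistics in coarse-grained dsDNA: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knotdna)
```

## The model

Double-stranded DNA is represented as a discrete worm-like (Kratky–Porod)
chain of $N$ impermeable spherical beads of diameter $d$ (nm), with fixed
bond length equal to $d$ (tangent spheres) and bending energy

$$ U/k_BT \;=\; -g \sum_{i} \cos\theta_i, $$

where the $\theta_i$ are the $N-2$ angles between adjacent bond vectors of
an open $N$-bead chain and $g \ge 0$ is a dimensionless stiffness. Beads at
chemical distance $\ge 2$ may not approach closer than $d$; bonded
neighbours sit exactly at contact. The helical rise of 0.34 nm per base
pair maps a strand of $B$ bp onto $N = \mathrm{round}(B \cdot 0.34/d)$
beads, so the contour length $N d$ equals $B \cdot 0.34$ nm. Because the
bond length and the hard-sphere diameter coincide, the chain statistics are
dimensionless in $(N, g)$; $d$ only sets the physical scale and the
bp-per-bead resolution.

Two parameters carry all the physics:

* `g` — bending stiffness. For the *ideal* chain (hard spheres off) the
  persistence length has the closed form
  $l_p(g,d) = -d / \ln(\coth g - 1/g)$, increasing monotonically in $g$ and
  proportional to $d$.
* `d` — effective diameter (nm). It subsumes the 2 nm structural thickness
  of the double helix *and* the salt-dependent screened electrostatic
  repulsion, so it exceeds the bare diameter at physiological salt.

The shipped preset `dna_params()` (`g = 11.673`, `d = 4.465` nm, 0.15 M
NaCl) was calibrated against gel-electrophoresis knotting probabilities of
5.6–10 kbp DNA; it implies $l_p \approx 49.85$ nm, in agreement with the
~50 nm experimental consensus, and a resolution of ~13 bp per bead. The
preset is shipped as data (a constructor), not as a hard-coded constant.

## Monte Carlo sampling

`sample_ensemble()` runs a Metropolis Markov chain. One sweep is $N$
attempted moves; a proposal that violates the hard-sphere constraint is
rejected outright, otherwise it is accepted with probability
$\min(1, e^{-\Delta U/k_BT})$. Five bond-length-preserving moves are mixed
with fixed probabilities (default 40/30/10/10/10):

* **pivot** — rigid rotation of everything on one side of a uniformly
  chosen internal bead, by a uniform angle in $(0, \pi]$ about a uniform
  random axis. We rotate the *shorter* side: the proposal set is identical
  by symmetry (side membership is fixed by the bead index, and the rotation
  family is closed under inversion), at half the expected cost.
* **crank-shaft** — rotation of the beads strictly between two chain points
  about their chord, by a uniform angle in $(0, 2\pi)$.
* **MOS inversion / reflection / interchange** — bond-vector
  rearrangements: inversion reverses the bond order of a window
  (equivalently, a point reflection of the window interior through the
  junction midpoint); reflection mirrors the interior through the plane
  normal to the junction chord, then reverses; interchange transplants two
  disjoint equal-length bond windows. All fix the junction beads and every
  bond length exactly.

The local moves draw window sizes up to 32 bonds (and interchange offsets
up to 64), keeping their cost bounded; pivots supply the global topology
changes. Each move family is an involution or closed under inverses with
index-determined selection probabilities, so detailed balance holds for the
mixture; the two-start ergodicity test (straight rod vs a deliberately
knotted start) checks in the test suite that the chain reaches the same
knotting level from both sides.

Energy bookkeeping exploits that every move either transforms contiguous
blocks rigidly or permutes window-interior angles among themselves: only
the few junction angles enter $\Delta U$, and the total energy is refreshed
from scratch at every recorded sample (the suite verifies stored vs
recomputed energies at $10^{-9}$ relative tolerance). Overlap detection
uses hashed linked cell lists with cell edge $d$; only moved beads are
re-checked, and rigid blocks skip their internal pairs.

Defaults: the sampler starts from a straight rod (trivially self-avoiding),
discards 100 sweeps of burn-in and records every 2 sweeps. Error bars on
knotting probabilities come from a blocked bootstrap over the recorded
stream (blocks of 10 samples), absorbing residual autocorrelation. Each run
is driven by one counter-based generator seeded from a single integer, so
every result is bit-reproducible given its seed.

## Knot detection in open chains

A knot is only defined for a closed curve, so an open conformation is
closed first (`close_chain()`): both terminal beads are extended along the
ray from the chain's centre of mass through the bead out to
$R_\mathrm{far} = 10 \max_i |r_i - \mathrm{COM}|$, and the two far points
are joined through a triangle apex at $2 R_\mathrm{far}$ along the bisector
of the ray directions. Any factor $> 1$ would place the added segments
outside the bounding sphere; 10 leaves a wide margin. Exactly structured
conformations (lattice-like or synthetic symmetric curves) can place chain
vertices exactly *on* an extension ray; the closure detects this and nudges
the ray deterministically until the added segment clears the chain. For
random-walk ensembles the COM-triangle closure and a plain end-to-end
closure give knotting probabilities within two percentage points of each
other (verified in the suite), so the closure choice is not load-bearing.

The closed polygon is reduced by Koniaris–Muthukumar elision
(`simplify_curve()`): a vertex is deleted whenever the triangle spanned
with its two neighbours is crossed by no other segment, which sweeps the
strand across an empty triangle — an isotopy. Ambiguous near-degenerate
cases block deletion (over-conservatism costs only reduction, never
correctness); collinear vertices that lie between their neighbours are
removed directly. Unknotted closed random walks typically collapse to a
triangle; a 1,000-bead equilibrium conformation reduces from ~1,000 to a
handful of vertices in about 2 ms, which is what makes per-frame knot
classification affordable.

`alexander_determinants()` projects the reduced curve along a random
direction, re-drawing on near-degenerate diagrams (crossings at segment
endpoints, near-parallel overlaps, depth ties), builds the crossing list
with under/over assignments, assembles the Alexander matrix, deletes one
row and column, and evaluates $|\det|$ at $t = -1$ and $t = -2$. The matrix
determinant equals $\pm t^k \Delta(t)$: at $t=-1$ the unit is modulus one;
at $t=-2$ the spurious $2^k$ is divided out, which is well defined because
$\Delta(1) = \pm 1$ forces the odd part to be invariant. Two evaluation
points are necessary: single determinants collide (figure-eight and $5_1$
both give 5; $3_1\#3_1$ and $6_1$ both give 9). The shipped table
(`knot_table()`) covers prime knots to seven crossings and the composites
that dominate long-DNA spectra, with composite entries formed as products
of their factors' values. A composite remains indistinguishable from the
8-crossing prime sharing its polynomial (e.g. $3_1\#3_1$ vs $8_{20}$); that
ambiguity is accepted because 7-crossing primes are already vanishingly
rare in these ensembles. Unresolvable pairs are reported as `"other"`,
never folded into the unknot.

Knot localization (`locate_knot()`) trims beads one at a time from the
first end, re-closing the remainder (with its own centre of mass — the
global-COM alternative is not meaningfully different for tight knots) and
re-analysing until the knot disappears; the bead whose removal unknots the
chain is the boundary, and the procedure repeats from the other terminus.
The knotted contour's radius of gyration gives the knot diameter as
$2\sqrt{\langle R_g^2\rangle}$. On a spliced-trefoil fixture whose knotted
region is known by construction, the recovered interval sits inside the
spliced region within a few beads (the trimmed core is tighter than the
full spliced arc, as it should be).

## Calibration

`build_surface()` simulates knotting probabilities on an equispaced
$(N, g)$ grid (production default $16\times16$ over $N \in [250, 1000]$,
$g \in [6.5, 14]$; desk-scale fits use $6\times6$) and fits a
local-regression (loess) surface, span 0.75 and degree 2 — the method the
calibration was designed around, at its common defaults. Experimental
targets $(B_i, P_i)$ enter through a trial diameter:
$N_i(d) = B_i \cdot 0.34/d$ (continuous, not rounded), and

$$ E(g, d) \;=\; \sum_i \left(\hat P(N_i(d),\, g) - P_i\right)^2 $$

is minimized by Levenberg–Marquardt (`minpack.lm::nls.lm`) from several
seeded starts inside the box for which all targets map into the grid hull
(multi-start because the loess surface can carry shallow local minima).
Residuals are unweighted by default — optional $1/\sigma^2$ weighting is a
flag — and the derived persistence length accompanies every fit. A
single-target fit is flagged as under-determined from the Jacobian's
singular values rather than silently returned.

`synthesize_targets()` stands in for the experimental electrophoresis
probabilities, which are not tabulated here: it simulates $P$ at chosen
lengths under known $(g^\*, d^\*)$ and adds Gaussian noise
($\sigma = 0.005$ by default, the scale of a careful gel experiment on
percent-level knotting).

### Identifiability at desk scale — an honest limitation

At the grid's chain lengths the knotting probabilities are only 1–4%, and
their stiffness dependence is weak and non-monotonic: precise runs at
$N = 700$ give $P = 0.0195(17)$ at $g = 6.5$, $0.0232(18)$ at $g = 10$ and
$0.0152(14)$ at $g = 14$ — about $10^{-3}$ per unit of $g$. Resolving a
10% change in $g$ therefore requires probabilities accurate to a few
$10^{-4}$, i.e. tens of thousands of effective samples per grid node.
Moreover, at small $P$ the surface is close to a separable form
$A(N)\,B(g)$ with $A$ nearly linear, so $g$ and $d$ trade off along a flat
error ridge ($d$ only rescales $N_i$); only the curvature of $A$ breaks the
degeneracy, and it is buried under sampling noise at desk scale. An
end-to-end desk-scale recovery run ($6\times6$ grid, a few hundred samples
per node, $\sigma = 0.005$ targets at $(g^\*, d^\*) = (10, 5)$) reaches a
near-vanishing error at parameters tens of percent away from the truth,
with $g$ pinned at the search-box boundary — the minimum slides freely
along the ridge, so the error function genuinely cannot see the truth at
this noise level. The
calibration machinery itself is verified on a noise-free analytic surface
with curvature in $N$, where the same pipeline recovers $(10, 5)$ to
better than 5%. Calibrating real parameters the way the production fit did
requires probability errors two orders of magnitude below experimental
ones — cluster-scale sampling, outside this package's test envelope. The
corresponding end-to-end MC recovery check in the test suite is expected
to fail at desk scale and is retained deliberately as a statement of that
limit.

## What the synthetic generator does and does not emulate

Synthetic targets reproduce the *statistical* structure of the calibration
inputs: percent-level knotting probabilities at kbp lengths with Gaussian
errors of a few tenths of a percent. They do not emulate experimental
systematics — cyclization bias (gel experiments circularize before
scoring), salt-condition drift between sources, or band-quantification
error correlations — so a green parameter-recovery test on synthetic
targets demonstrates correctness of the pipeline, not robustness to those
systematics.

## Numerical choices and degenerate inputs

* Bond lengths are validated to $10^{-9}$ relative tolerance; all moves
  preserve them exactly (rigid maps), so no re-normalization drift occurs.
* The hard-sphere test uses $|r_i - r_j|^2 < d^2(1 - 10^{-9})$, letting
  exact-contact lattice conformations through.
* Projection degeneracies re-draw the direction (up to 25 attempts) rather
  than guess; an even determinant at $t=-1$ (impossible for a knot) also
  forces a re-draw. Determinants whose magnitude approaches the float-exact
  integer range are reported as overflow (`"other"`), never rounded into a
  table entry.
* $g = 0$ is rejected by `persistence_length()` (the log diverges); the
  sampler itself accepts $g = 0$ (freely jointed hard-sphere chain).
* A chain endpoint coinciding with the centre of mass gets a fixed fallback
  ray direction, with a warning.
* Loess evaluation is clipped to $[0,1]$ and warns outside the grid hull;
  the fit box shrinks targets' feasible $(g,d)$ rectangle by $10^{-6}$ of
  its width to keep LM strictly interior.

## Problem sizes in the shipped tests

The suite samples chains of 40–1,000 beads, ensembles of 120–600 frames,
2,000 random walks for the freely-jointed baseline, and a $6\times6$
calibration grid at a few hundred samples per node — sizes chosen so the
whole suite completes in minutes on one core while every statistical
assertion retains a 3-standard-error margin. Production-scale runs
($N = 40{,}000$, ~525 kbp, where ~88% of chains are knotted and the
unknotting length $B_0 \approx 250$ kbp) use exactly the same code paths;
only the sample counts and grid densities differ.
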