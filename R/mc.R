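#' Monte Carlo move mix
#'
#' Selection probabilities for the five chain moves. Pivot moves rotate one
#' side of the chain rigidly about an internal bead and drive decorrelation
#' of the global topology; crank-shaft moves rotate an internal stretch
#' about the chord between its endpoints; the generalized MOS moves
#' rearrange bond vectors (inversion reverses a window's bond order,
#' reflection mirrors a window through the plane normal to its chord,
#' interchange swaps two equal-length bond windows). All moves preserve
#' every bond length exactly, and the probabilities are fixed for a run, as
#' detailed balance requires.
#'
#' @param pivot,crankshaft,mos_inversion,mos_reflection,mos_interchange
#'   Selection probabilities; must sum to 1.
#' @param max_window Largest bond window (beads) used by the local moves.
#' @return An object of class `move_set`.
#' @export
move_set <- function(pivot = 0.4, crankshaft = 0.3, mos_inversion = 0.1,
                     mos_reflection = 0.1, mos_interchange = 0.1,
                     max_window = 32L) {
  p <- c(pivot = pivot, crankshaft = crankshaft,
         mos_inversion = mos_inversion, mos_reflection = mos_reflection,
         mos_interchange = mos_interchange)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("move probabilities must be non-negative and sum to 1", call. = FALSE)
  structure(list(probs = p, max_window = as.integer(max_window)),
            class = "move_set")
}

#' Sample equilibrium conformations of the semi-flexible chain
#'
#' Runs the Metropolis Markov chain from a straight rod (or a supplied
#' start), discards `burn_in` sweeps, then records one conformation every
#' `sampling_interval` sweeps. One sweep is N attempted moves. Proposals
#' that violate the hard-sphere constraint are rejected outright; otherwise
#' the usual `min(1, exp(-dU/kBT))` criterion on the bending energy applies.
#' The stream is deterministic given the seed.
#'
#' @param params A [model_params()].
#' @param n_beads Number of beads N (>= 3).
#' @param n_samples Number of recorded conformations.
#' @param sampling_interval Sweeps between recorded conformations.
#' @param burn_in Discarded initial sweeps.
#' @param seed Integer seed.
#' @param moves A [move_set()].
#' @param ideal If `TRUE`, disable the hard-sphere interaction (ideal
#'   Kratky-Porod chain); used for closed-form validation.
#' @param start Optional starting [dna_chain()] (must satisfy the chain
#'   invariants); defaults to a straight rod.
#' @return A `chain_ensemble`: list of [dna_chain()] objects with sampler
#'   diagnostics in attributes (`acceptance`, `energy`, `params`).
#' @export
sample_ensemble <- function(params, n_beads, n_samples,
                            sampling_interval = 2L, burn_in = 100L,
                            seed = 1L, moves = move_set(), ideal = FALSE,
                            start = NULL) {
  stopifnot(inherits(params, "model_params"), n_beads >= 3, n_samples >= 1)
  start_m <- mc_start_matrix(params, n_beads, start, ideal)
  r <- mc_run_cpp(start_m, params$g, params$d, as.integer(n_samples),
                  as.integer(sampling_interval), as.integer(burn_in),
                  unname(moves$probs), as.integer(seed), ideal,
                  return_frames = TRUE, analyze_knots = FALSE,
                  max_window = moves$max_window)
  chains <- lapply(r$frames, function(m)
    dna_chain(m, bond_length = params$d, bead_diameter = params$d))
  structure(chains, class = "chain_ensemble",
            acceptance = stats::setNames(r$accepted / pmax(r$attempted, 1),
                                         names(moves$probs)),
            energy = r$energy, params = params, seed = seed,
            sampling_interval = sampling_interval, burn_in = burn_in)
}

mc_start_matrix <- function(params, n_beads, start, ideal) {
  if (is.null(start))
    return(straight_chain(n_beads, params$d)$coords)
  stopifnot(inherits(start, "dna_chain"))
  if (nrow(start$coords) != n_beads)
    stop("`start` has the wrong number of beads", call. = FALSE)
  validate_chain(start, tol = 1e-6, ideal = ideal)
  start$coords
}

#' @export
print.chain_ensemble <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<chain_ensemble> %d conformations of %d beads (g = %.3f, d = %.3f nm)\n",
              length(x), nrow(x[[1]]$coords), p$g, p$d))
  acc <- attr(x, "acceptance")
  cat("  acceptance:", paste(sprintf("%s %.2f", names(acc), acc), collapse = ", "), "\n")
  invisible(x)
}

#' Per-conformation summary of an ensemble
#'
#' @param x A `chain_ensemble` from [sample_ensemble()].
#' @param ... Unused.
#' @return A tibble with one row per conformation: `sample`, `energy_kbt`,
#'   `rg_nm`, `end_to_end_nm`, `mean_cos_angle`.
#' @export
tidy.chain_ensemble <- function(x, ...) {
  tibble::tibble(
    sample = seq_along(x),
    energy_kbt = attr(x, "energy"),
    rg_nm = vapply(x, radius_of_gyration, 0),
    end_to_end_nm = vapply(x, function(ch) {
      co <- ch$coords
      sqrt(sum((co[nrow(co), ] - co[1, ])^2))
    }, 0),
    mean_cos_angle = vapply(x, function(ch) mean(bond_angle_cosines(ch)), 0)
  )
}

#' Cosines of the bond angles of a chain
#'
#' @param chain A [dna_chain()] or coordinate matrix.
#' @return Numeric vector of the N - 2 consecutive bond-angle cosines.
#' @export
bond_angle_cosines <- function(chain) {
  co <- if (inherits(chain, "dna_chain")) chain$coords else as.matrix(chain)
  b <- diff(co)
  b <- b / sqrt(rowSums(b^2))
  nb <- nrow(b)
  rowSums(b[-nb, , drop = FALSE] * b[-1, , drop = FALSE])
}

#' Bond-direction correlation function of an ensemble
#'
#' `C(s) = <u_i . u_{i+s}>` averaged over bonds and conformations. For the
#' ideal chain this decays as `(coth g - 1/g)^s`, giving the persistence
#' length `l_p = -d / log(C(1))`.
#'
#' @param ensemble A `chain_ensemble`.
#' @param max_lag Largest chemical distance s.
#' @return A tibble with columns `lag` and `correlation`.
#' @export
bond_correlation <- function(ensemble, max_lag = 20L) {
  stopifnot(inherits(ensemble, "chain_ensemble"))
  acc <- numeric(max_lag)
  cnt <- numeric(max_lag)
  for (ch in ensemble) {
    b <- diff(ch$coords)
    b <- b / sqrt(rowSums(b^2))
    nb <- nrow(b)
    for (s in seq_len(min(max_lag, nb - 1))) {
      acc[s] <- acc[s] + sum(b[seq_len(nb - s), ] * b[seq_len(nb - s) + s, ])
      cnt[s] <- cnt[s] + (nb - s)
    }
  }
  tibble::tibble(lag = seq_len(max_lag), correlation = acc / pmax(cnt, 1))
}

#' Estimate the knotting probability of a chain
#'
#' Samples conformations, classifies each one with the triangle closure plus
#' Alexander determinants, and reports the fraction whose closed knot type
#' is not the unknot. The standard error is a blocked bootstrap over the
#' sample stream (blocks of 10 consecutive samples), which absorbs residual
#' autocorrelation between recorded conformations.
#'
#' @inheritParams sample_ensemble
#' @param block Block length (samples) of the bootstrap.
#' @param n_boot Bootstrap replicates.
#' @return A one-row tibble: `n_beads`, `bp`, `n_samples`, `p_knot`, `se`,
#'   `p_unknot`, `p_trefoil`, `p_complex`, and a list-column `counts` with
#'   the per-label tally.
#' @export
estimate_knotting_probability <- function(params, n_beads, n_samples = 500L,
                                          sampling_interval = 2L,
                                          burn_in = 100L, seed = 1L,
                                          moves = move_set(), ideal = FALSE,
                                          start = NULL, block = 10L,
                                          n_boot = 200L) {
  stopifnot(inherits(params, "model_params"), n_beads >= 3)
  start_m <- mc_start_matrix(params, n_beads, start, ideal)
  r <- mc_run_cpp(start_m, params$g, params$d, as.integer(n_samples),
                  as.integer(sampling_interval), as.integer(burn_in),
                  unname(moves$probs), as.integer(seed), ideal,
                  return_frames = FALSE, analyze_knots = TRUE,
                  max_window = moves$max_window)
  labels <- identify_knot(r$det1, r$det2)
  knotted <- labels != "0_1"
  p <- mean(knotted)
  se <- blocked_bootstrap_se(knotted, block = block, n_boot = n_boot,
                             seed = seed)
  counts <- sort(table(labels), decreasing = TRUE)
  tibble::tibble(
    n_beads = as.integer(n_beads),
    bp = bp_for_beads(n_beads, params),
    n_samples = as.integer(n_samples),
    p_knot = p,
    se = se,
    p_unknot = 1 - p,
    p_trefoil = mean(labels == "3_1"),
    p_complex = mean(knotted & is_complex_label(labels)),
    counts = list(counts)
  )
}

# blocked bootstrap standard error of the mean of a binary/numeric stream
blocked_bootstrap_se <- function(x, block = 10L, n_boot = 200L, seed = 1L) {
  n <- length(x)
  if (n < 2 * block) {  # too short to block: binomial fallback
    return(sqrt(max(mean(x) * (1 - mean(x)), 1e-12) / n))
  }
  nb <- floor(n / block)
  xb <- vapply(seq_len(nb), function(i)
    mean(x[((i - 1) * block + 1):(i * block)]), 0)
  with_preserved_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(b)
      mean(xb[sample.int(nb, nb, replace = TRUE)]), 0)
    stats::sd(reps)
  })
}
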