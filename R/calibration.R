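#' Simulation grid specification for the probability surface
#'
#' The knotting probability of the model depends on the bead count N and the
#' stiffness g only (the diameter d sets the physical length scale but drops
#' out of the dimensionless chain statistics), so the calibration surface is
#' simulated on an equispaced (N, g) grid. The production-scale default
#' mirrors the 16 x 16 grid with corners N = 250, 1000 and g = 6.5, 14;
#' desk-scale fits use coarser grids.
#'
#' @param n_range Range of bead counts (length 2).
#' @param n_count Number of grid levels along N (>= 2).
#' @param g_range Range of stiffness values (length 2).
#' @param g_count Number of grid levels along g (>= 2).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_range = c(250, 1000), n_count = 16,
                      g_range = c(6.5, 14), g_count = 16) {
  stopifnot(length(n_range) == 2, length(g_range) == 2,
            n_count >= 2, g_count >= 2,
            n_range[1] < n_range[2], g_range[1] < g_range[2])
  structure(list(n_range = n_range, n_count = as.integer(n_count),
                 g_range = g_range, g_count = as.integer(g_count)),
            class = "grid_spec")
}

grid_nodes <- function(grid) {
  tidyr::expand_grid(
    n_beads = as.integer(round(seq(grid$n_range[1], grid$n_range[2],
                                   length.out = grid$n_count))),
    g = seq(grid$g_range[1], grid$g_range[2], length.out = grid$g_count)
  )
}

#' Build the knotting-probability surface P(N, g)
#'
#' Runs [estimate_knotting_probability()] at every node of the grid (each
#' node independently seeded) and fits a local-regression (loess) surface to
#' the simulated probabilities. The fitted surface is the forward map of the
#' calibration: experimental chain lengths are converted to bead counts
#' through a trial diameter d and compared against `P_hat(N(d), g)`.
#'
#' @param grid A [grid_spec()].
#' @param n_samples,sampling_interval,burn_in,moves Sampler settings passed
#'   to [estimate_knotting_probability()] at each node.
#' @param seed Integer seed; node k runs with seed `seed + k`.
#' @param span,degree Loess meta-parameters.
#' @param progress Print one line per grid node.
#' @return An object of class `probability_surface` with the node data
#'   (tibble `data`), the loess `fit`, and the grid hull.
#' @export
build_surface <- function(grid = grid_spec(), n_samples = 400L,
                          sampling_interval = 2L, burn_in = 100L,
                          moves = move_set(), seed = 1L, span = 0.75,
                          degree = 2, progress = FALSE) {
  stopifnot(inherits(grid, "grid_spec"))
  nodes <- grid_nodes(grid)
  sim <- purrr::pmap(list(nodes$n_beads, nodes$g, seq_len(nrow(nodes))),
    function(n, g, k) {
      row <- tryCatch(
        estimate_knotting_probability(
          model_params(g = g, d = 1), n_beads = n, n_samples = n_samples,
          sampling_interval = sampling_interval, burn_in = burn_in,
          seed = seed + k, moves = moves),
        error = function(e)
          stop(sprintf("simulation failed at grid node N = %d, g = %.3f: %s",
                       n, g, conditionMessage(e)), call. = FALSE))
      if (progress)
        message(sprintf("node %d/%d: N = %4d g = %5.2f -> P = %.4f",
                        k, nrow(nodes), n, g, row$p_knot))
      row
    })
  dat <- dplyr::bind_cols(
    nodes,
    dplyr::bind_rows(sim)[, c("p_knot", "se", "p_trefoil", "p_complex")])
  probability_surface(dat, span = span, degree = degree, seed = seed)
}

#' Construct a probability surface from precomputed grid data
#'
#' Fits the loess interpolant to an existing table of simulated (or
#' externally supplied) knotting probabilities. [build_surface()] is the
#' simulate-then-fit convenience wrapper around this constructor.
#'
#' @param data A data frame with columns `n_beads`, `g`, `p_knot` (and
#'   optionally `se`).
#' @param span,degree Loess meta-parameters.
#' @param seed Seed recorded for provenance.
#' @return A `probability_surface`.
#' @export
probability_surface <- function(data, span = 0.75, degree = 2, seed = NA) {
  stopifnot(all(c("n_beads", "g", "p_knot") %in% names(data)))
  dat <- tibble::as_tibble(data)
  fit <- stats::loess(p_knot ~ n_beads * g, data = dat, span = span,
                      degree = degree,
                      control = stats::loess.control(surface = "direct"))
  structure(list(data = dat, fit = fit,
                 n_range = range(dat$n_beads), g_range = range(dat$g),
                 span = span, degree = degree, seed = seed),
            class = "probability_surface")
}

#' @export
print.probability_surface <- function(x, ...) {
  cat(sprintf("<probability_surface> %d nodes, N in [%g, %g], g in [%g, %g]\n",
              nrow(x$data), x$n_range[1], x$n_range[2],
              x$g_range[1], x$g_range[2]))
  cat(sprintf("  loess span %.2f, degree %d; P range [%.4f, %.4f]\n",
              x$span, x$degree, min(x$data$p_knot), max(x$data$p_knot)))
  invisible(x)
}

#' Evaluate the fitted probability surface
#'
#' @param surface A `probability_surface`.
#' @param n_beads,g Coordinates (vectors, recycled).
#' @param warn_extrapolation Warn when a point lies outside the simulated
#'   grid hull.
#' @return Interpolated knotting probabilities, clipped to `[0, 1]`.
#' @export
surface_probability <- function(surface, n_beads, g,
                                warn_extrapolation = TRUE) {
  stopifnot(inherits(surface, "probability_surface"))
  df <- data.frame(n_beads = n_beads, g = g)
  outside <- n_beads < surface$n_range[1] | n_beads > surface$n_range[2] |
    g < surface$g_range[1] | g > surface$g_range[2]
  if (warn_extrapolation && any(outside))
    warning("evaluating the probability surface outside the simulated grid hull",
            call. = FALSE)
  p <- predict(surface$fit, newdata = df)
  pmin(pmax(p, 0), 1)
}

#' Calibration targets
#'
#' A tidy container for experimental knotting probabilities: one row per DNA
#' length with the measured knotting probability and its uncertainty. The
#' electrophoresis data behind the published calibration (5.6, 8.6 and
#' 10 kbp at various salt concentrations) live in the original experimental
#' reports; [synthesize_targets()] generates stand-ins from the model itself
#' for testing the machinery.
#'
#' @param bp DNA lengths in base pairs.
#' @param p_knot Experimental knotting probabilities in `[0, 1]`.
#' @param sigma Experimental standard errors.
#' @param salt Salt-condition label.
#' @return A tibble of class `calibration_targets`.
#' @export
calibration_targets <- function(bp, p_knot, sigma = NA_real_,
                                salt = NA_character_) {
  stopifnot(all(bp > 0), all(p_knot >= 0 & p_knot <= 1))
  out <- tibble::tibble(bp = bp, p_knot = p_knot, sigma = sigma, salt = salt)
  class(out) <- c("calibration_targets", class(out))
  out
}

#' Least-squares calibration error E(g, d)
#'
#' `E(g, d) = sum_i (P_hat(N_i(d), g) - P_i)^2` with `N_i(d) = B_i * 0.34/d`
#' evaluated continuously (no rounding) on the fitted surface. Residuals are
#' unweighted by default; `weighted = TRUE` divides each residual by its
#' experimental sigma.
#'
#' @param g,d Trial stiffness and diameter (nm).
#' @param surface A `probability_surface`.
#' @param targets A [calibration_targets()] tibble.
#' @param weighted Use 1/sigma^2 weighting.
#' @param rise_per_bp Helical rise (nm/bp).
#' @return The scalar error E.
#' @export
calibration_error <- function(g, d, surface, targets, weighted = FALSE,
                              rise_per_bp = 0.34) {
  sum(calibration_residuals(c(g, d), surface, targets, weighted,
                            rise_per_bp)^2)
}

calibration_residuals <- function(par, surface, targets, weighted,
                                  rise_per_bp = 0.34, strict_hull = TRUE) {
  g <- par[1]; d <- par[2]
  n <- targets$bp * rise_per_bp / d
  if (strict_hull) {
    bad <- n < surface$n_range[1] | n > surface$n_range[2] |
      g < surface$g_range[1] | g > surface$g_range[2]
    if (any(bad))
      stop(sprintf("target at %d bp maps to N = %.1f, outside the surface hull",
                   targets$bp[which(bad)[1]], n[which(bad)[1]]), call. = FALSE)
  }
  r <- surface_probability(surface, n, rep(g, length(n)),
                           warn_extrapolation = FALSE) - targets$p_knot
  if (weighted) r <- r / targets$sigma
  r
}

#' Fit the model parameters (g, d) to knotting-probability targets
#'
#' Minimizes the least-squares error between the interpolated surface and
#' the targets with the Levenberg-Marquardt algorithm (`minpack.lm::nls.lm`),
#' restarted from several seeded points inside the search box because the
#' local-regression surface can carry shallow local minima. The box is the
#' largest (g, d) rectangle for which every target maps inside the simulated
#' grid hull. The derived persistence length accompanies the fit.
#'
#' @param surface A `probability_surface`.
#' @param targets A [calibration_targets()] tibble.
#' @param start Optional `c(g, d)` start; by default multi-start sampling is
#'   used.
#' @param n_starts Number of seeded starts.
#' @param seed Integer seed for the starts.
#' @param weighted Use 1/sigma^2 residual weighting.
#' @param rise_per_bp Helical rise (nm/bp).
#' @return An object of class `calibration_result` with elements `g`, `d`,
#'   `error`, `l_p_nm`, `trace` (one row per start), `under_determined`.
#' @export
fit_parameters <- function(surface, targets, start = NULL, n_starts = 5L,
                           seed = 1L, weighted = FALSE, rise_per_bp = 0.34) {
  stopifnot(inherits(surface, "probability_surface"), nrow(targets) >= 1)
  g_box <- surface$g_range
  d_box <- c(max(targets$bp) * rise_per_bp / surface$n_range[2],
             min(targets$bp) * rise_per_bp / surface$n_range[1])
  if (d_box[1] >= d_box[2])
    stop("no diameter maps all targets into the surface hull; widen the grid or drop targets",
         call. = FALSE)
  shrink <- function(b, f = 1e-6) b + c(f, -f) * diff(b)
  g_box <- shrink(g_box); d_box <- shrink(d_box)

  starts <- if (!is.null(start)) {
    matrix(start, nrow = 1)
  } else {
    with_preserved_seed(seed, cbind(
      runif(n_starts, g_box[1], g_box[2]),
      runif(n_starts, d_box[1], d_box[2])))
  }
  runs <- purrr::map(seq_len(nrow(starts)), function(i) {
    p0 <- starts[i, ]
    # LM needs at least as many residuals as parameters; zero-padding keeps
    # a deliberately under-determined single-target fit runnable (it is
    # flagged below)
    resid_fn <- function(par) {
      r <- calibration_residuals(par, surface, targets, weighted,
                                 rise_per_bp, strict_hull = FALSE)
      if (length(r) < 2) r <- c(r, rep(0, 2 - length(r)))
      r
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = p0, fn = resid_fn,
        lower = c(g_box[1], d_box[1]), upper = c(g_box[2], d_box[2]),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    tibble::tibble(start_g = p0[1], start_d = p0[2],
                   g = fit$par[1], d = fit$par[2],
                   error = sum(fit$fvec^2), converged = fit$info %in% 1:4)
  })
  trace <- dplyr::bind_rows(runs)
  if (nrow(trace) == 0 || !any(trace$converged))
    stop("Levenberg-Marquardt failed to converge from every start",
         call. = FALSE)
  best <- trace[which.min(trace$error), ]
  # flat-direction diagnostic from the numerical Jacobian at the optimum
  jac <- numeric_jacobian(function(p)
    calibration_residuals(p, surface, targets, weighted, rise_per_bp,
                          strict_hull = FALSE), c(best$g, best$d))
  sv <- svd(jac)$d
  under <- nrow(targets) < 2 || sv[2] < 1e-8 * max(sv[1], 1e-12)
  if (under)
    warning("fit is under-determined: a flat direction in (g, d) remains",
            call. = FALSE)
  structure(list(g = best$g, d = best$d, error = best$error,
                 l_p_nm = persistence_length(best$g, best$d),
                 trace = trace, targets = targets,
                 under_determined = under, weighted = weighted),
            class = "calibration_result")
}

numeric_jacobian <- function(fn, p, h = 1e-4) {
  f0 <- fn(p)
  vapply(seq_along(p), function(j) {
    pj <- p; pj[j] <- pj[j] + h
    (fn(pj) - f0) / h
  }, numeric(length(f0)))
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n")
  cat(sprintf("  g = %.4f, d = %.4f nm, E = %.3e\n", x$g, x$d, x$error))
  cat(sprintf("  persistence length l_p = %.3f nm\n", x$l_p_nm))
  cat(sprintf("  %d starts, %d converged%s\n", nrow(x$trace),
              sum(x$trace$converged),
              if (x$under_determined) " (UNDER-DETERMINED)" else ""))
  invisible(x)
}

#' Synthesize calibration targets from the model itself
#'
#' Simulates the knotting probability at each requested DNA length under a
#' known parameter set and adds Gaussian noise, producing targets whose
#' ground truth is known by construction. This is the stand-in for the
#' experimental gel-electrophoresis probabilities used in
#' parameter-recovery tests of the calibration pipeline.
#'
#' @param g_true,d_true Ground-truth parameters.
#' @param lengths_bp DNA lengths in base pairs.
#' @param noise_sd Gaussian noise added to each probability.
#' @param seed Integer seed (simulation and noise are both deterministic
#'   given the seed).
#' @param n_samples,sampling_interval,burn_in,moves Sampler settings.
#' @return A [calibration_targets()] tibble with attribute `truth`.
#' @export
synthesize_targets <- function(g_true, d_true, lengths_bp, noise_sd = 0.005,
                               seed = 1L, n_samples = 800L,
                               sampling_interval = 2L, burn_in = 100L,
                               moves = move_set()) {
  params <- model_params(g = g_true, d = d_true)
  sims <- purrr::imap(lengths_bp, function(bp, k) {
    n <- beads_for_bp(bp, params)
    estimate_knotting_probability(
      model_params(g = g_true, d = 1), n_beads = n, n_samples = n_samples,
      sampling_interval = sampling_interval, burn_in = burn_in,
      seed = seed + 1000L * k, moves = moves)
  })
  p_sim <- vapply(sims, function(s) s$p_knot, 0)
  se_sim <- vapply(sims, function(s) s$se, 0)
  noise <- if (noise_sd > 0)
    with_preserved_seed(seed, rnorm(length(lengths_bp), 0, noise_sd))
  else rep(0, length(lengths_bp))
  out <- calibration_targets(
    bp = lengths_bp,
    p_knot = pmin(pmax(p_sim + noise, 0), 1),
    sigma = pmax(noise_sd, se_sim),
    salt = "synthetic")
  attr(out, "truth") <- c(g = g_true, d = d_true)
  out
}
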