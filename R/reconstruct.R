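#' Optimizer configuration
#'
#' Collects the tunable parameters of the reconstruction.  Defaults follow
#' common practice for Hi-C data: `alpha = 0.5` for the frequency-distance
#' power law, convergence factor `beta = 0.1` (larger values damp the step
#' and slow convergence), stopping tolerance `tol = 1e-6` on the change of
#' the objective, and an iteration cap of 20000.
#'
#' @param alpha exponent of the frequency-to-distance power law.
#' @param beta convergence factor (>= 0); the per-pair resultant weight is
#'   `coCC_ij / (N-1)^beta`, so larger values damp the step and slow
#'   convergence.
#' @param tol stopping tolerance on `|F_t - F_(t-1)|`.
#' @param max_iter iteration cap (>= 1).
#' @param seed integer random seed for the coordinate initialization (and
#'   the coincident-point jitter guard).
#' @param init_scale multiplier for the initial coordinate spread relative
#'   to the mean finite target distance.
#' @return object of class `OptimizerConfig`.
#' @export
evrc_config <- function(alpha = 0.5, beta = 0.1, tol = 1e-6,
                        max_iter = 20000L, seed = 1L, init_scale = 1.0) {
  stopifnot(tol > 0, max_iter >= 1, beta >= 0, init_scale > 0)
  structure(list(alpha = alpha, beta = beta, tol = tol,
                 max_iter = as.integer(max_iter), seed = as.integer(seed),
                 init_scale = init_scale), class = "OptimizerConfig")
}

#' Random initial coordinates
#'
#' Draws `n` points uniformly in a cube whose side is
#' `init_scale * mean(finite D_ij)`, deterministically for a given seed.
#' For `n = 2` coincident draws are re-drawn so the two points are
#' distinct.
#'
#' @param n number of bins (>= 2).
#' @param config an [evrc_config()]; `seed` and `init_scale` are used.
#' @param D the `DistanceMatrix`, used only for its mean finite distance.
#' @return a [evrc_structure()] with `n` rows.
#' @export
init_coords <- function(n, config, D) {
  if (n < 2) stop("need at least 2 bins to reconstruct")
  ut <- D$D[upper.tri(D$D)]
  side <- config$init_scale * mean(ut[is.finite(ut)])
  set.seed(config$seed)
  P <- matrix(runif(3 * n, 0, side), n, 3)
  while (n == 2 && sqrt(sum((P[1, ] - P[2, ])^2)) < 1e-12)
    P <- matrix(runif(3 * n, 0, side), n, 3)
  evrc_structure(P, chains = D$chains)
}

#' Error vector of one bin pair
#'
#' `E_ij = unit(P_i - P_j) * (|P_i - P_j| - D_ij)`: a vector along the
#' line joining the two bins whose signed magnitude is the violation of
#' the target distance.  Added to `P_j` it moves bin `j` toward bin `i`
#' when the pair is too far apart and away when too close.  When the two
#' points are (numerically) coincident the direction is undefined and a
#' seeded-random unit direction of magnitude `D_ij` is returned.
#'
#' @param P_i,P_j 3-vectors of coordinates.
#' @param D_ij finite positive target distance.
#' @return 3-vector.
#' @export
error_vector <- function(P_i, P_j, D_ij) {
  if (!all(is.finite(P_i)) || !all(is.finite(P_j)) || !is.finite(D_ij))
    stop("error_vector needs finite coordinates and a finite target distance")
  d <- P_i - P_j
  nd <- sqrt(sum(d^2))
  if (nd < 1e-12) {
    u <- runif(3, -1, 1)
    nu <- sqrt(sum(u^2))
    if (nu < 1e-12) u <- c(1, 0, 0) else u <- u / nu
    return(u * D_ij)
  }
  d / nd * (nd - D_ij)
}

#' Weighted resultant error vector of one bin
#'
#' `E_j = sum over i != j, D_ij finite, of w_ij * E_ij` with
#' `w_ij = coCC_ij / (N-1)^beta` and `N` the total number of kept bins.
#' The per-iteration displacement of bin `j` is this resultant damped by
#' `1/(N-1)` (see [evrc_step()]).
#'
#' @param j bin index (1-based).
#' @param S current [evrc_structure()].
#' @param D `DistanceMatrix` of targets.
#' @param W [cocc_matrix()] weights.
#' @param beta convergence factor.
#' @return 3-vector.
#' @export
resultant <- function(j, S, D, W, beta = 0.1) {
  P <- S$coords
  n <- nrow(P)
  if (j < 1 || j > n) stop("bin index out of range: ", j)
  wnorm <- (n - 1)^beta
  E <- c(0, 0, 0)
  for (i in seq_len(n)) {
    if (i == j || !is.finite(D$D[i, j])) next
    E <- E + W$values[i, j] / wnorm * error_vector(P[i, ], P[j, ], D$D[i, j])
  }
  E
}

#' Optimization objective
#'
#' `F = sum over bins j of |E_j|`, the summed magnitude of all weighted
#' resultants; zero exactly when every resultant vanishes.
#'
#' @inheritParams resultant
#' @return non-negative scalar.
#' @export
evrc_objective <- function(S, D, W, beta = 0.1) {
  sum(vapply(seq_len(nrow(S$coords)),
             function(j) sqrt(sum(resultant(j, S, D, W, beta)^2)),
             numeric(1)))
}

#' One synchronous optimization step
#'
#' Computes all resultants from the current coordinates, then moves every
#' bin simultaneously along its resultant, damped by the bin count:
#' `P_j <- P_j + E_j / (N-1)`.  (The undamped move amplifies rather than
#' shrinks the constraint violations whenever many pairs pull in similar
#' directions; dividing by `N-1` turns the move into a weighted mean of
#' the per-pair error vectors, which preserves the fixed points and is
#' stable at any `N`.)  Returns the updated structure and the objective
#' `F` evaluated on the pre-update coordinates.
#'
#' @inheritParams resultant
#' @return list with `S` (updated structure) and `F` (pre-update
#'   objective).
#' @export
evrc_step <- function(S, D, W, beta = 0.1) {
  n <- nrow(S$coords)
  E <- t(vapply(seq_len(n), function(j) resultant(j, S, D, W, beta),
                numeric(3)))
  F_val <- sum(sqrt(rowSums(E^2)))
  P <- S$coords + E / (n - 1)
  if (any(!is.finite(P)))
    stop("non-finite coordinates produced in optimization step")
  list(S = evrc_structure(P, chains = S$chains, index_map = S$index_map),
       F = F_val)
}

#' Run the error-vector resultant reconstruction
#'
#' Starting from seeded-random coordinates, repeats [evrc_step()] until
#' the objective change `|F_t - F_(t-1)|` stays below `tol` (for 10
#' consecutive iterations, guarding against transient stalls) or
#' `max_iter` is reached.  The returned trace records every per-iteration
#' objective value; the whole run is reproducible bit-for-bit given the
#' seed.  A run whose objective rises for 100 consecutive iterations (or
#' goes non-finite) aborts with a divergence error suggesting a larger
#' `beta`.
#'
#' @param D `DistanceMatrix` of target distances.
#' @param W matching [cocc_matrix()]; pairs with `D_ij = Inf` contribute
#'   nothing regardless of their weight.
#' @param config an [evrc_config()].
#' @param init optional [evrc_structure()] of starting coordinates
#'   (defaults to [init_coords()]).
#' @return list with `S` (the reconstructed [evrc_structure()]) and
#'   `trace` (class `OptimizerTrace`: `F_values`, `iterations_run`,
#'   `converged`, `final_dF`).
#' @export
evrc_run <- function(D, W, config = evrc_config(), init = NULL) {
  stopifnot(inherits(D, "DistanceMatrix"), inherits(W, "CoCCMatrix"))
  if (D$n_bins != W$n_bins)
    stop("distance matrix and weight matrix sizes differ")
  if (is.null(init)) init <- init_coords(D$n_bins, config, D)
  set.seed(config$seed + 1L)   # RNG stream for the jitter guard
  res <- evrc_iterate_cpp(init$coords, D$D, W$values, config$beta,
                          config$tol, config$max_iter,
                          10L,    # consecutive sub-tol iterations to stop
                          100L)   # consecutive rises declared divergence
  if (res$diverged_at > 0)
    stop("optimization diverged at iteration ", res$diverged_at,
         "; consider a larger beta (stronger damping)")
  trace <- structure(list(F_values = res$F_values,
                          iterations_run = res$iterations,
                          converged = res$converged,
                          final_dF = res$final_dF),
                     class = "OptimizerTrace")
  list(S = evrc_structure(res$coords, chains = D$chains,
                          index_map = bin_index_map(D$chains,
                                                    local_bin_indices(D$chains))),
       trace = trace)
}

#' @export
print.OptimizerTrace <- function(x, ...) {
  cat("OptimizerTrace:", x$iterations_run, "iterations,",
      if (x$converged) "converged" else "iteration cap reached",
      "| final F =", signif(utils::tail(x$F_values, 1), 4),
      "| final dF =", signif(x$final_dF, 4), "\n")
  invisible(x)
}

#' Gaussian smoothing along the chain
#'
#' For visualization only: each coordinate axis is filtered along the bin
#' order with a truncated Gaussian kernel of standard deviation `sigma`
#' (in bins), independently per chain so chain boundaries never blend.
#' Kernel weights falling outside the chain are dropped and the remainder
#' renormalised.  `sigma = "auto"` (the default) returns the input
#' unchanged — evaluation metrics must always use unsmoothed coordinates.
#'
#' @param S a [evrc_structure()].
#' @param sigma positive standard deviation in bins, or `"auto"` for no
#'   smoothing.
#' @return a smoothed [evrc_structure()].
#' @export
smooth_structure <- function(S, sigma = "auto") {
  stopifnot(inherits(S, "Structure"))
  if (identical(sigma, "auto")) return(S)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("sigma must be a positive number or \"auto\"")
  half <- max(1L, ceiling(4 * sigma))
  kern <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  P <- S$coords
  out <- P
  for (ch in unique(S$chains)) {
    idx <- which(S$chains == ch)
    m <- length(idx)
    for (a in 1:3) {
      v <- P[idx, a]
      sm <- numeric(m)
      for (t in seq_len(m)) {
        lo <- max(1L, t - half); hi <- min(m, t + half)
        w <- kern[(lo - t + half + 1L):(hi - t + half + 1L)]
        sm[t] <- sum(w * v[lo:hi]) / sum(w)
      }
      out[idx, a] <- sm
    }
  }
  evrc_structure(out, chains = S$chains, index_map = S$index_map)
}
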