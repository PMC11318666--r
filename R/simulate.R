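#' Specification of a simulated model structure
#'
#' Six canonical curve structures of increasing complexity serve as the
#' simulation test bed: three single-chain curves — `circle`, `spiral`
#' (open helix), `circular_spiral` (a helix wound around a torus and
#' closed end to end) — and three double-chain structures emulating
#' multi-chromosome systems — `replication_fork` (two chains sharing a
#' common trunk, then diverging smoothly), `double_helix` (two anti-phase
#' helices), and `double_spherical_helix` (two phase-shifted
#' latitude-sweeping spirals on a sphere).  Each structure totals
#' `n_points` points; double-chain models split them evenly across the two
#' chains.
#'
#' @param name one of `"circle"`, `"spiral"`, `"circular_spiral"`,
#'   `"replication_fork"`, `"double_helix"`, `"double_spherical_helix"`.
#' @param n_points total number of points (>= 4); 500 by default.
#' @param geometry named list overriding the canonical geometry defaults
#'   (see Details).
#'
#' @details Canonical geometry (all overridable via `geometry`):
#' * circle: `radius = 1`.
#' * spiral: `radius = 1`, `turns = 4`, `height = 4`.
#' * circular_spiral: torus `major_radius = 3`, `minor_radius = 1`,
#'   `windings = 16`, closed.
#' * replication_fork: trunk of length 2 along x with strand offset
#'   `offset = 0.05`, then quadratic divergence of the two branches.
#' * double_helix: `radius = 1`, `turns = 4`, `height = 4`, chains in
#'   anti-phase.
#' * double_spherical_helix: unit sphere, `windings = 8`, polar angle
#'   swept over `[0.05, 0.95] * pi` (poles trimmed so the chains never
#'   touch), second chain phase-shifted by pi.
#' @return object of class `ModelSpec`.
#' @export
model_spec <- function(name, n_points = 500L, geometry = list()) {
  names_ok <- c("circle", "spiral", "circular_spiral", "replication_fork",
                "double_helix", "double_spherical_helix")
  if (!name %in% names_ok)
    stop("unknown model name '", name, "'; expected one of: ",
         paste(names_ok, collapse = ", "))
  n_points <- as.integer(n_points)
  if (n_points < 4) stop("n_points must be at least 4")
  structure(list(name = name, n_points = n_points, geometry = geometry),
            class = "ModelSpec")
}

#' Names of the six simulated model structures
#' @return character vector of the six model names.
#' @export
model_names <- function() {
  c("circle", "spiral", "circular_spiral", "replication_fork",
    "double_helix", "double_spherical_helix")
}

#' Generate a model structure
#'
#' Deterministic closed-form parameterization of the curve named in the
#' spec; single-chain models are labelled `"A"`, double-chain models
#' `"A"`/`"B"` with `n_points/2` points each.
#'
#' @param spec a [model_spec()].
#' @return a [evrc_structure()].
#' @export
generate_model <- function(spec) {
  stopifnot(inherits(spec, "ModelSpec"))
  n <- spec$n_points
  g <- function(key, default)
    if (!is.null(spec$geometry[[key]])) spec$geometry[[key]] else default
  two_chain <- function(P1, P2) {
    evrc_structure(rbind(P1, P2),
                   chains = rep(c("A", "B"), c(nrow(P1), nrow(P2))))
  }
  switch(spec$name,
    circle = {
      r <- g("radius", 1)
      t <- 2 * pi * (seq_len(n) - 1) / n
      evrc_structure(cbind(r * cos(t), r * sin(t), 0), chains = "A")
    },
    spiral = {
      r <- g("radius", 1); turns <- g("turns", 4); h <- g("height", 4)
      t <- seq(0, 2 * pi * turns, length.out = n)
      evrc_structure(cbind(r * cos(t), r * sin(t), h * t / (2 * pi * turns)),
                     chains = "A")
    },
    circular_spiral = {
      R <- g("major_radius", 3); r <- g("minor_radius", 1)
      w <- g("windings", 16)
      th <- 2 * pi * (seq_len(n) - 1) / n      # closed: no endpoint repeat
      ph <- w * th
      evrc_structure(cbind((R + r * cos(ph)) * cos(th),
                           (R + r * cos(ph)) * sin(th),
                           r * sin(ph)), chains = "A")
    },
    replication_fork = {
      m <- n %/% 2
      off <- g("offset", 0.05); len <- g("length", 4)
      t <- seq(0, 1, length.out = m)
      br <- ifelse(t < 0.5, 0, 2 * (t - 0.5)^2)  # smooth divergence
      P1 <- cbind(len * t, off + br, 0)
      P2 <- cbind(len * t, -off - br, 0)
      two_chain(P1, P2)
    },
    double_helix = {
      r <- g("radius", 1); turns <- g("turns", 4); h <- g("height", 4)
      m <- n %/% 2
      t <- seq(0, 2 * pi * turns, length.out = m)
      z <- h * t / (2 * pi * turns)
      P1 <- cbind(r * cos(t), r * sin(t), z)
      P2 <- cbind(r * cos(t + pi), r * sin(t + pi), z)
      two_chain(P1, P2)
    },
    double_spherical_helix = {
      w <- g("windings", 8); r <- g("radius", 1)
      m <- n %/% 2
      t <- seq(0, 1, length.out = m)
      th <- pi * (0.05 + 0.90 * t)             # poles trimmed
      sph <- function(phase) {
        ph <- 2 * pi * w * t + phase
        cbind(r * sin(th) * cos(ph), r * sin(th) * sin(ph), r * cos(th))
      }
      two_chain(sph(0), sph(pi))
    })
}

#' Derive contact frequencies from a structure
#'
#' The interaction frequency of each pair is the reciprocal of its spatial
#' distance, `F_ij = 1 / |P_i - P_j|`, spanning intra- and inter-chain
#' pairs alike; the diagonal is 0.
#'
#' @param S a [evrc_structure()] with no two points coincident.
#' @return a [contact_matrix()].
#' @export
contacts_from_structure <- function(S) {
  stopifnot(inherits(S, "Structure"))
  d <- as.matrix(stats::dist(S$coords))
  off <- d[upper.tri(d)]
  if (any(off < 1e-12))
    stop("degenerate structure: coincident points have no finite frequency")
  F <- 1 / d
  diag(F) <- 0
  contact_matrix(F, chains = S$chains)
}

#' Pairwise distances of a structure as a DistanceMatrix
#'
#' Convenience for the simulation pipeline (all pairs finite,
#' `alpha_used = 1`).
#'
#' @param S a [evrc_structure()].
#' @return a `DistanceMatrix`.
#' @export
structure_distances <- function(S) {
  new_distance_matrix(as.matrix(stats::dist(S$coords)), alpha_used = 1,
                      chains = S$chains)
}

#' Noise specification
#'
#' @param s noise level in `[0, 1]`.
#' @param seed integer random seed.
#' @return object of class `NoiseSpec`.
#' @export
noise_spec <- function(s, seed = 1L) {
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 0 || s > 1)
    stop("noise level s must lie in [0, 1]")
  structure(list(s = s, seed = as.integer(seed)), class = "NoiseSpec")
}

#' Add multiplicative noise to target distances
#'
#' Each finite distance is independently multiplied by `(1 + r * s)` with
#' `r` uniform on `[-1, 1]`, drawn once per unordered pair so the matrix
#' stays symmetric.  Results are clamped below at `1e-9` times the
#' original value (relevant only at `s = 1` when `r` approaches `-1`);
#' `Inf` entries are untouched.  Deterministic for a given seed.
#'
#' @param D a `DistanceMatrix` with positive finite entries.
#' @param noise a [noise_spec()].
#' @return a noisy `DistanceMatrix`.
#' @export
add_noise <- function(D, noise) {
  stopifnot(inherits(D, "DistanceMatrix"), inherits(noise, "NoiseSpec"))
  M <- D$D
  ut <- upper.tri(M)
  set.seed(noise$seed)
  r <- runif(sum(ut), -1, 1)
  v <- M[ut]
  fin <- is.finite(v)
  v[fin] <- pmax(v[fin] * (1 + r[fin] * noise$s), 1e-9 * v[fin])
  M[ut] <- v
  M <- t(M); M[ut] <- v; M <- t(M)   # mirror into the lower triangle
  new_distance_matrix(M, alpha_used = D$alpha_used, chains = D$chains)
}

#' Simulate noisy contacts for a model structure
#'
#' Full pipeline: generate the model, take pairwise distances, perturb
#' them with multiplicative noise (noise is applied to distances, before
#' the conversion to frequencies), then set `F = 1 / D_noisy`.
#'
#' @param spec a [model_spec()].
#' @param noise a [noise_spec()].
#' @return list with `S` (ground-truth structure) and `contacts` (noisy
#'   [contact_matrix()]).
#' @export
noisy_contacts <- function(spec, noise) {
  S <- generate_model(spec)
  Dn <- add_noise(structure_distances(S), noise)
  F <- 1 / Dn$D
  diag(F) <- 0
  list(S = S, contacts = contact_matrix(F, chains = S$chains))
}
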