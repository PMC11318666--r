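#' Least-squares superposition of two structures
#'
#' Finds the translation + rotation (optionally improper rotation, i.e.
#' reflection; optionally uniform scale) of `B` that minimises the mean
#' squared residual to `A`, by the SVD (Kabsch) solution, and reports the
#' post-fit RMSD.  Reflection is allowed by default because contact data
#' cannot determine chirality; scale matching is off by default since the
#' frequency-distance power law fixes the absolute scale.
#'
#' @param A,B [evrc_structure()]s (or n x 3 matrices) with equal bin
#'   counts, bins corresponding by row.
#' @param allow_reflection permit an improper rotation (det = -1).
#' @param allow_scale also fit a uniform scale factor applied to `B`.
#' @return object of class `AlignmentResult`: `rotation` (3 x 3,
#'   applied on the right: `B %*% rotation`), `translation`, `scale`,
#'   `reflection_used`, `rmsd`, and `B_aligned` (transformed coordinates).
#' @export
superpose <- function(A, B, allow_reflection = TRUE, allow_scale = FALSE) {
  PA <- if (inherits(A, "Structure")) A$coords else as.matrix(A)
  PB <- if (inherits(B, "Structure")) B$coords else as.matrix(B)
  if (nrow(PA) != nrow(PB))
    stop("structures have different bin counts: ", nrow(PA), " vs ", nrow(PB))
  n <- nrow(PA)
  cA <- colMeans(PA); cB <- colMeans(PB)
  X <- sweep(PB, 2, cB); Y <- sweep(PA, 2, cA)
  if (allow_scale) {
    # scale fitting needs a genuinely 3D-determined problem
    if (n < 3 || qr(X)$rank < 2)
      stop("degenerate alignment: scale fitting needs >= 3 non-collinear points")
  }
  sv <- svd(t(X) %*% Y)
  d <- sign(det(sv$u %*% t(sv$v)))
  refl <- FALSE
  if (allow_reflection) {
    R <- sv$u %*% t(sv$v)            # unconstrained orthogonal optimum
    refl <- d < 0
  } else {
    S <- diag(c(1, 1, d))            # constrain to a proper rotation
    R <- sv$u %*% S %*% t(sv$v)
  }
  sing <- sv$d
  if (!allow_reflection && d < 0) sing[3] <- -sing[3]
  scl <- if (allow_scale) sum(sing) / sum(X^2) else 1
  Bt <- scl * (X %*% R)
  Bt <- sweep(Bt, 2, cA, `+`)
  rmsd_val <- sqrt(mean(rowSums((Bt - PA)^2)))
  structure(list(rotation = R, translation = cA - cB %*% R * scl,
                 scale = scl, reflection_used = refl, rmsd = rmsd_val,
                 B_aligned = Bt),
            class = "AlignmentResult")
}

#' @export
print.AlignmentResult <- function(x, ...) {
  cat("AlignmentResult: rmsd =", signif(x$rmsd, 6),
      "| scale =", signif(x$scale, 6),
      "| reflection", if (x$reflection_used) "used" else "not used", "\n")
  invisible(x)
}

#' Superposition RMSD between two structures
#'
#' Convenience wrapper around [superpose()] with reflection allowed and
#' scale disabled (the defaults); the value is in the length units of the
#' first (reference) structure.
#'
#' @inheritParams superpose
#' @param ... passed to [superpose()].
#' @return non-negative RMSD.
#' @export
rmsd <- function(A, B, ...) superpose(A, B, ...)$rmsd

#' Pearson correlation of pairwise distances
#'
#' Correlates the upper-triangle pairwise-distance vectors of the two
#' structures over all bin pairs (including inter-chain pairs).  Invariant
#' under rigid motion, reflection, and uniform scaling of either
#' structure.
#'
#' @inheritParams superpose
#' @return Pearson correlation in `[-1, 1]`.
#' @export
distance_pcc <- function(A, B) {
  PA <- if (inherits(A, "Structure")) A$coords else as.matrix(A)
  PB <- if (inherits(B, "Structure")) B$coords else as.matrix(B)
  if (nrow(PA) != nrow(PB))
    stop("structures have different bin counts")
  if (nrow(PA) < 3)
    stop("need at least 3 bins for a distance correlation")
  dA <- as.vector(stats::dist(PA))
  dB <- as.vector(stats::dist(PB))
  if (stats::sd(dA) == 0 || stats::sd(dB) == 0)
    stop("zero-variance distance vector: correlation undefined")
  stats::cor(dA, dB)
}

#' Spearman correlation of recovered contact frequencies
#'
#' Back-computes frequencies from the reconstructed geometry by inverting
#' the power law, `F'_ij = d_ij^(-1/alpha)` with `d_ij` the Euclidean
#' distance in `S`, and rank-correlates them with the input frequencies
#' over all pairs with `F_ij > 0` (zero-frequency pairs map to infinite
#' distance and carry no recoverable rank).  Average ranks are used for
#' ties; the value is invariant under uniform rescaling of `S`.
#'
#' @param C_input the input [contact_matrix()].
#' @param S the reconstructed [evrc_structure()] (unsmoothed).
#' @param alpha the exponent used in the frequency-to-distance conversion.
#' @return Spearman correlation in `[-1, 1]`.
#' @export
recovered_scc <- function(C_input, S, alpha = 0.5) {
  stopifnot(inherits(C_input, "ContactMatrix"), inherits(S, "Structure"))
  if (C_input$n_bins != nrow(S$coords))
    stop("contact matrix and structure sizes differ")
  ut <- upper.tri(C_input$F)
  f_in <- C_input$F[ut]
  pos <- f_in > 0
  if (!any(pos))
    stop("no positive input frequencies: correlation undefined")
  d <- as.matrix(stats::dist(S$coords))[ut]
  f_rec <- d[pos]^(-1 / alpha)
  stats::cor(f_in[pos], f_rec, method = "spearman")
}

#' Structure diameter
#'
#' Largest pairwise distance; handy for expressing RMSD as a fraction of
#' structure size.
#'
#' @param S a [evrc_structure()] or n x 3 matrix.
#' @return positive scalar.
#' @export
structure_diameter <- function(S) {
  P <- if (inherits(S, "Structure")) S$coords else as.matrix(S)
  max(stats::dist(P))
}
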