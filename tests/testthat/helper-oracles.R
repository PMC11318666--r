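# Shared fixtures and independent oracles used across the suite.

# Build a ContactGraph directly from an edge list (1-based node pairs).
graph_from_edges <- function(n, edges) {
  A <- matrix(FALSE, n, n)
  for (e in edges) {
    A[e[1], e[2]] <- TRUE
    A[e[2], e[1]] <- TRUE
  }
  structure(list(n_nodes = n, adjacency = A), class = "ContactGraph")
}

# Random Erdos-Renyi contact graph at a given edge density.
random_graph <- function(n, density, seed) {
  set.seed(seed)
  A <- matrix(FALSE, n, n)
  ut <- upper.tri(A)
  A[ut] <- runif(sum(ut)) < density
  A <- A | t(A)
  structure(list(n_nodes = n, adjacency = A), class = "ContactGraph")
}

# Independent coCC oracle: edge-list membership recount, no adjacency
# submatrix arithmetic shared with the implementation.
cocc_oracle <- function(g, i, j) {
  A <- g$adjacency
  U <- sort(unique(c(which(A[i, ]), which(A[j, ]))))
  k <- length(U)
  if (k <= 1) return(0)
  el <- which(A & upper.tri(A), arr.ind = TRUE)
  e <- sum(el[, 1] %in% U & el[, 2] %in% U)
  2 * e / (k * (k - 1))
}

# Term-by-term resultant oracle: literal sum of weighted error vectors.
resultant_oracle <- function(j, P, D, W, beta) {
  n <- nrow(P)
  E <- c(0, 0, 0)
  for (i in seq_len(n)) {
    if (i == j || !is.finite(D[i, j])) next
    d <- P[i, ] - P[j, ]
    nd <- sqrt(sum(d^2))
    E <- E + W[i, j] / (n - 1)^beta * (d / nd * (nd - D[i, j]))
  }
  E
}

objective_oracle <- function(P, D, W, beta) {
  sum(sapply(seq_len(nrow(P)), function(j)
    sqrt(sum(resultant_oracle(j, P, D, W, beta)^2))))
}

# DistanceMatrix from a plain matrix (Inf marks missing pairs).
dist_mat <- function(M, chains = "chr", alpha_used = 1) {
  diag(M) <- 0
  structure(list(D = unname(M), n_bins = nrow(M), alpha_used = alpha_used,
                 chains = rep(chains, length.out = nrow(M))),
            class = "DistanceMatrix")
}

# Random rigid motion (proper rotation + translation) applied to coords.
apply_rigid <- function(P, seed, reflect = FALSE) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]          # make proper
  if (reflect) Q[, 1] <- -Q[, 1]
  sweep(P %*% Q, 2, rnorm(3, sd = 5), `+`)
}

# Small full reconstruction used by several tests.
reconstruct_model <- function(name, n, s = 0, seed = 1, ...) {
  sim <- noisy_contacts(model_spec(name, n), noise_spec(s, seed = seed))
  D <- freq_to_dist(sim$contacts, alpha = 1)
  W <- cocc_matrix(build_graph(D))
  fit <- evrc_run(D, W, evrc_config(alpha = 1, seed = seed, ...))
  list(sim = sim, D = D, W = W, fit = fit)
}
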