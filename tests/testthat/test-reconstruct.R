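test_that("initial coordinates are seeded, bounded, and distinct for n = 2", {
  D <- dist_mat(matrix(2, 10, 10))
  cfg <- evrc_config(seed = 5)
  A <- init_coords(10, cfg, D)
  B <- init_coords(10, cfg, D)
  expect_identical(A$coords, B$coords)
  C <- init_coords(10, evrc_config(seed = 6), D)
  expect_false(identical(A$coords, C$coords))
  expect_true(all(A$coords >= 0 & A$coords <= 2))   # mean finite D = 2

  D2 <- dist_mat(matrix(1, 2, 2))
  P2 <- init_coords(2, cfg, D2)$coords
  expect_gt(sqrt(sum((P2[1, ] - P2[2, ])^2)), 0)

  expect_error(init_coords(1, cfg, D), "at least 2")
})

test_that("error vector points along the pair axis with signed magnitude", {
  expect_equal(error_vector(c(2, 0, 0), c(0, 0, 0), 1), c(1, 0, 0))
  expect_equal(error_vector(c(0, 3, 0), c(0, 0, 0), 3), c(0, 0, 0))
  # too-close pair is pushed apart: P_j below target distance from P_i
  expect_equal(error_vector(c(0, 0, 0), c(0, 0, 3), 5), c(0, 0, 2))
  # cross-check against the plain formula on random inputs
  set.seed(11)
  for (k in 1:20) {
    Pi <- rnorm(3); Pj <- rnorm(3); Dij <- runif(1, 0.1, 3)
    d <- Pi - Pj; nd <- sqrt(sum(d^2))
    expect_equal(error_vector(Pi, Pj, Dij), d / nd * (nd - Dij))
  }
  expect_error(error_vector(c(NA, 0, 0), c(0, 0, 0), 1), "finite")
})

test_that("resultant and objective equal term-by-term brute force", {
  # satisfied constraints: everything vanishes
  t <- 2 * pi * (0:5) / 6
  P <- cbind(cos(t), sin(t), 0)
  D <- dist_mat(as.matrix(dist(P)))
  W <- structure(list(values = matrix(1, 6, 6), n_bins = 6),
                 class = "CoCCMatrix")
  S <- evrc_structure(P)
  expect_equal(resultant(3, S, D, W), c(0, 0, 0))
  expect_equal(evrc_objective(S, D, W), 0)

  # N = 2: weight reduces to the coCC alone
  P2 <- rbind(c(0, 0, 0), c(2, 0, 0))
  D2 <- dist_mat(matrix(1, 2, 2))
  for (cval in c(1, 0.35)) {
    W2 <- structure(list(values = matrix(cval, 2, 2), n_bins = 2),
                    class = "CoCCMatrix")
    S2 <- evrc_structure(P2)
    expect_equal(resultant(2, S2, D2, W2, beta = 0),
                 cval * error_vector(P2[1, ], P2[2, ], 1))
  }

  # random instances vs the independent oracle, including missing pairs
  set.seed(21)
  for (n in c(4, 10, 20)) {
    P <- matrix(rnorm(3 * n), n, 3)
    M <- as.matrix(dist(P)) * exp(rnorm(n * n, sd = 0.2))
    M <- (M + t(M)) / 2
    M[sample(n * n, n)] <- Inf
    M <- pmax(M, t(M))                      # keep symmetric
    D <- dist_mat(M)
    Wv <- matrix(runif(n * n), n, n); Wv <- (Wv + t(Wv)) / 2
    W <- structure(list(values = Wv, n_bins = n), class = "CoCCMatrix")
    S <- evrc_structure(P)
    for (j in sample(n, 3))
      expect_equal(resultant(j, S, D, W, beta = 0.1),
                   resultant_oracle(j, P, D$D, Wv, 0.1))
    expect_equal(evrc_objective(S, D, W, beta = 0.1),
                 objective_oracle(P, D$D, Wv, 0.1))
  }
})

test_that("a perfectly embedded structure is a fixed point of the step", {
  t <- seq(0, 2 * pi, length.out = 13)[-13]
  P <- cbind(cos(t), sin(t), t / 5)
  D <- dist_mat(as.matrix(dist(P)))
  W <- cocc_matrix(build_graph(D))
  out <- evrc_step(evrc_structure(P), D, W)
  expect_equal(out$S$coords, P)
  expect_equal(out$F, 0)
})

test_that("the two-bin synchronous step overshoots as predicted", {
  # both bins move toward each other by the full violation: the known
  # synchronous overshoot at tiny N (the (N-1) damping is 1 here)
  P <- rbind(c(0, 0, 0), c(2, 0, 0))
  D <- dist_mat(matrix(1, 2, 2))
  W <- structure(list(values = matrix(1, 2, 2), n_bins = 2),
                 class = "CoCCMatrix")
  out <- evrc_step(evrc_structure(P), D, W, beta = 0)
  expect_equal(out$S$coords[1, ], c(1, 0, 0))
  expect_equal(out$S$coords[2, ], c(1, 0, 0))
  expect_equal(out$F, 2)                      # each resultant has norm 1
})

test_that("step commutes with rigid motions", {
  set.seed(8)
  P <- matrix(rnorm(30), 10, 3)
  M <- as.matrix(dist(P)) * exp(rnorm(100, sd = 0.3))
  M <- (M + t(M)) / 2
  D <- dist_mat(M)
  W <- cocc_matrix(build_graph(D))
  out1 <- evrc_step(evrc_structure(P), D, W)$S$coords

  set.seed(77)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  tr <- rnorm(3)
  Pr <- sweep(P %*% Q, 2, tr, `+`)
  out2 <- evrc_step(evrc_structure(Pr), D, W)$S$coords
  expect_equal(out2, sweep(out1 %*% Q, 2, tr, `+`), tolerance = 1e-10)
})

test_that("the run loop is deterministic and honours max_iter", {
  res <- reconstruct_model("spiral", 40)
  res2 <- reconstruct_model("spiral", 40)
  expect_identical(res$fit$trace$F_values, res2$fit$trace$F_values)
  expect_identical(res$fit$S$coords, res2$fit$S$coords)
  expect_equal(length(res$fit$trace$F_values),
               res$fit$trace$iterations_run)
  expect_true(res$fit$trace$converged)
  expect_lt(res$fit$trace$final_dF, 1e-6)

  one <- reconstruct_model("spiral", 40, max_iter = 1)
  expect_equal(one$fit$trace$iterations_run, 1)
  expect_false(one$fit$trace$converged)
})

test_that("one compiled iteration equals the R-level step", {
  res <- reconstruct_model("circle", 30, max_iter = 1)
  D <- res$D; W <- res$W
  init <- init_coords(30, evrc_config(alpha = 1, seed = 1), D)
  stepped <- evrc_step(init, D, W, beta = 0.1)
  expect_equal(res$fit$S$coords, stepped$S$coords, tolerance = 1e-12)
  expect_equal(res$fit$trace$F_values[1], stepped$F, tolerance = 1e-12)
})

test_that("noiseless circle distances reconstruct the circle", {
  res <- reconstruct_model("circle", 100)
  expect_true(res$fit$trace$converged)
  expect_gt(distance_pcc(res$sim$S, res$fit$S), 0.999)
})

test_that("Gaussian smoothing is per-chain and auto is the identity", {
  set.seed(4)
  P <- matrix(rnorm(60), 20, 3)
  S <- evrc_structure(P, chains = rep(c("A", "B"), each = 10))
  expect_identical(smooth_structure(S, "auto")$coords, P)

  # a straight equally-spaced line is invariant away from the ends
  L <- evrc_structure(cbind(1:30, 2 * (1:30), -0.5 * (1:30)))
  sm <- smooth_structure(L, sigma = 2)$coords
  expect_equal(sm[10:21, ], L$coords[10:21, ], tolerance = 1e-9)

  # smoothing chain A is unaffected by arbitrary changes to chain B
  sm1 <- smooth_structure(S, sigma = 1.5)$coords[1:10, ]
  S2 <- S
  S2$coords[11:20, ] <- S2$coords[11:20, ] + 100
  sm2 <- smooth_structure(S2, sigma = 1.5)$coords[1:10, ]
  expect_identical(sm1, sm2)

  expect_error(smooth_structure(S, 0), "positive")
  expect_error(smooth_structure(S, -2), "positive")
})
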