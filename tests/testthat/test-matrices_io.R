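test_that("dense matrix reader parses, validates, and symmetrizes", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("0 2 1", "2 0 4", "1 4 0"), f)
  C <- read_dense_matrix(f, chain_label = "chrX")
  expect_s3_class(C, "ContactMatrix")
  expect_equal(C$n_bins, 3)
  expect_equal(C$F[1, 2], 2)
  expect_equal(C$F[2, 3], 4)
  expect_equal(unique(C$chains), "chrX")

  writeLines(c("0 0", "0 0"), f)
  C0 <- read_dense_matrix(f)
  expect_equal(C0$F[1, 2], 0)

  writeLines(c("0 1 2 3", "1 0 1 2", "2 1 0 1"), f)
  expect_error(read_dense_matrix(f), "square")

  writeLines(c("0 -1", "-1 0"), f)
  expect_error(read_dense_matrix(f), "negative")

  writeLines(c("0 1", "2 0"), f)
  expect_warning(Ca <- read_dense_matrix(f), "symmetriz")
  expect_equal(Ca$F[1, 2], 1.5)
})

test_that("sparse triplet reader sums duplicates and range-checks indices", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("0\t1\t2.0", f)
  C <- read_sparse_triplet(f, n_bins = 3)
  expect_equal(C$F[1, 2], 2)
  expect_equal(C$F[2, 1], 2)
  expect_equal(sum(C$F), 4)

  writeLines(c("0\t1\t1.0", "1\t0\t1.0"), f)
  expect_equal(read_sparse_triplet(f, n_bins = 2)$F[1, 2], 2)

  writeLines("0\t5\t1.0", f)
  expect_error(read_sparse_triplet(f, n_bins = 3), "range")

  writeLines("0\t1\t-1.0", f)
  expect_error(read_sparse_triplet(f, n_bins = 2), "negative")
})

test_that("triplet writer omits zero pairs and round-trips", {
  f <- withr::local_tempfile(fileext = ".tsv")
  F <- matrix(0, 4, 4)
  F[1, 2] <- F[2, 1] <- 2.5
  F[3, 4] <- F[4, 3] <- 0.75
  C <- contact_matrix(F)
  write_sparse_triplet(C, f)
  expect_length(readLines(f), 2)          # only observed pairs listed
  C2 <- read_sparse_triplet(f, n_bins = 4)
  expect_equal(C2$F, C$F)
})

test_that("multi-chromosome assembly places intra and inter blocks", {
  man <- list(chains = data.frame(name = c("c1", "c2"), n_bins = c(2L, 2L)),
              intra = list(c1 = matrix(c(0, 1, 1, 0), 2),
                           c2 = matrix(c(0, 3, 3, 0), 2)),
              inter = list())
  out <- assemble_multichrom(man)
  expect_equal(out$contacts$F,
               rbind(c(0, 1, 0, 0), c(1, 0, 0, 0),
                     c(0, 0, 0, 3), c(0, 0, 3, 0)))

  inter <- matrix(1:6 / 10, 2, 3)
  man <- list(chains = data.frame(name = c("a", "b"), n_bins = c(2L, 3L)),
              intra = list(a = matrix(0, 2, 2), b = matrix(0, 3, 3)),
              inter = list("a|b" = inter))
  out <- assemble_multichrom(man)
  G <- out$contacts$F
  expect_equal(G[1:2, 3:5], inter)
  expect_equal(G, t(G))
  expect_equal(out$contacts$chains, rep(c("a", "b"), c(2, 3)))
  expect_equal(out$index_map$kept$local_bin, c(0L, 1L, 0L, 1L, 2L))

  man$inter <- list("a|b" = t(inter))   # 3 x 2: wrong orientation
  expect_error(assemble_multichrom(man), "expected 2x3")
})

test_that("manifest files round-trip through assembly", {
  dir <- withr::local_tempdir()
  write_dense_matrix(matrix(c(0, 2, 2, 0), 2), file.path(dir, "a.tsv"))
  write_dense_matrix(matrix(c(0, 5, 5, 0), 2), file.path(dir, "b.tsv"))
  write_dense_matrix(matrix(0.5, 2, 2), file.path(dir, "ab.tsv"))
  writeLines(c("# toy genome", "chain a 2 a.tsv", "chain b 2 b.tsv",
               "inter a b ab.tsv"), file.path(dir, "genome.cfg"))
  man <- read_chrom_manifest(file.path(dir, "genome.cfg"))
  expect_equal(man$chains$n_bins, c(2L, 2L))
  G <- assemble_multichrom(man)$contacts$F
  expect_equal(G[1, 2], 2)
  expect_equal(G[3, 4], 5)
  expect_equal(G[1, 3], 0.5)
  expect_equal(G, t(G))
})

test_that("frequency-to-distance conversion follows the power law", {
  C <- contact_matrix(matrix(c(0, 4, 4, 0), 2))
  expect_equal(freq_to_dist(C, alpha = 0.5)$D[1, 2], 0.5)   # 4^(-1/2)
  expect_equal(freq_to_dist(C, alpha = 2)$D[1, 2], 1 / 16)

  C1 <- contact_matrix(matrix(c(0, 1, 1, 0), 2))
  expect_equal(freq_to_dist(C1, alpha = 0.77)$D[1, 2], 1)

  C0 <- contact_matrix(matrix(0, 2, 2))
  expect_identical(freq_to_dist(C0)$D[1, 2], Inf)

  expect_error(freq_to_dist(C, alpha = 0), "positive")
  expect_error(freq_to_dist(C, alpha = -1), "positive")

  # strictly decreasing in F; and D^(-1/alpha) recovers F exactly
  set.seed(42)
  F <- matrix(0, 6, 6)
  F[upper.tri(F)] <- sample(1:100, 15) / 10
  C <- contact_matrix(F + t(F))
  for (alpha in c(0.3, 0.5, 1, 2)) {
    D <- freq_to_dist(C, alpha)$D
    ut <- upper.tri(D)
    ord_F <- order(C$F[ut])
    expect_equal(order(D[ut])[seq_along(ord_F)], rev(ord_F))
    expect_equal(D[ut]^(-1 / alpha), C$F[ut])
  }
})

test_that("isolated bins are dropped and tracked", {
  M <- matrix(Inf, 3, 3)
  M[1, 2] <- M[2, 1] <- 1
  D <- dist_mat(M)
  out <- drop_isolated_bins(D)
  expect_equal(out$D$n_bins, 2)
  expect_equal(out$index_map$dropped$local_bin, 2L)   # 0-based
  expect_equal(nrow(out$index_map$kept), 2)

  Dfull <- dist_mat(matrix(1, 3, 3))
  out2 <- drop_isolated_bins(Dfull)
  expect_equal(out2$D$D, Dfull$D)
  expect_equal(nrow(out2$index_map$dropped), 0)

  expect_error(drop_isolated_bins(dist_mat(matrix(Inf, 3, 3))),
               "isolated")
})

test_that("structure TSV round trip preserves coordinates and drops", {
  f <- withr::local_tempfile(fileext = ".tsv")
  set.seed(3)
  S <- evrc_structure(matrix(rnorm(12), 4, 3),
                      chains = c("A", "A", "B", "B"))
  write_structure(S, f, "tsv")
  S2 <- read_structure(f)
  expect_equal(S2$coords, S$coords, tolerance = 1e-6)
  expect_equal(S2$chains, S$chains)

  # dropped bins come back as NaN rows and are recorded in the map
  S$index_map$dropped <- data.frame(chain = "A", local_bin = 2L)
  write_structure(S, f, "tsv")
  raw <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(raw), 5)
  expect_true(any(is.nan(raw$x)))
  S3 <- read_structure(f)
  expect_equal(nrow(S3$coords), 4)
  expect_equal(S3$index_map$dropped$local_bin, 2L)
})

test_that("PDB output carries one chain ID per chromosome", {
  f <- withr::local_tempfile(fileext = ".pdb")
  S <- evrc_structure(matrix(seq_len(18), 6, 3),
                      chains = rep(c("chr1", "chr2"), each = 3))
  write_structure(S, f, "pdb")
  pdb <- bio3d::read.pdb(f)
  expect_equal(sort(unique(pdb$atom$chain)), c("A", "B"))
  expect_equal(nrow(pdb$atom), 6)
})
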