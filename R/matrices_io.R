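#' Construct a ContactMatrix
#'
#' A `ContactMatrix` holds a symmetric, non-negative matrix of interaction
#' frequencies `F` over `n_bins` genomic bins, plus a chain (chromosome)
#' label per bin.  Diagonal entries are ignored by all downstream
#' computation and stored as 0.
#'
#' @param F numeric matrix of interaction frequencies (symmetrized,
#'   non-negative).
#' @param chains character vector of per-bin chain labels (recycled from a
#'   single label).
#' @return An object of class `ContactMatrix` with fields `F`, `n_bins`,
#'   `chains`.
#' @export
contact_matrix <- function(F, chains = "chr") {
  F <- as.matrix(F)
  if (nrow(F) != ncol(F))
    stop("contact matrix must be square, got ", nrow(F), "x", ncol(F))
  if (any(!is.finite(F)))
    stop("contact matrix contains non-finite entries")
  if (any(F < 0))
    stop("contact matrix contains negative frequencies")
  asym <- max(abs(F - t(F)))
  if (asym > 1e-9) {
    warning("input matrix asymmetric (max |F - t(F)| = ", signif(asym, 3),
            "); symmetrizing by averaging")
  }
  F <- (F + t(F)) / 2
  diag(F) <- 0
  n <- nrow(F)
  chains <- as.character(chains)
  if (length(chains) == 1L) chains <- rep(chains, n)
  if (length(chains) != n)
    stop("chain labels must have length 1 or n_bins")
  structure(list(F = unname(F), n_bins = n, chains = chains),
            class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat("ContactMatrix:", x$n_bins, "bins,",
      length(unique(x$chains)), "chain(s),",
      sum(x$F[upper.tri(x$F)] > 0), "non-zero pairs\n")
  invisible(x)
}

#' Read a dense interaction matrix
#'
#' Reads a plain-text N x N whitespace/tab-separated grid of interaction
#' frequencies.  Asymmetric input (beyond 1e-9) is symmetrized by averaging
#' with a warning; raw Hi-C dumps often carry float asymmetry.
#'
#' @param path file path of the dense matrix.
#' @param chain_label chain (chromosome) label to attach to all bins.
#' @return A [contact_matrix()] object.
#' @export
read_dense_matrix <- function(path, chain_label = "chr") {
  M <- parse_dense_grid(path)
  if (nrow(M) != ncol(M))
    stop("matrix file not square: ", nrow(M), " rows x ", ncol(M), " cols")
  contact_matrix(M, chains = chain_label)
}

# internal: plain numeric grid, no square/symmetry semantics (inter-chain
# blocks are rectangular and must not be symmetrized)
parse_dense_grid <- function(path) {
  rows <- scan(path, what = character(), sep = "\n", quiet = TRUE,
               comment.char = "#")
  fields <- lapply(strsplit(trimws(rows), "[ \t]+"), as.numeric)
  ncols <- unique(lengths(fields))
  if (length(ncols) != 1L)
    stop("ragged matrix file: row lengths ", paste(ncols, collapse = ", "))
  M <- do.call(rbind, fields)
  if (anyNA(M))
    stop("matrix file contains non-numeric entries")
  M
}

#' Read a sparse triplet interaction file
#'
#' Each line holds `i j value` with 0-based bin indices.  Unlisted pairs
#' are 0; duplicate pairs (including the mirrored `j i` entry) are summed;
#' the result is symmetrized.
#'
#' @param path file path of the triplet file.
#' @param n_bins total number of bins of the matrix.
#' @param chain_label chain label to attach to all bins.
#' @return A [contact_matrix()] object.
#' @export
read_sparse_triplet <- function(path, n_bins, chain_label = "chr") {
  df <- utils::read.table(path, header = FALSE, col.names = c("i", "j", "value"),
                          colClasses = c("integer", "integer", "numeric"))
  if (nrow(df) > 0) {
    if (any(df$i < 0 | df$j < 0 | df$i >= n_bins | df$j >= n_bins))
      stop("triplet index out of range for n_bins = ", n_bins)
    if (any(df$value < 0))
      stop("triplet file contains negative frequencies")
  }
  M <- matrix(0, n_bins, n_bins)
  for (k in seq_len(nrow(df))) {
    i <- df$i[k] + 1L; j <- df$j[k] + 1L
    M[i, j] <- M[i, j] + df$value[k]
  }
  M <- M + t(M)          # symmetrize; a pair listed both ways is summed
  diag(M) <- 0
  contact_matrix(M, chains = chain_label)
}

#' Read a multi-chromosome manifest
#'
#' The manifest is a small plain-text key-value file listing chains and the
#' matrix files of their intra- and inter-chain interactions.  Lines
#' (whitespace-separated, `#` comments allowed):
#' \preformatted{
#' chain <name> <n_bins> <intra-matrix-path>
#' inter <name1> <name2> <inter-matrix-path>
#' }
#' Paths are resolved relative to the manifest's directory.  Every chain
#' needs an intra entry; an inter matrix has rows = first chain, columns =
#' second chain.  Missing inter entries default to all-zero blocks (no
#' observed inter-chain contacts).
#'
#' @param path manifest file path.
#' @return A `MultiChromManifest`: list with `chains` (data.frame
#'   `name`, `n_bins`), `intra` (named list of file paths) and `inter`
#'   (named list, names `"A|B"`).
#' @export
read_chrom_manifest <- function(path) {
  dir <- dirname(normalizePath(path))
  rows <- scan(path, what = character(), sep = "\n", quiet = TRUE,
               comment.char = "#")
  rows <- trimws(rows)
  rows <- rows[nzchar(rows)]
  chains <- list(); intra <- list(); inter <- list()
  for (r in rows) {
    f <- strsplit(r, "[ \t]+")[[1]]
    if (f[1] == "chain") {
      if (length(f) != 4) stop("bad manifest line: ", r)
      chains[[f[2]]] <- as.integer(f[3])
      intra[[f[2]]] <- file.path(dir, f[4])
    } else if (f[1] == "inter") {
      if (length(f) != 4) stop("bad manifest line: ", r)
      inter[[paste(f[2], f[3], sep = "|")]] <- file.path(dir, f[4])
    } else stop("unknown manifest keyword: ", f[1])
  }
  if (length(chains) == 0) stop("manifest lists no chains")
  structure(list(
    chains = data.frame(name = names(chains),
                        n_bins = unlist(chains, use.names = FALSE),
                        stringsAsFactors = FALSE),
    intra = intra, inter = inter), class = "MultiChromManifest")
}

#' Assemble a genome-wide matrix from per-chromosome blocks
#'
#' Builds one global symmetric contact matrix with intra-chain matrices on
#' the diagonal blocks and inter-chain matrices off-diagonal (transposed
#' into the lower triangle).  Matrix sources may be file paths (read with
#' [read_dense_matrix()]), plain matrices, or `ContactMatrix` objects.
#'
#' @param manifest a `MultiChromManifest` from [read_chrom_manifest()], or
#'   a list with the same shape whose `intra`/`inter` entries are matrices.
#' @return list with `contacts` (global [contact_matrix()]) and
#'   `index_map` (a [bin_index_map()] with all bins kept).
#' @export
assemble_multichrom <- function(manifest) {
  ch <- manifest$chains
  n_tot <- sum(ch$n_bins)
  offs <- c(0L, cumsum(ch$n_bins))      # 0-based block offsets
  G <- matrix(0, n_tot, n_tot)
  fetch <- function(src) {
    if (is.character(src)) src <- parse_dense_grid(src)
    else if (inherits(src, "ContactMatrix")) src <- src$F
    as.matrix(src)
  }
  for (k in seq_len(nrow(ch))) {
    M <- fetch(manifest$intra[[ch$name[k]]])
    if (nrow(M) != ch$n_bins[k] || ncol(M) != ch$n_bins[k])
      stop("intra matrix for chain '", ch$name[k], "' is ",
           nrow(M), "x", ncol(M), ", expected ", ch$n_bins[k], " bins")
    idx <- (offs[k] + 1L):offs[k + 1L]
    G[idx, idx] <- M
  }
  for (key in names(manifest$inter)) {
    nm <- strsplit(key, "|", fixed = TRUE)[[1]]
    ka <- match(nm[1], ch$name); kb <- match(nm[2], ch$name)
    if (is.na(ka) || is.na(kb))
      stop("inter entry '", key, "' names an unknown chain")
    M <- fetch(manifest$inter[[key]])
    if (nrow(M) != ch$n_bins[ka] || ncol(M) != ch$n_bins[kb])
      stop("inter matrix '", key, "' is ", nrow(M), "x", ncol(M),
           ", expected ", ch$n_bins[ka], "x", ch$n_bins[kb])
    ia <- (offs[ka] + 1L):offs[ka + 1L]
    ib <- (offs[kb] + 1L):offs[kb + 1L]
    G[ia, ib] <- M
    G[ib, ia] <- t(M)
  }
  chains <- rep(ch$name, ch$n_bins)
  cm <- contact_matrix(G, chains = chains)
  local_bin <- unlist(lapply(ch$n_bins, function(n) seq_len(n) - 1L))
  list(contacts = cm,
       index_map = bin_index_map(chains, local_bin))
}

#' Bin index bookkeeping
#'
#' Records, for every input bin, its chain, its 0-based index within the
#' chain, and its 0-based global index in the assembled matrix; bins
#' dropped for having no finite contacts are listed separately so output
#' coordinates can be reported against the original numbering.
#'
#' @param chains character vector of chain labels, one per kept bin.
#' @param local_bin integer vector of 0-based within-chain bin indices.
#' @param dropped data.frame with columns `chain`, `local_bin` (may be
#'   empty).
#' @return object of class `BinIndexMap` with data.frames `kept`
#'   (`chain`, `local_bin`, `global_index`) and `dropped`.
#' @export
bin_index_map <- function(chains, local_bin,
                          dropped = data.frame(chain = character(),
                                               local_bin = integer())) {
  stopifnot(length(chains) == length(local_bin))
  structure(list(
    kept = data.frame(chain = as.character(chains),
                      local_bin = as.integer(local_bin),
                      global_index = seq_along(chains) - 1L,
                      stringsAsFactors = FALSE),
    dropped = dropped), class = "BinIndexMap")
}

#' Convert interaction frequencies to target distances
#'
#' Applies the power law `D_ij = F_ij^(-alpha)` for `F_ij > 0`; pairs with
#' no observed contact (`F_ij = 0`) get `D_ij = Inf` and impose no
#' constraint downstream.  The diagonal is excluded (stored as 0, unused).
#'
#' @param C a [contact_matrix()].
#' @param alpha positive exponent; 0.5 by default, suited to real Hi-C
#'   counts.  Use `alpha = 1` for the simulation test bed, whose
#'   frequencies are exact reciprocal distances.
#' @return object of class `DistanceMatrix`: fields `D` (with `Inf` for
#'   unobserved pairs), `n_bins`, `alpha_used`, `chains`.
#' @export
freq_to_dist <- function(C, alpha = 0.5) {
  stopifnot(inherits(C, "ContactMatrix"))
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("alpha must be a positive number")
  D <- ifelse(C$F > 0, C$F^(-alpha), Inf)
  diag(D) <- 0
  structure(list(D = D, n_bins = C$n_bins, alpha_used = alpha,
                 chains = C$chains), class = "DistanceMatrix")
}

#' @export
print.DistanceMatrix <- function(x, ...) {
  ut <- x$D[upper.tri(x$D)]
  cat("DistanceMatrix:", x$n_bins, "bins, alpha =", x$alpha_used, ",",
      sum(is.finite(ut)), "finite /", length(ut), "pairs\n")
  invisible(x)
}

# internal: build a DistanceMatrix from raw parts
new_distance_matrix <- function(D, alpha_used, chains) {
  diag(D) <- 0
  structure(list(D = unname(D), n_bins = nrow(D), alpha_used = alpha_used,
                 chains = chains), class = "DistanceMatrix")
}

#' Drop bins with no usable distance constraints
#'
#' Removes bins whose entire off-diagonal row is `Inf` (no observed
#' contact with any other bin), recording them in the returned
#' `BinIndexMap` so that output coordinates can be re-aligned to the
#' original bin numbering with dropped bins flagged as `NaN` rows.
#'
#' @param D a `DistanceMatrix`.
#' @return list with `D` (reduced `DistanceMatrix`) and `index_map`
#'   (a [bin_index_map()]).
#' @export
drop_isolated_bins <- function(D) {
  stopifnot(inherits(D, "DistanceMatrix"))
  M <- D$D
  diag(M) <- Inf
  keep <- apply(M, 1L, function(r) any(is.finite(r)))
  if (!any(keep))
    stop("all bins are isolated: no finite distances anywhere in the input")
  chains <- D$chains
  local_bin <- local_bin_indices(chains)
  dropped <- data.frame(chain = chains[!keep],
                        local_bin = local_bin[!keep],
                        stringsAsFactors = FALSE)
  map <- bin_index_map(chains[keep], local_bin[keep], dropped = dropped)
  D2 <- new_distance_matrix(D$D[keep, keep, drop = FALSE],
                            alpha_used = D$alpha_used,
                            chains = chains[keep])
  list(D = D2, index_map = map)
}

# internal: 0-based bin index within each chain, chains assumed contiguous
local_bin_indices <- function(chains) {
  unlist(lapply(rle(chains)$lengths, function(n) seq_len(n) - 1L),
         use.names = FALSE)
}

#' Construct a Structure
#'
#' An ordered set of 3D bin coordinates with a chain label per bin and an
#' optional index map linking rows back to the original input bins.
#'
#' @param coords numeric n x 3 matrix of coordinates.
#' @param chains character vector of per-bin chain labels (recycled).
#' @param index_map optional [bin_index_map()].
#' @return object of class `Structure` with fields `coords`, `chains`,
#'   `index_map`.
#' @export
evrc_structure <- function(coords, chains = "chr", index_map = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix")
  n <- nrow(coords)
  chains <- as.character(chains)
  if (length(chains) == 1L) chains <- rep(chains, n)
  if (length(chains) != n) stop("chain labels must have length 1 or n")
  if (is.null(index_map))
    index_map <- bin_index_map(chains, local_bin_indices(chains))
  structure(list(coords = unname(coords), chains = chains,
                 index_map = index_map), class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat("Structure:", nrow(x$coords), "bins,",
      length(unique(x$chains)), "chain(s)\n")
  invisible(x)
}

#' Write a structure to TSV or PDB
#'
#' TSV output has columns `chain`, `bin`, `x`, `y`, `z` with 0-based
#' within-chain bin indices; bins dropped before reconstruction are
#' re-inserted as rows with `NaN` coordinates so genome coordinates stay
#' aligned.  PDB output writes one pseudo-atom per bin (CA), one chain ID
#' per chromosome, sequential residue numbers, with coordinates uniformly
#' rescaled to fit fixed-width PDB columns.
#'
#' @param S a [evrc_structure()].
#' @param path output file path.
#' @param format `"tsv"` or `"pdb"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(S, path, format = c("tsv", "pdb")) {
  format <- match.arg(format)
  stopifnot(inherits(S, "Structure"))
  if (any(!is.finite(S$coords)))
    stop("structure has non-finite coordinates")
  if (format == "tsv") {
    df <- data.frame(chain = S$chains,
                     bin = S$index_map$kept$local_bin,
                     x = S$coords[, 1], y = S$coords[, 2], z = S$coords[, 3],
                     stringsAsFactors = FALSE)
    dr <- S$index_map$dropped
    if (nrow(dr) > 0) {
      df <- rbind(df, data.frame(chain = dr$chain, bin = dr$local_bin,
                                 x = NaN, y = NaN, z = NaN))
      df <- df[order(df$chain, df$bin), ]
    }
    # format explicitly so dropped bins serialize as NaN, not NA
    for (a in c("x", "y", "z")) df[[a]] <- sprintf("%.12g", df[[a]])
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    xyz <- S$coords
    # rescale into comfortable PDB numeric range (fixed 8.3 columns)
    span <- max(apply(xyz, 2, function(v) diff(range(v))), 1e-12)
    xyz <- (xyz - matrix(colMeans(xyz), nrow(xyz), 3, byrow = TRUE)) *
      (100 / span)
    ids <- LETTERS[match(S$chains, unique(S$chains))]
    n <- nrow(xyz)
    bio3d::write.pdb(file = path, xyz = as.vector(t(xyz)),
                     resno = seq_len(n), chain = ids,
                     resid = rep("BIN", n), elety = rep("CA", n))
  }
  invisible(path)
}

#' Read a structure written in TSV format
#'
#' Inverse of [write_structure()] (`format = "tsv"`); rows with `NaN`
#' coordinates (dropped bins) are recorded in the index map and excluded
#' from `coords`.
#'
#' @param path TSV file path.
#' @return a [evrc_structure()].
#' @export
read_structure <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  ok <- is.finite(df$x) & is.finite(df$y) & is.finite(df$z)
  dropped <- data.frame(chain = df$chain[!ok], local_bin = df$bin[!ok],
                        stringsAsFactors = FALSE)
  evrc_structure(cbind(df$x[ok], df$y[ok], df$z[ok]),
                 chains = df$chain[ok],
                 index_map = bin_index_map(df$chain[ok], df$bin[ok],
                                           dropped = dropped))
}

#' Write a contact matrix as sparse triplets
#'
#' Emits one `i<TAB>j<TAB>value` line per non-zero upper-triangle pair,
#' 0-based; pairs with no observed contact are simply omitted (the
#' reader restores them as 0).
#'
#' @param C a [contact_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sparse_triplet <- function(C, path) {
  stopifnot(inherits(C, "ContactMatrix"))
  idx <- which(upper.tri(C$F) & C$F > 0, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                   value = C$F[idx])
  df <- df[order(df$i, df$j), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a dense matrix as TSV
#'
#' Companion writer for contact, distance, or co-clustering matrices in
#' the same plain-text dialect the readers accept.
#'
#' @param M numeric matrix, or a `ContactMatrix` / `CoCCMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dense_matrix <- function(M, path) {
  if (inherits(M, "ContactMatrix")) M <- M$F
  if (inherits(M, "CoCCMatrix")) M <- M$values
  utils::write.table(as.matrix(M), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
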