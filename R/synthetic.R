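# Seeded generators of test populations with known structure. Each generator
# derives its own RNG stream from the user seed plus a fixed per-generator
# offset (documented in the vignette), so adding a generator call elsewhere
# never perturbs existing fixtures.

.stream_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 16L + offset) %% .Machine$integer.max)
}

#' Random Euclidean point-cloud dissimilarity matrix
#'
#' `N` points uniform in the unit hypercube of dimension `dim`; the matrix of
#' pairwise Euclidean distances. The default synthetic population: a genuine
#' metric, like conformer RMSD.
#'
#' @param N population size (>= 2).
#' @param dim Euclidean dimension (>= 1, default 3).
#' @param seed integer seed; the same seed reproduces the matrix bit-exactly.
#' @return a `dissim_matrix` with generator parameters in its metadata.
#' @export
random_point_population <- function(N, dim = 3, seed) {
  N <- as.integer(N); dim <- as.integer(dim)
  if (N < 2) stop("N must be >= 2")
  if (dim < 1) stop("dim must be >= 1")
  pts <- with_seed(.stream_seed(seed, 1L),
                   matrix(runif(N * dim), nrow = N, ncol = dim))
  validate_matrix(as.matrix(dist(pts)),
                  metadata = list(generator = "points", N = N, dim = dim,
                                  seed = seed))
}

#' Random symmetric dissimilarity matrix
#'
#' I.i.d. draws for the strict upper triangle, mirrored, zero diagonal. Not a
#' metric in general -- a stress test for the selectors, which never assume
#' the triangle inequality. The default distribution is uniform on
#' (0.1, 1]; supply `rdist` to change it. Distributions that can produce
#' zeros (duplicates) require `allow_zeros = TRUE`.
#'
#' @param N population size (>= 2).
#' @param seed integer seed.
#' @param rdist function of one argument `m` returning `m` draws
#'   (default `function(m) runif(m, 0.1, 1)`).
#' @param allow_zeros permit zero distances (exact duplicates)?
#' @return a `dissim_matrix`.
#' @export
random_matrix <- function(N, seed, rdist = NULL, allow_zeros = FALSE) {
  N <- as.integer(N)
  if (N < 2) stop("N must be >= 2")
  if (is.null(rdist)) rdist <- function(m) runif(m, 0.1, 1)
  m <- N * (N - 1) / 2
  draws <- with_seed(.stream_seed(seed, 2L), rdist(m))
  if (length(draws) != m || any(!is.finite(draws)))
    stop("rdist must return m finite draws")
  if (any(draws < 0) || (!allow_zeros && any(draws == 0)))
    stop("rdist produced non-positive draws; use allow_zeros for zero distances")
  v <- matrix(0, N, N)
  v[lower.tri(v)] <- draws
  v <- v + t(v)
  validate_matrix(v, metadata = list(generator = "matrix", N = N, seed = seed,
                                     allow_zeros = allow_zeros))
}

#' Gaussian-perturbed synthetic conformer ensemble
#'
#' One random base structure (atoms uniform in a 10 Angstrom box, elements
#' drawn from C/N/O/H), then `K` conformers each displacing every coordinate
#' by i.i.d. Gaussian noise with standard deviation `sigma`. Emulates a
#' conformer population for pipeline tests: for two independently perturbed
#' copies the expected squared unsuperposed RMSD is `6 * sigma^2` (difference
#' variance `2 sigma^2` per coordinate, 3 coordinates per atom).
#'
#' @param atom_count atoms per conformer (>= 1).
#' @param K number of conformers (>= 2).
#' @param sigma displacement standard deviation in Angstrom (> 0).
#' @param seed integer seed.
#' @return a `conformer_ensemble` (writable with [write_xyz()]).
#' @export
perturbed_ensemble <- function(atom_count, K, sigma, seed) {
  atom_count <- as.integer(atom_count); K <- as.integer(K)
  if (atom_count < 1) stop("atom_count must be >= 1")
  if (K < 2) stop("K must be >= 2")
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  with_seed(.stream_seed(seed, 3L), {
    elements <- sample(c("C", "N", "O", "H"), atom_count, replace = TRUE)
    base <- matrix(runif(atom_count * 3, 0, 10), ncol = 3)
    confs <- lapply(seq_len(K), function(k)
      new_conformer(sprintf("conf_%d", k), elements,
                    base + matrix(rnorm(atom_count * 3, sd = sigma), ncol = 3)))
    new_ensemble(confs, source = "synthetic")
  })
}
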