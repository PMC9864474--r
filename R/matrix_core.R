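#' Validate and construct a pairwise dissimilarity matrix
#'
#' Checks a raw square matrix of pairwise dissimilarities (e.g. conformer
#' RMSDs in Angstrom) and returns a validated `dissim_matrix`: symmetric,
#' nonnegative, finite, with an exactly zero diagonal. Asymmetries within
#' `symmetry_tol` (relative to `max(1, |value|)`) are averaged away --
#' floating-point RMSD can differ in the last bits depending on argument
#' order; larger asymmetries are errors.
#'
#' @param raw square numeric matrix, `N >= 2`.
#' @param symmetry_tol relative symmetry tolerance (default `1e-8`).
#' @param labels optional character vector of N item labels; defaults to
#'   existing rownames or `item_1 ... item_N`.
#' @param metadata optional named list recorded with the matrix (provenance:
#'   source file, metric, flags).
#' @return A `dissim_matrix`: list with `values` (N x N numeric matrix),
#'   `labels`, `metadata`.
#' @examples
#' validate_matrix(matrix(c(0, 1, 1, 0), 2))
#' @export
validate_matrix <- function(raw, symmetry_tol = 1e-8, labels = NULL,
                            metadata = list()) {
  if (inherits(raw, "dissim_matrix")) return(raw)
  raw <- as.matrix(raw)
  if (!is.numeric(raw)) stop("matrix values must be numeric")
  if (nrow(raw) != ncol(raw)) stop("dissimilarity matrix must be square")
  N <- nrow(raw)
  if (N < 2) stop("need at least 2 items (N >= 2)")
  if (any(!is.finite(raw))) stop("all entries must be finite")
  if (any(raw < 0)) stop("dissimilarities must be nonnegative")
  asym <- abs(raw - t(raw))
  tol_ij <- symmetry_tol * pmax(1, abs(raw))
  if (any(asym > tol_ij)) {
    bad <- which(asym > tol_ij, arr.ind = TRUE)[1, ]
    stop(sprintf("matrix is asymmetric beyond tolerance at (%d, %d): %g vs %g",
                 bad[1], bad[2], raw[bad[1], bad[2]], raw[bad[2], bad[1]]))
  }
  if (any(abs(diag(raw)) > symmetry_tol))
    stop("diagonal entries must be zero (self-dissimilarity)")
  values <- (raw + t(raw)) / 2
  diag(values) <- 0
  if (is.null(labels)) {
    labels <- rownames(raw)
    if (is.null(labels)) labels <- paste0("item_", seq_len(N))
  }
  if (length(labels) != N) stop("labels must have length N")
  dimnames(values) <- NULL
  structure(list(values = values, labels = as.character(labels),
                 metadata = metadata),
            class = "dissim_matrix")
}

#' @export
print.dissim_matrix <- function(x, ...) {
  cat(sprintf("dissim_matrix: %d items\n", nrow(x$values)))
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("  off-diagonal range: [%g, %g]; zero pairs: %d\n",
              min(off), max(off), sum(off == 0)))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), unlist(lapply(x$metadata, format)),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.matrix.dissim_matrix <- function(x, ...) {
  v <- x$values
  dimnames(v) <- list(x$labels, x$labels)
  v
}

#' Number of items in a dissimilarity matrix
#' @param m a `dissim_matrix`.
#' @return integer N.
#' @export
n_items <- function(m) nrow(m$values)

#' Element-wise natural log of a dissimilarity matrix
#'
#' The working representation of the greedy selector: off-diagonal entry
#' (i, j) is `ln(d_ij)`, a zero distance (exact duplicates) becomes `-Inf`,
#' and the diagonal carries the masked sentinel `NA` so a selected item can
#' never score. Exponentiating any finite off-diagonal entry recovers the
#' source distance to within 1e-12 relative.
#'
#' @param m a `dissim_matrix` (or raw matrix, validated first).
#' @return A `log_dissim_matrix`: list with `values` (N x N, `NA` diagonal),
#'   `labels`.
#' @export
log_transform <- function(m) {
  m <- validate_matrix(m)
  L <- log(m$values) # log(0) == -Inf, the duplicate sentinel
  diag(L) <- NA_real_
  structure(list(values = L, labels = m$labels), class = "log_dissim_matrix")
}

#' @export
print.log_dissim_matrix <- function(x, ...) {
  cat(sprintf("log_dissim_matrix: %d items (diagonal masked)\n",
              nrow(x$values)))
  invisible(x)
}

#' Log-sum objective of a subset
#'
#' The total pairwise dissimilarity of a subset on the log scale:
#' \eqn{\sum_{\{i,j\} \subset S, i<j} \ln d_{ij}}, every unordered pair counted
#' exactly once, equal to the log of the product of pairwise distances
#' whenever that product is representable. If the subset contains a duplicate
#' pair (`d_ij = 0`) the objective is `-Inf` -- the log-sum punishes a single
#' very small pairwise relation, which is the point of the scoring.
#'
#' @param m a `dissim_matrix`.
#' @param subset integer vector of at least 2 distinct 1-based item indices;
#'   order is irrelevant.
#' @return scalar objective value (possibly `-Inf`).
#' @examples
#' m <- random_point_population(8, dim = 2, seed = 1)
#' set_objective(m, c(1, 4, 6))
#' @export
set_objective <- function(m, subset) {
  m <- validate_matrix(m)
  subset <- as.integer(subset)
  N <- n_items(m)
  if (length(subset) < 2) stop("subset must contain at least 2 indices")
  if (anyDuplicated(subset)) stop("subset contains duplicate indices")
  if (any(subset < 1L | subset > N)) stop("subset index out of range [1, N]")
  sub <- m$values[subset, subset, drop = FALSE]
  sum(log(sub[upper.tri(sub)]))
}

#' Expected objective of a uniformly random subset
#'
#' Closed-form expectation of [set_objective()] over uniformly random size-`n`
#' subsets: by linearity of expectation every unordered pair is included with
#' the same probability, so the expectation is `choose(n, 2)` times the mean
#' of `ln d_ij` over all `N(N-1)/2` off-diagonal pairs. This is the "mean"
#' reference curve of the exact-search benchmark, computed exactly rather
#' than by sampling.
#'
#' @param m a `dissim_matrix` with strictly positive off-diagonal distances.
#' @param n subset size, `2 <= n <= N`.
#' @return scalar expected objective.
#' @export
mean_random_objective <- function(m, n) {
  m <- validate_matrix(m)
  N <- n_items(m)
  n <- as.integer(n)
  if (n < 2 || n > N) stop("n must satisfy 2 <= n <= N")
  off <- m$values[upper.tri(m$values)]
  if (any(off == 0))
    stop("matrix has a zero off-diagonal distance: the expectation is -Inf")
  choose(n, 2) * mean(log(off))
}
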