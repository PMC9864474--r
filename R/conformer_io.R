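new_conformer <- function(id, elements, coords) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (length(elements) < 1 || nrow(coords) != length(elements))
    stop("conformer needs one (x, y, z) row per element")
  if (any(!is.finite(coords))) stop("non-finite coordinate in conformer")
  structure(list(id = as.character(id), elements = as.character(elements),
                 coords = coords),
            class = "conformer")
}

new_ensemble <- function(conformers, source = "synthetic") {
  if (length(conformers) < 2) stop("ensemble needs at least 2 conformers")
  ref <- conformers[[1]]$elements
  for (k in seq_along(conformers)) {
    if (!identical(conformers[[k]]$elements, ref))
      stop(sprintf(
        "conformer %d has a different element sequence than conformer 1", k))
  }
  structure(list(conformers = conformers, source = source),
            class = "conformer_ensemble")
}

#' @export
length.conformer_ensemble <- function(x) length(x$conformers)

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("conformer_ensemble: %d conformers x %d atoms (source: %s)\n",
              length(x), length(x$conformers[[1]]$elements), x$source))
  invisible(x)
}

#' Read a multi-record XYZ file as a conformer ensemble
#'
#' Each record is an atom-count line, a comment line (used as the conformer
#' id when non-empty), and that many `element x y z` lines. Every record must
#' have the same elements in the same order -- RMSD between corresponding
#' atoms is only defined for conformers of one molecule.
#'
#' @param path path to an XYZ file with at least 2 records.
#' @return a `conformer_ensemble`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  confs <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    natoms <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(natoms) || natoms < 1)
      stop(sprintf("malformed XYZ record at line %d: bad atom count", i))
    if (i + 1L + natoms > length(lines))
      stop("truncated XYZ record at end of file")
    comment <- trimws(lines[i + 1L])
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + natoms)]), "\\s+")
    if (any(lengths(rows) < 4))
      stop(sprintf("malformed XYZ atom line in record starting at line %d", i))
    elements <- vapply(rows, `[[`, character(1), 1)
    coords <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    if (any(!is.finite(coords)))
      stop(sprintf("non-numeric coordinate in record starting at line %d", i))
    id <- if (nzchar(comment)) comment else paste0("conf_", length(confs) + 1L)
    confs[[length(confs) + 1L]] <- new_conformer(id, elements, coords)
    i <- i + 2L + natoms
  }
  new_ensemble(confs, source = path)
}

#' Write a conformer ensemble as a multi-record XYZ file
#'
#' @param e a `conformer_ensemble`.
#' @param path output path.
#' @param digits significant digits per coordinate (default 12; round-trips
#'   well below 1e-6 Angstrom).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(e, path, digits = 12) {
  stopifnot(inherits(e, "conformer_ensemble"))
  out <- character(0)
  for (cf in e$conformers) {
    out <- c(out, as.character(length(cf$elements)), cf$id,
             sprintf(paste0("%s %.", digits, "g %.", digits, "g %.", digits, "g"),
                     cf$elements, cf$coords[, 1], cf$coords[, 2], cf$coords[, 3]))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a multi-record SDF/MOL V2000 file as a conformer ensemble
#'
#' Records are separated by `$$$$`; atoms come from each record's atom block.
#' Properties, bonds and charges are ignored -- only elements and Cartesian
#' coordinates matter for RMSD.
#'
#' @param path path to an SDF file with at least 2 records.
#' @return a `conformer_ensemble`.
#' @export
read_sdf <- function(path) {
  lines <- readLines(path)
  recs <- split(lines, cumsum(c(0, head(lines, -1) == "$$$$")))
  confs <- list()
  for (rec in recs) {
    rec <- rec[rec != "$$$$"]
    if (!any(nzchar(trimws(rec)))) next
    if (length(rec) < 5) stop("malformed SDF record: too short")
    counts <- rec[4]
    natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
    if (is.na(natoms) || natoms < 1)
      stop("malformed SDF record: bad or missing counts line")
    if (length(rec) < 4 + natoms) stop("malformed SDF record: truncated atom block")
    rows <- strsplit(trimws(rec[5:(4 + natoms)]), "\\s+")
    if (any(lengths(rows) < 4)) stop("malformed SDF atom line")
    coords <- t(vapply(rows, function(r) as.numeric(r[1:3]), numeric(3)))
    if (any(!is.finite(coords))) stop("non-numeric coordinate in SDF atom block")
    elements <- vapply(rows, `[[`, character(1), 4)
    id <- if (nzchar(trimws(rec[1]))) trimws(rec[1])
          else paste0("conf_", length(confs) + 1L)
    confs[[length(confs) + 1L]] <- new_conformer(id, elements, coords)
  }
  new_ensemble(confs, source = path)
}

#' RMSD between corresponding atoms of two conformers
#'
#' `sqrt(mean(|a_k - b_k|^2))` over the corresponding atom pairs, in the
#' coordinate units of the input (Angstrom). With `superpose = TRUE`, `b` is
#' first rigidly superposed onto `a` by least squares (Kabsch), so the result
#' is invariant under rigid motions of either conformer and never larger than
#' the unsuperposed value.
#'
#' @param a,b `conformer` objects with identical element sequences.
#' @param superpose align `b` onto `a` first? Default `FALSE`: coordinates
#'   are compared as given.
#' @return scalar RMSD (Angstrom).
#' @export
pairwise_rmsd <- function(a, b, superpose = FALSE) {
  stopifnot(inherits(a, "conformer"), inherits(b, "conformer"))
  if (!identical(a$elements, b$elements))
    stop("conformers have different element sequences")
  A <- a$coords
  B <- b$coords
  if (superpose) {
    Ac <- sweep(A, 2, colMeans(A))
    Bc <- sweep(B, 2, colMeans(B))
    s <- svd(crossprod(Bc, Ac))
    d <- sign(det(s$v %*% t(s$u)))
    R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    A <- Ac
    B <- Bc %*% t(R)
  }
  sqrt(mean(rowSums((A - B)^2)))
}

#' Build a pairwise-RMSD dissimilarity matrix from a conformer ensemble
#'
#' Entry (i, j) is [pairwise_rmsd()] between conformers i and j; each
#' unordered pair is computed exactly once. Without superposition this is
#' vectorized as Euclidean distance between flattened coordinate vectors
#' divided by `sqrt(atom count)`.
#'
#' @param e a `conformer_ensemble`.
#' @param superpose apply Kabsch superposition per pair? Recorded in the
#'   matrix metadata.
#' @return a validated `dissim_matrix` with conformer ids as labels.
#' @export
build_matrix <- function(e, superpose = FALSE) {
  stopifnot(inherits(e, "conformer_ensemble"))
  K <- length(e)
  A <- length(e$conformers[[1]]$elements)
  if (superpose) {
    v <- matrix(0, K, K)
    for (i in seq_len(K - 1)) {
      for (j in (i + 1):K) {
        v[i, j] <- v[j, i] <- pairwise_rmsd(e$conformers[[i]], e$conformers[[j]],
                                            superpose = TRUE)
      }
    }
  } else {
    flat <- t(vapply(e$conformers, function(cf) as.numeric(cf$coords),
                     numeric(3 * A)))
    v <- as.matrix(dist(flat)) / sqrt(A)
  }
  validate_matrix(v,
                  labels = vapply(e$conformers, `[[`, character(1), "id"),
                  metadata = list(metric = "rmsd", superpose = superpose,
                                  source = e$source, atoms = A))
}

#' Drop hydrogen atoms from every conformer of an ensemble
#'
#' Conformer pipelines often compare heavy atoms only; this removes all `H`
#' entries (same positions in every conformer by the shared-elements
#' invariant).
#'
#' @param e a `conformer_ensemble` with at least one non-hydrogen atom.
#' @return a `conformer_ensemble`.
#' @export
strip_hydrogens <- function(e) {
  stopifnot(inherits(e, "conformer_ensemble"))
  keep <- e$conformers[[1]]$elements != "H"
  if (!any(keep)) stop("ensemble has no non-hydrogen atoms")
  new_ensemble(lapply(e$conformers, function(cf)
    new_conformer(cf$id, cf$elements[keep], cf$coords[keep, , drop = FALSE])),
    source = e$source)
}
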