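# Matrix persistence. Text: delimited with labels in the first row and
# column, %.17g cells (round-trips to equal doubles). Binary: magic "SDSM",
# one version byte, N as unsigned 64-bit little-endian, then the strict upper
# triangle row-major as little-endian IEEE doubles (bit-exact round trip; no
# labels).

.SDSM_MAGIC <- charToRaw("SDSM")
.SDSM_VERSION <- as.raw(1L)

#' Write a dissimilarity matrix to disk
#'
#' @param m a `dissim_matrix`.
#' @param path output path.
#' @param format `"text"` (tab-separated, labelled, full precision) or
#'   `"binary"` (compact upper-triangle format; labels are not stored).
#' @return `path`, invisibly.
#' @seealso [read_matrix()]
#' @export
write_matrix <- function(m, path, format = c("text", "binary")) {
  format <- match.arg(format)
  m <- validate_matrix(m)
  N <- n_items(m)
  if (format == "text") {
    cells <- matrix(sprintf("%.17g", m$values), N, N)
    lines <- c(paste(c("", m$labels), collapse = "\t"),
               vapply(seq_len(N), function(i)
                 paste(c(m$labels[i], cells[i, ]), collapse = "\t"),
                 character(1)))
    writeLines(lines, path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(.SDSM_MAGIC, con)
    writeBin(.SDSM_VERSION, con)
    writeBin(.uint64_le(N), con)
    ut <- m$values[lower.tri(m$values)] # symmetric: == upper triangle row-major
    writeBin(ut, con, size = 8, endian = "little")
  }
  invisible(path)
}

.uint64_le <- function(n) {
  stopifnot(n >= 0, n < 2^31)
  as.raw(c(n %% 256, (n %/% 256) %% 256, (n %/% 65536) %% 256,
           (n %/% 16777216) %% 256, 0, 0, 0, 0))
}

#' Read a dissimilarity matrix from disk
#'
#' Auto-detects the binary format by its magic bytes; otherwise parses
#' delimited text (tab or comma separated, first row and column are labels).
#' The result is re-validated on read.
#'
#' @param path path written by [write_matrix()] (or compatible).
#' @param symmetry_tol passed to [validate_matrix()].
#' @return a `dissim_matrix`.
#' @export
read_matrix <- function(path, symmetry_tol = 1e-8) {
  con <- file(path, "rb")
  magic <- readBin(con, "raw", 4)
  close(con)
  if (length(magic) == 4 && identical(magic, .SDSM_MAGIC)) {
    .read_matrix_binary(path, symmetry_tol)
  } else {
    .read_matrix_text(path, symmetry_tol)
  }
}

.read_matrix_binary <- function(path, symmetry_tol) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 4)
  version <- readBin(con, "raw", 1)
  if (length(version) != 1 || version != .SDSM_VERSION)
    stop("unsupported or missing binary matrix format version")
  nb <- readBin(con, "raw", 8)
  if (length(nb) != 8) stop("truncated binary matrix file (header)")
  if (any(nb[5:8] != as.raw(0))) stop("matrix dimension exceeds supported range")
  N <- sum(as.integer(nb[1:4]) * 256^(0:3))
  want <- N * (N - 1) / 2
  ut <- readBin(con, "double", want, size = 8, endian = "little")
  if (length(ut) != want) stop("truncated binary matrix file (payload)")
  if (length(readBin(con, "raw", 1)) != 0)
    stop("trailing bytes after binary matrix payload")
  v <- matrix(0, N, N)
  v[lower.tri(v)] <- ut
  v <- v + t(v)
  validate_matrix(v, symmetry_tol = symmetry_tol,
                  metadata = list(source = path, format = "binary"))
}

.read_matrix_text <- function(path, symmetry_tol) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("matrix text file too short")
  sep <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  header <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  labels <- header[-1]
  N <- length(labels)
  if (length(lines) != N + 1) stop("matrix text file: row count does not match header")
  v <- matrix(NA_real_, N, N)
  for (i in seq_len(N)) {
    f <- strsplit(lines[i + 1], sep, fixed = TRUE)[[1]]
    if (length(f) != N + 1) stop(sprintf("matrix text file: bad field count on row %d", i))
    v[i, ] <- as.numeric(f[-1])
  }
  validate_matrix(v, symmetry_tol = symmetry_tol, labels = labels,
                  metadata = list(source = path, format = "text"))
}
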