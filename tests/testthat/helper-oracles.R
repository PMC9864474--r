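# Independent oracles and tiny fixture builders. Everything here is kept
# deliberately naive (double loops, full enumeration, Pascal's triangle) so
# it cannot share a defect with the implementation paths it checks.

# Seed-scoped RNG for test determinism (restores the ambient RNG state).
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# 1-D points at 0, 1, 10, 11: the hand-traceable greedy instance.
# d01 = 1, d02 = 10, d03 = 11, d12 = 9, d13 = 10, d23 = 1.
line_points_matrix <- function() {
  x <- c(0, 1, 10, 11)
  validate_matrix(abs(outer(x, x, "-")))
}

# Brute-force log-sum over all unordered pairs, explicit double loop.
brute_objective <- function(m, subset) {
  v <- if (inherits(m, "dissim_matrix")) m$values else m
  tot <- 0
  for (a in seq_along(subset)) {
    for (b in seq_along(subset)) {
      if (a < b) tot <- tot + log(v[subset[a], subset[b]])
    }
  }
  tot
}

# Full enumeration in plain R via utils::combn; returns the lexicographically
# first optimal subset and its objective.
brute_best_subset <- function(m, n, maximize = TRUE) {
  v <- if (inherits(m, "dissim_matrix")) m$values else m
  combs <- utils::combn(nrow(v), n)
  objs <- apply(combs, 2, function(s) brute_objective(v, s))
  best <- if (maximize) max(objs) else min(objs)
  list(indices = combs[, which(objs == best)[1]], objective = best,
       all_objectives = objs)
}

# Exact binomial coefficients by Pascal's recurrence in doubles; exact for
# every value below 2^53 (all uses here are far below).
pascal_choose <- function(N, n) {
  row <- 1
  for (k in seq_len(N)) row <- c(1, row[-length(row)] + row[-1], 1)
  stopifnot(max(row) < 2^53)
  row[n + 1]
}

# Random validated matrix with off-diagonal entries in a given range.
rand_matrix <- function(N, seed, lo = 0.1, hi = 10) {
  random_matrix(N, seed = seed, rdist = function(m) runif(m, lo, hi))
}

# Minimal V2000 SDF writer for fixtures (atoms only, no bonds).
write_sdf_fixture <- function(confs, path) {
  lines <- character(0)
  for (cf in confs) {
    lines <- c(lines,
               cf$id, "  synthetic", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       length(cf$elements), 0L),
               sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       cf$coords[, 1], cf$coords[, 2], cf$coords[, 3], cf$elements),
               "M  END", "$$$$")
  }
  writeLines(lines, path)
  invisible(path)
}
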