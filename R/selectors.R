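.check_mode <- function(mode) match.arg(mode, c("dissimilar", "similar"))

new_selection <- function(method, mode, order, objective, N, labels,
                          step_scores = NULL, objective_trace = NULL,
                          iterations = NA_integer_, seed = NA_integer_) {
  structure(list(method = method, mode = mode,
                 order = as.integer(order), n = length(order), N = N,
                 labels = labels,
                 step_scores = step_scores, objective_trace = objective_trace,
                 objective = objective,
                 iterations = iterations, seed = seed),
            class = "sds_selection")
}

#' @export
print.sds_selection <- function(x, ...) {
  cat(sprintf("%s selection (%s mode): n = %d of N = %d\n",
              x$method, x$mode, x$n, x$N))
  cat("  indices (1-based):", paste(x$order, collapse = ", "), "\n")
  cat(sprintf("  log-sum objective: %.6g\n", x$objective))
  if (!is.na(x$iterations))
    cat(sprintf("  iterations: %d, seed: %d\n", x$iterations, x$seed))
  invisible(x)
}

#' Structured text report of a selection
#'
#' One record per selected item: rank, 1-based index, label, step score (the
#' summation-array value at which the item was chosen; greedy selections
#' only), and prefix objective.
#'
#' @param x an `sds_selection`.
#' @return a data.frame (invisibly writable with [utils::write.table()]).
#' @export
selection_report <- function(x) {
  stopifnot(inherits(x, "sds_selection"))
  data.frame(
    rank = seq_len(x$n),
    index = x$order,
    label = x$labels[x$order],
    step_score = if (is.null(x$step_scores)) rep(NA_real_, x$n)
                 else c(NA, NA, x$step_scores),
    prefix_objective = if (is.null(x$objective_trace)) rep(NA_real_, x$n)
                       else c(NA, x$objective_trace),
    stringsAsFactors = FALSE)
}

#' Machine-readable key-value summary of a selection
#'
#' @param x an `sds_selection`.
#' @return named character vector (`method`, `mode`, `n`, `N`, `seed`,
#'   `iterations`, `objective`, `index_base`, `indices`).
#' @export
selection_summary <- function(x) {
  stopifnot(inherits(x, "sds_selection"))
  c(method = x$method, mode = x$mode, n = as.character(x$n),
    N = as.character(x$N),
    seed = as.character(x$seed), iterations = as.character(x$iterations),
    objective = sprintf("%.17g", x$objective),
    index_base = "1",
    indices = paste(x$order, collapse = ","))
}

#' Exact most (or least) dissimilar pair
#'
#' The pair of items with the largest (dissimilar mode) or smallest (similar
#' mode) pairwise distance -- the provably exact n = 2 solution that seeds the
#' greedy selector. Ties are broken by the lexicographically smallest (i, j).
#'
#' @param L a `log_dissim_matrix` (or a `dissim_matrix`/raw matrix, which is
#'   log-transformed first).
#' @param mode `"dissimilar"` (maximize) or `"similar"` (minimize).
#' @return integer vector `c(i, j)` with `i < j` (1-based).
#' @export
select_initial_pair <- function(L, mode = c("dissimilar", "similar")) {
  mode <- .check_mode(mode)
  if (!inherits(L, "log_dissim_matrix")) L <- log_transform(L)
  v <- L$values
  N <- nrow(v)
  ut <- upper.tri(v)
  vals <- v[ut]
  target <- if (mode == "dissimilar") max(vals) else min(vals)
  hits <- which(ut & v == target, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  as.integer(unname(c(hits[1, 1], hits[1, 2])))
}

# Shared greedy engine. Maintains the running summation array of log
# distances to everything selected so far; selected indices carry the NA
# mask, exact duplicates of a selected item carry -Inf and are only ever
# chosen (in dissimilar mode) when no finite-scored candidate remains.
sds_engine <- function(L, n, mode) {
  v <- L$values
  N <- nrow(v)
  pick_fun <- if (mode == "dissimilar") which.max else which.min
  pair <- select_initial_pair(L, mode)
  order_out <- integer(n)
  order_out[1:2] <- pair
  step_scores <- numeric(max(0L, n - 2L))
  trace <- numeric(n - 1L)
  trace[1] <- v[pair[1], pair[2]]
  ssum <- v[pair[1], ] + v[pair[2], ]
  ssum[pair] <- NA_real_
  k <- 2L
  while (k < n) {
    pick <- pick_fun(ssum) # ignores NA; first hit = smallest-index tie-break
    s <- ssum[pick]
    k <- k + 1L
    order_out[k] <- pick
    step_scores[k - 2L] <- s
    trace[k - 1L] <- trace[k - 2L] + s
    ssum <- ssum + v[pick, ]
    ssum[pick] <- NA_real_
  }
  list(order = order_out, step_scores = step_scores, trace = trace)
}

#' Greedy similarity downselection
#'
#' The greedy heuristic for the most-dissimilar-set problem. Starting from
#' the exact most-dissimilar pair, each iteration adds the item with the
#' largest running log-sum of distances to everything already selected
#' (smallest, in similar mode): the natural logs of the selected items' rows
#' are summed element-wise into a summation array, already-selected indices
#' are masked, and the argmax (argmin) of the array is the next item. The
#' size-n solution is therefore nested inside the size-(n+1) solution by
#' construction. Ties break to the smallest index, so results are fully
#' deterministic.
#'
#' @param m a `dissim_matrix` (or raw matrix).
#' @param n target subset size, `2 <= n <= N`.
#' @param mode `"dissimilar"` (default) or `"similar"`.
#' @return An `sds_selection` with `order` (selection order), `step_scores`
#'   (summation-array value at which each item after the second was chosen),
#'   `objective_trace` (objective of each prefix of length 2..n) and
#'   `objective`.
#' @examples
#' m <- random_point_population(50, dim = 3, seed = 7)
#' sds_select(m, 5)
#' @export
sds_select <- function(m, n, mode = c("dissimilar", "similar")) {
  mode <- .check_mode(mode)
  m <- validate_matrix(m)
  N <- n_items(m)
  n <- as.integer(n)
  if (n < 2 || n > N) stop("n must satisfy 2 <= n <= N")
  eng <- sds_engine(log_transform(m), n, mode)
  new_selection("sds", mode, eng$order,
                objective = eng$trace[n - 1L], N = N, labels = m$labels,
                step_scores = eng$step_scores, objective_trace = eng$trace)
}

#' Full greedy selection order of all N items
#'
#' A single O(N^2)-time, O(N)-extra-space pass whose length-k prefix is the
#' greedy solution for every set size k: one run answers all n at once.
#'
#' @inheritParams sds_select
#' @return An `sds_selection` with `n = N`.
#' @export
sds_select_all <- function(m, mode = c("dissimilar", "similar")) {
  m <- validate_matrix(m)
  sds_select(m, n_items(m), mode)
}

#' Best-of-k Monte Carlo subset selection
#'
#' Draws `iterations` uniformly random size-`n` subsets (independent across
#' iterations, repeats permitted), scores each with [set_objective()], and
#' returns the best -- the random-sampling baseline the greedy heuristic is
#' benchmarked against. Deterministic for a fixed `seed`; equal-objective
#' draws resolve to the lexicographically smallest sorted subset.
#'
#' @inheritParams sds_select
#' @param iterations number of random subsets to draw (>= 1).
#' @param seed integer RNG seed; required, and recorded in the result.
#' @param chunk_size internal scoring batch size.
#' @return An `sds_selection` with `order` sorted ascending (selection order
#'   is meaningless for sampling), `iterations` and `seed` recorded.
#' @export
mc_select <- function(m, n, iterations, seed,
                      mode = c("dissimilar", "similar"), chunk_size = 5000L) {
  mode <- .check_mode(mode)
  m <- validate_matrix(m)
  N <- n_items(m)
  n <- as.integer(n)
  iterations <- as.integer(iterations)
  if (n < 2 || n > N) stop("n must satisfy 2 <= n <= N")
  if (iterations < 1L) stop("iterations must be >= 1")
  if (missing(seed)) stop("mc_select requires an explicit seed")
  L <- log(m$values)
  pr <- utils::combn(n, 2)
  better <- if (mode == "dissimilar") `>` else `<`
  best_obj <- NA_real_
  best_set <- NULL
  with_seed(seed, {
    done <- 0L
    while (done < iterations) {
      b <- min(chunk_size, iterations - done)
      S <- vapply(seq_len(b), function(i) sample.int(N, n), integer(n))
      obj <- numeric(b)
      for (p in seq_len(ncol(pr))) {
        obj <- obj + L[S[pr[1, p], ] + (S[pr[2, p], ] - 1L) * N]
      }
      for (i in seq_len(b)) {
        if (is.null(best_set) || better(obj[i], best_obj)) {
          best_obj <- obj[i]
          best_set <- sort.int(S[, i])
        } else if (obj[i] == best_obj) {
          s <- sort.int(S[, i]) # tie: keep the lexicographically smallest set
          if (.lex_less(s, best_set)) best_set <- s
        }
      }
      done <- done + b
    }
  })
  new_selection("monte_carlo", mode, best_set, objective = best_obj,
                N = N, labels = m$labels,
                iterations = iterations, seed = as.integer(seed))
}

.lex_less <- function(a, b) {
  d <- which(a != b)
  length(d) > 0L && a[d[1]] < b[d[1]]
}

#' Exhaustive exact subset selection
#'
#' Enumerates all `choose(N, n)` subsets in lexicographic order and returns
#' the first one attaining the optimal log-sum objective. A tractability
#' guard refuses by default when the search space exceeds `guard` subsets
#' (the count is reported exactly); pass `override = TRUE` at your own risk.
#'
#' @inheritParams sds_select
#' @param guard maximum number of subsets enumerated without `override`
#'   (default `1e7`).
#' @param override set `TRUE` to enumerate past the guard.
#' @return An `sds_selection` with `order` sorted ascending.
#' @export
exact_select <- function(m, n, mode = c("dissimilar", "similar"),
                         guard = 1e7, override = FALSE) {
  mode <- .check_mode(mode)
  m <- validate_matrix(m)
  N <- n_items(m)
  n <- as.integer(n)
  if (n < 2 || n > N) stop("n must satisfy 2 <= n <= N")
  count <- choose(N, n)
  if (count > guard && !override) {
    stop(sprintf(
      "exhaustive search over choose(%d, %d) = %s subsets exceeds the guard (%g); set override = TRUE to proceed",
      N, n, as.character(search_space_size(N, n)), guard))
  }
  L <- log(m$values)
  diag(L) <- 0 # never read (i < j only), but keep the matrix NA-free
  res <- exact_enumerate_cpp(L, n, mode == "dissimilar")
  new_selection("exact", mode, res$indices, objective = res$objective,
                N = N, labels = m$labels)
}
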