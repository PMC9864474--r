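test_that("select_initial_pair finds the extreme pair with lexicographic ties", {
  m3 <- validate_matrix(matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3))
  expect_identical(select_initial_pair(m3, "dissimilar"), c(2L, 3L))
  expect_identical(select_initial_pair(m3, "similar"), c(1L, 2L))

  eq <- validate_matrix(matrix(1, 4, 4) - diag(1, 4))
  expect_identical(select_initial_pair(eq, "dissimilar"), c(1L, 2L))

  for (seed in 1:5) {
    m <- rand_matrix(12, seed = 300 + seed)
    v <- m$values
    # brute-force pair scan oracle
    ut <- which(upper.tri(v), arr.ind = TRUE)
    objs <- v[ut]
    exp_pair <- ut[order(-objs, ut[, 1], ut[, 2])[1], ]
    expect_identical(select_initial_pair(m, "dissimilar"),
                     as.integer(c(exp_pair[1], exp_pair[2])))
    exp_min <- ut[order(objs, ut[, 1], ut[, 2])[1], ]
    expect_identical(select_initial_pair(m, "similar"),
                     as.integer(c(exp_min[1], exp_min[2])))
  }
})

test_that("sds_select reproduces the hand-traced 1-D instance", {
  # points 0, 1, 10, 11: initial pair (1, 4), d = 11; then items 2 and 3 tie
  # at ln 1 + ln 10, so the smaller index 2 is chosen
  m <- line_points_matrix()
  sel <- sds_select(m, 3)
  expect_identical(sel$order, c(1L, 4L, 2L))
  expect_equal(sel$step_scores, log(1) + log(10))
  expect_equal(sel$objective, log(11) + log(1) + log(10))
  expect_equal(sel$objective_trace, c(log(11), log(11) + log(10)))
})

test_that("sds_select at n = 2 is the exact solution", {
  for (seed in 1:10) {
    m <- rand_matrix(15, seed = 400 + seed)
    s2 <- sds_select(m, 2)
    expect_identical(s2$order, select_initial_pair(m, "dissimilar"))
    ex <- exact_select(m, 2)
    expect_identical(sort(s2$order), ex$order)
    expect_equal(s2$objective, ex$objective, tolerance = 1e-12)
  }
})

test_that("exact duplicates are shunned until no finite candidate remains", {
  base <- rand_matrix(6, seed = 17)$values
  v <- rbind(cbind(base, base[, 1]), c(base[1, ], 0)) # item 7 duplicates item 1
  m <- validate_matrix(v)
  # rows 1 and 7 are identical, so ties always prefer 1; once 1 is in, 7
  # scores -Inf and must be the last item standing
  sel <- sds_select(m, 6)
  expect_false(7L %in% sel$order)
  expect_true(1L %in% sel$order)
  # only once everything else is in can the duplicate enter, at -Inf score
  all7 <- sds_select(m, 7)
  expect_identical(sort(all7$order), 1:7)
  expect_identical(all7$objective, -Inf)
})

test_that("greedy increments equal step scores and recomputed prefix objectives", {
  m <- rand_matrix(20, seed = 11)
  for (mode in c("dissimilar", "similar")) {
    sel <- sds_select_all(m, mode)
    expect_equal(diff(sel$objective_trace), sel$step_scores, tolerance = 1e-9)
    for (k in 2:20) {
      expect_equal(sel$objective_trace[k - 1],
                   set_objective(m, sel$order[seq_len(k)]), tolerance = 1e-9)
    }
  }
})

test_that("sds_select_all prefixes are the smaller selections (nesting)", {
  for (seed in c(5, 23)) {
    m <- random_point_population(30, dim = 3, seed = seed)
    for (mode in c("dissimilar", "similar")) {
      full <- sds_select_all(m, mode)
      expect_identical(sort(full$order), 1:30)
      for (k in c(2, 3, 7, 15, 29)) {
        part <- sds_select(m, k, mode)
        expect_identical(part$order, full$order[seq_len(k)])
        expect_identical(part$step_scores, full$step_scores[seq_len(k - 2)])
      }
    }
  }
})

test_that("mc_select is seed-deterministic and scores what it reports", {
  m <- random_point_population(40, dim = 2, seed = 3)
  a <- mc_select(m, 4, iterations = 200, seed = 77)
  b <- mc_select(m, 4, iterations = 200, seed = 77)
  expect_identical(a[c("order", "objective", "iterations", "seed")],
                   b[c("order", "objective", "iterations", "seed")])
  expect_identical(a$order, sort(a$order))
  expect_equal(a$objective, set_objective(m, a$order), tolerance = 1e-12)

  one <- mc_select(m, 5, iterations = 1, seed = 9)
  expect_equal(one$objective, set_objective(m, one$order), tolerance = 1e-12)
  expect_identical(one$iterations, 1L)

  expect_error(mc_select(m, 4, iterations = 0, seed = 1), "iterations")
  expect_error(mc_select(m, 4, iterations = 10), "seed")
})

test_that("mc_select converges to the exact optimum on a tiny instance", {
  # N = 6, n = 3: only 20 subsets; 5,000 draws miss one with prob < 1e-400
  m <- rand_matrix(6, seed = 31)
  ex <- exact_select(m, 3)
  mc <- mc_select(m, 3, iterations = 5000, seed = 1)
  expect_identical(mc$order, ex$order)
  expect_equal(mc$objective, ex$objective, tolerance = 1e-12)
})

test_that("mc_select best-so-far is non-decreasing in nested iteration budgets", {
  m <- random_point_population(50, dim = 3, seed = 13)
  objs <- vapply(c(50, 200, 1000), function(k)
    mc_select(m, 5, iterations = k, seed = 42)$objective, numeric(1))
  expect_true(all(diff(objs) >= 0))
  objs_min <- vapply(c(50, 200, 1000), function(k)
    mc_select(m, 5, iterations = k, seed = 42, mode = "similar")$objective,
    numeric(1))
  expect_true(all(diff(objs_min) <= 0))
})

test_that("exact_select agrees with independent full enumeration", {
  for (seed in 1:4) {
    m <- rand_matrix(10, seed = 500 + seed)
    for (mode in c("dissimilar", "similar")) {
      ex <- exact_select(m, 5, mode)
      oracle <- brute_best_subset(m, 5, maximize = mode == "dissimilar")
      expect_identical(ex$order, as.integer(oracle$indices))
      expect_equal(ex$objective, oracle$objective, tolerance = 1e-9)
      if (mode == "dissimilar") {
        expect_true(all(ex$objective >= oracle$all_objectives - 1e-12))
      }
    }
  }
})

test_that("exact_select boundary cases and the tractability guard", {
  m <- rand_matrix(8, seed = 61)
  expect_identical(exact_select(m, 2)$order, select_initial_pair(m, "dissimilar"))
  expect_identical(exact_select(m, 8)$order, 1:8)
  expect_error(exact_select(m, 4, guard = 10), "guard")
  expect_error(exact_select(m, 4, guard = 10), "70") # exact count in message
  ov <- exact_select(m, 4, guard = 10, override = TRUE)
  expect_s3_class(ov, "sds_selection")
})

test_that("selection objectives sandwich correctly on random instances", {
  for (seed in 1:6) {
    m <- random_point_population(14, dim = 3, seed = 600 + seed)
    n <- 6
    ex <- exact_select(m, n)$objective
    sds <- sds_select(m, n)$objective
    mc <- mc_select(m, n, iterations = 400, seed = seed)$objective
    mn <- exact_select(m, n, "similar")$objective
    expect_true(ex >= sds - 1e-9)
    expect_true(ex >= mc - 1e-9)
    expect_true(sds >= mn - 1e-9)
    # similar mode mirrors the ordering
    ex_min <- exact_select(m, n, "similar")$objective
    sds_min <- sds_select(m, n, "similar")$objective
    expect_true(ex_min <= sds_min + 1e-9)
  }
})

test_that("selection reports and summaries round-trip the selection", {
  m <- line_points_matrix()
  sel <- sds_select(m, 4)
  rep <- selection_report(sel)
  expect_identical(rep$index, sel$order)
  expect_equal(rep$prefix_objective[-1], sel$objective_trace)
  expect_equal(rep$step_score[-(1:2)], sel$step_scores)

  s <- selection_summary(sel)
  expect_identical(unname(s["method"]), "sds")
  expect_identical(as.integer(strsplit(s[["indices"]], ",")[[1]]), sel$order)
  expect_equal(as.numeric(s[["objective"]]), sel$objective, tolerance = 1e-15)
})
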