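test_that("singleton support is exact and prunes below sup_min", {
  toy <- toy_cohort()
  expect_null(singleton_support(toy$matrix, 1, 0.5))  # 4/10 < 0.5
  s6 <- singleton_support(toy$matrix, 6, 0.5)
  expect_equal(s6$support, 1.0)
  expect_equal(s6$support_set, 1:10)
  empty <- binary_matrix(matrix(0L, 3, 5))
  expect_null(singleton_support(empty, 2, 0.01))
})

test_that("weak ETI support uses the optimal ranked prefix", {
  B <- nested_pair(10, 5)
  ws <- weak_eti_support(B, 1, 2, 0.2)
  expect_equal(ws$support, 0.8)  # 5 full + 3 half-samples: 13/16 >= 0.8
  expect_equal(ws$support_set, 1:8)

  # epsilon = 0 collapses to classical exact support
  B2 <- random_binary(6, 9, 0.5, seed = 21)
  for (iv in list(c(1, 3), c(2, 6), c(4, 4))) {
    ws0 <- weak_eti_support(B2, iv[1], iv[2], 0)
    expect_equal(ws0$support_count,
                 exact_interval_support(B2, iv[1], iv[2]))
  }

  # size-1 intervals ignore epsilon entirely
  one <- weak_eti_support(B, 2, 2, 0.9)
  expect_equal(one$support, 0.5)
  expect_equal(one$support_set, 1:5)
})

test_that("adjacency requires equal size and a one-probe shift", {
  expect_true(is_adjacent(c(2, 3), c(3, 4)))
  expect_true(is_adjacent(c(3, 4), c(2, 3)))
  expect_false(is_adjacent(c(2, 3), c(4, 5)))
  expect_true(is_adjacent(c(2, 2), c(3, 3)))
  expect_false(is_adjacent(c(2, 4), c(3, 4)))
})

test_that("merge dissimilarity is the Jaccard distance of support sets", {
  expect_equal(merge_dissimilarity(1:10, 1:5), 0.5)
  expect_equal(merge_dissimilarity(3:7, 3:7), 0)
  expect_equal(merge_dissimilarity(1:3, 4:6), 1)
  expect_error(merge_dissimilarity(integer(0), 1:3), "non-empty")
})

test_that("the toy cohort mines to the documented maximal patterns", {
  toy <- toy_cohort()
  fit <- mine_cnv(toy$matrix, sup_min = toy$params$sup_min,
                  epsilon = toy$params$epsilon, delta = toy$params$delta)
  p <- fit$patterns
  expect_equal(nrow(p), 3L)
  expect_equal(p$start, c(2L, 6L, 7L))
  expect_equal(p$end, c(5L, 6L, 7L))
  # probe 1 pruned from every pattern; probes 6 and 7 never joined
  expect_true(all(p$start > 1L))
  expect_false(any(p$start <= 6L & p$end >= 7L))
  expect_equal(p$support, c(0.6, 1.0, 0.5))
})

test_that("a noiseless implanted block is recovered exactly", {
  n <- 50
  cells <- matrix(0L, 30, n)
  carriers <- seq(3, 42, by = 2)  # 20 of 50 samples = 40%
  cells[11:20, carriers] <- 1L
  B <- binary_matrix(cells)
  p <- mine_chromosome(B, mining_params(0.3, 0.1, 0.2))
  expect_equal(nrow(p), 1L)
  expect_equal(c(p$start, p$end), c(11L, 20L))
  # the weak criterion admits zero-contribution samples while the pooled
  # density stays above 1 - eps: floor(200 / (0.9 * 10)) = 22 samples, the
  # 20 carriers plus the 2 lowest-index non-carriers (deterministic ties)
  expect_equal(p$support_set[[1]], sort(c(1L, 2L, carriers)))
  expect_equal(p$support_count, 22L)

  # with no tolerance the support set is exactly the carriers
  p0 <- mine_chromosome(B, mining_params(0.3, 0, 0.2))
  expect_equal(c(p0$start, p0$end), c(11L, 20L))
  expect_equal(p0$support_set[[1]], carriers)

  expect_equal(nrow(mine_chromosome(binary_matrix(matrix(0L, 5, 5)),
                                    mining_params(0.2, 0.1, 1))), 0L)
})

test_that("reported patterns satisfy the frequency invariants", {
  params <- mining_params(0.3, 0.2, 0.6)
  for (seed in 1:5) {
    B <- random_binary(25, 15, 0.35, seed = 100 + seed)
    p <- mine_chromosome(B, params)
    quota <- ceiling(params$sup_min * 15 - 1e-9)
    for (i in seq_len(nrow(p))) {
      expect_gte(p$support_count[i], quota)
      # every probe in a pattern was itself frequent (pruning soundness)
      expect_true(all(rowSums(B$cells[p$start[i]:p$end[i], , drop = FALSE])
                      >= quota))
      # every consecutive sub-interval passes the weak density bound
      for (a in p$start[i]:p$end[i]) for (b in a:p$end[i])
        expect_gte(weak_eti_support(B, a, b, params$epsilon)$support_count,
                   quota)
    }
  }
})

test_that("identical inputs give identical output (determinism)", {
  B <- random_binary(40, 12, 0.3, seed = 5)
  params <- mining_params(0.25, 0.2, 0.5)
  p1 <- mine_chromosome(B, params)
  p2 <- mine_chromosome(B, params)
  expect_identical(p1, p2)
})

test_that("total pattern length is monotone in sup_min and epsilon", {
  B <- random_binary(60, 20, 0.3, seed = 9)
  total_len <- function(p) sum(p$size)
  lens <- vapply(c(0.15, 0.25, 0.35, 0.5), function(s)
    total_len(mine_chromosome(B, mining_params(s, 0.2, 1))), numeric(1))
  expect_true(all(diff(lens) <= 0))  # higher support, fewer/shorter patterns

  lens_eps <- vapply(c(0, 0.1, 0.2, 0.3), function(e)
    total_len(mine_chromosome(B, mining_params(0.25, e, 1))), numeric(1))
  expect_true(all(diff(lens_eps) >= 0))  # more tolerance, larger patterns
})

test_that("genome mining is per chromosome and split-invariant", {
  c1 <- matrix(0L, 10, 8); c1[3:5, 1:4] <- 1L
  c2 <- matrix(0L, 12, 8); c2[7:10, 5:8] <- 1L
  B1 <- binary_matrix(c1, track = probe_track(paste0("a", 1:10), "chr1", 1:10))
  B2 <- binary_matrix(c2, track = probe_track(paste0("b", 1:12), "chr2", 1:12))
  p <- mine_genome(list(B1, B2), mining_params(0.4, 0.1, 0.5))
  expect_equal(nrow(p), 2L)
  expect_equal(sort(p$chromosome), c("chr1", "chr2"))

  # splitting a matrix outside any pattern leaves the pattern set unchanged
  B <- random_binary(30, 10, 0.25, seed = 31)
  whole <- mine_chromosome(B, mining_params(0.3, 0.2, 1))
  # pick a split position no pattern crosses
  free <- Filter(function(c) all(whole$end <= c | whole$start > c), 1:29)
  expect_gt(length(free), 0L)
  cut <- free[ceiling(length(free) / 2)]
  top <- binary_matrix(B$cells[1:cut, , drop = FALSE])
  bot <- binary_matrix(B$cells[(cut + 1L):30, , drop = FALSE])
  split_pat <- rbind(mine_chromosome(top, mining_params(0.3, 0.2, 1)),
                     transform(mine_chromosome(bot, mining_params(0.3, 0.2, 1)),
                               start = start + cut, end = end + cut))
  expect_equal(unname(as.matrix(whole[, c("start", "end")])),
               unname(as.matrix(split_pat[, c("start", "end")])))

  bad <- binary_matrix(c1, sample_ids = paste0("x", 1:8))
  expect_error(mine_genome(list(B1, bad), mining_params(0.4, 0.1, 0.5)),
               "sample IDs differ")
})

test_that("parameter ranges are validated", {
  expect_error(mining_params(0, 0.2, 0.4), "sup_min")
  expect_error(mining_params(1.5, 0.2, 0.4), "sup_min")
  expect_error(mining_params(0.5, 1, 0.4), "epsilon")
  expect_error(mining_params(0.5, 0.2, -0.1), "delta")
})
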