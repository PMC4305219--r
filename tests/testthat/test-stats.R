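test_that("proportional support sets give a null chi-squared result", {
  labels <- rep(c("A", "B", "C"), each = 30)
  support <- c(1:10, 31:40, 61:70)  # 10 from each group
  res <- specificity_test(support, labels)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$dof, 2L)
  expect_false(res$flagged)
})

test_that("a fully group-specific pattern reproduces the hand-computed table", {
  labels <- rep(c("YRI", "CEU", "ASN"), each = 30)
  res <- specificity_test(1:30, labels)  # support = all of one group
  # expected counts 10/10/10 and 20/20/20 give Pearson chi-squared 90
  expect_equal(res$statistic, 90)
  expect_equal(res$dof, 2L)
  expect_lt(res$p_value, 1e-3)
  expect_equal(unname(rowSums(res$table)), c(30, 60))
})

test_that("degenerate margins are flagged, not tested", {
  labels <- factor(rep(c("A", "B"), each = 10), levels = c("A", "B", "C"))
  res <- specificity_test(1:5, labels)
  expect_true(res$flagged)
  expect_true(is.na(res$p_value))
  all_support <- specificity_test(1:20, rep(c("A", "B"), each = 10))
  expect_true(all_support$flagged)  # empty non-support row
  expect_error(specificity_test(1:3, rep("A", 10)), "two sample groups")
})

test_that("the statistic is invariant under group relabeling", {
  set.seed(10)
  labels <- sample(rep(c("g1", "g2", "g3"), times = c(20, 30, 40)))
  support <- sort(sample.int(90, 25))
  a <- specificity_test(support, labels)
  relab <- c(g1 = "x", g2 = "y", g3 = "z")[labels]
  b <- specificity_test(support, relab)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)
})

test_that("filter_specific applies the alpha cutoff (optionally Bonferroni)", {
  df <- data.frame(p_value = c(1e-5, 0.02, 0.5, NA),
                   flagged = c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(nrow(filter_specific(df, 1)), 3L)  # NA (flagged) dropped
  expect_equal(nrow(filter_specific(df, 1e-10)), 0L)
  expect_equal(nrow(filter_specific(df, 0.05)), 2L)
  expect_equal(nrow(filter_specific(df, 0.05, adjust = "bonferroni")), 1L)
})

test_that("type-I error of the specificity test is near nominal", {
  set.seed(77)
  labels <- rep(c("A", "B", "C"), each = 30)
  n_pat <- 1500
  p <- vapply(seq_len(n_pat), function(i) {
    support <- sample.int(90, sample(15:75, 1))  # independent of groups
    specificity_test(support, labels)$p_value
  }, numeric(1))
  for (alpha in c(0.05, 1e-3)) {
    rate <- mean(p < alpha)
    se <- sqrt(alpha * (1 - alpha) / n_pat)
    expect_lt(abs(rate - alpha), 3 * se + 1e-12)
  }
})

test_that("patterns map to genomic coordinates and back", {
  track <- probe_track(paste0("p", 1:6), "chr7",
                       c(100, 250, 400, 410, 900, 1500))
  pat <- list(chromosome = "chr7", start = 2L, end = 5L)
  reg <- pattern_to_region(pat, track)
  expect_equal(reg$bp_start, 250)
  expect_equal(reg$bp_stop, 900)
  expect_gte(reg$bp_stop, reg$bp_start)
  # inverse lookup recovers the probe interval
  idx <- which(track$chromosome == reg$chromosome &
                 track$position_bp >= reg$bp_start &
                 track$position_bp <= reg$bp_stop)
  expect_equal(range(idx), c(2L, 5L))
  single <- pattern_to_region(list(chromosome = "chr7", start = 3L, end = 3L),
                              track)
  expect_equal(single$bp_start, single$bp_stop)
  expect_error(pattern_to_region(list(chromosome = "chrX", start = 1L,
                                      end = 1L), track), "not present")
})

test_that("pattern density counts unioned cells once", {
  expect_equal(pattern_density(empty_patterns(), 10, 10), 0)
  full <- data.frame(chromosome = "c", direction = "gain", start = 1L,
                     end = 10L, size = 10L, support_count = 10L,
                     support = 1, support_set = I(list(1:10)))
  expect_equal(pattern_density(full, 10, 10), 1)
  two <- data.frame(chromosome = "c", direction = "gain",
                    start = c(1L, 51L), end = c(10L, 60L),
                    size = c(10L, 10L), support_count = c(10L, 10L),
                    support = c(0.1, 0.1),
                    support_set = I(list(1:10, 41:50)))
  expect_equal(pattern_density(two, 100, 100), 0.02)
  # overlap is not double-counted
  overlap <- data.frame(chromosome = "c", direction = "gain",
                        start = c(1L, 1L), end = c(10L, 10L),
                        size = c(10L, 10L), support_count = c(10L, 10L),
                        support = c(0.1, 0.1),
                        support_set = I(list(1:10, 1:10)))
  expect_equal(pattern_density(overlap, 100, 100), 0.01)
})
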