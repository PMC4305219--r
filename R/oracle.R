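#' Exhaustive weak-ETI support (testing oracle)
#'
#' Independent brute-force maximization of the weak error-tolerant support
#' of an interval: enumerates sample subsets explicitly instead of using the
#' greedy ranked-prefix argument of [weak_eti_support()]. Exponential in the
#' number of samples by intent and guarded accordingly; it exists to verify
#' the production path, never to replace it.
#'
#' @param B a [binary_matrix()] with at most 16 samples.
#' @param start,end 1-based inclusive probe interval.
#' @param epsilon tolerance in [0, 1) (forced to 0 for size-1 intervals, as
#'   in the production path).
#' @return A list with `support`, `support_count`, `support_set` (the
#'   lexicographically smallest maximizing subset, for reproducible
#'   comparison of the support size), and `is_strong` (whether that subset
#'   also satisfies the per-sample strong-ETI condition).
#' @export
bruteforce_weak_support <- function(B, start, end, epsilon) {
  stopifnot(inherits(B, "binary_matrix"))
  n <- ncol(B$cells)
  if (n > 16L) stop("oracle guarded to n <= 16 samples", call. = FALSE)
  size <- end - start + 1L
  if (size == 1L) epsilon <- 0
  counts <- if (size == 1L) B$cells[start, ] else
    colSums(B$cells[start:end, , drop = FALSE])
  for (k in rev(seq_len(n))) {
    need <- (1 - epsilon) * size * k - 1e-9
    sets <- utils::combn(n, k)
    totals <- if (k == 1L) counts[sets[1L, ]] else colSums(
      matrix(counts[sets], nrow = k))
    hit <- which(totals >= need)
    if (length(hit) > 0L) {
      set <- sets[, hit[1L]]  # combn order = lexicographic
      return(list(support = k / n, support_count = k, support_set = set,
                  is_strong = check_strong_eti(B, start, end, epsilon, set)))
    }
  }
  list(support = 0, support_count = 0L, support_set = integer(0),
       is_strong = FALSE)
}

#' Strong-ETI check
#'
#' Tests the stricter per-sample condition: every sample of `tset`
#' individually must carry 1s on at least `1 - epsilon` of the interval's
#' probes. Strong implies weak at equal tolerance, never the reverse; the
#' strong criterion is provided only as a check because it is typically too
#' restrictive to discover useful associations, and it is not offered as a
#' mining mode.
#'
#' @param B a [binary_matrix()].
#' @param start,end 1-based inclusive probe interval.
#' @param epsilon tolerance in [0, 1).
#' @param tset non-empty vector of 1-based sample indices.
#' @return `TRUE` iff every sample in `tset` meets the density bound.
#' @export
check_strong_eti <- function(B, start, end, epsilon, tset) {
  stopifnot(inherits(B, "binary_matrix"))
  if (length(tset) == 0L) stop("`tset` must be non-empty", call. = FALSE)
  size <- end - start + 1L
  dens <- colSums(B$cells[start:end, tset, drop = FALSE]) / size
  all(dens + 1e-9 >= 1 - epsilon)
}

#' Brute-force enumeration of recursive-weak frequent intervals
#'
#' Dynamic-programming testing oracle over all probe intervals (no merge
#' heuristics, dissimilarity constraint fixed at `delta = 1`): an interval
#' is frequent iff its brute-force weak support reaches `sup_min` and both
#' maximal sub-intervals are frequent; singletons use exact support. The
#' maximal intervals are the frequent ones not contained in a larger
#' frequent interval extending them by one probe on either side — exactly
#' the report of the level-wise miner at `delta = 1`.
#'
#' @param B a [binary_matrix()] with at most 40 probes and 16 samples.
#' @param sup_min,epsilon parameters as in [mining_params()].
#' @return A list with `frequent` (logical m x m matrix, `[a, b]` is the
#'   interval status for `a <= b`) and `maximal` (data frame of maximal
#'   intervals with brute-force support, sorted by start then end).
#' @export
mine_bruteforce <- function(B, sup_min, epsilon) {
  stopifnot(inherits(B, "binary_matrix"))
  m <- nrow(B$cells); n <- ncol(B$cells)
  if (m > 40L || n > 16L)
    stop("oracle guarded to m <= 40, n <= 16", call. = FALSE)
  quota <- support_quota(sup_min, n)
  freq <- matrix(FALSE, m, m)
  supp <- matrix(NA_real_, m, m)
  for (a in seq_len(m)) {
    cnt <- sum(B$cells[a, ])
    freq[a, a] <- cnt >= quota
    supp[a, a] <- cnt / n
  }
  if (m > 1L) for (len in 2:m) for (a in seq_len(m - len + 1L)) {
    b <- a + len - 1L
    if (!(freq[a, b - 1L] && freq[a + 1L, b])) next
    bf <- bruteforce_weak_support(B, a, b, epsilon)
    supp[a, b] <- bf$support
    freq[a, b] <- bf$support_count >= quota
  }
  ivs <- which(freq, arr.ind = TRUE)
  maximal <- if (nrow(ivs) > 0L) {
    keep <- vapply(seq_len(nrow(ivs)), function(i) {
      a <- ivs[i, 1L]; b <- ivs[i, 2L]
      grown_left <- a > 1L && freq[a - 1L, b]
      grown_right <- b < m && freq[a, b + 1L]
      !(grown_left || grown_right)
    }, logical(1))
    iv <- ivs[keep, , drop = FALSE]
    out <- data.frame(start = iv[, 1L], end = iv[, 2L],
                      support = supp[iv], stringsAsFactors = FALSE)
    out[order(out$start, out$end), , drop = FALSE]
  } else data.frame(start = integer(0), end = integer(0),
                    support = numeric(0))
  rownames(maximal) <- NULL
  list(frequent = freq, maximal = maximal)
}
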