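# Shared fixture builders. Random matrices are drawn inside withr-style
# local seeds so tests are order-independent.

local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

random_binary <- function(m, n, density, seed, direction = "gain") {
  local_seed(seed, binary_matrix(matrix(rbinom(m * n, 1L, density), m, n),
                                 direction = direction))
}

# probe A in all n samples, probe B in the first k (nested support sets)
nested_pair <- function(n = 10, k = 5) {
  binary_matrix(rbind(rep(1L, n), rep(c(1L, 0L), c(k, n - k))))
}

# exact (no-tolerance) support of an interval: samples carrying every probe
exact_interval_support <- function(B, s, e) {
  sum(colSums(B$cells[s:e, , drop = FALSE]) == (e - s + 1L))
}

empty_patterns <- function() {
  data.frame(chromosome = character(0), direction = character(0),
             start = integer(0), end = integer(0), size = integer(0),
             support_count = integer(0), support = numeric(0),
             support_set = I(list()), stringsAsFactors = FALSE)
}

# naive enumerator of maximal exact-support intervals (classical frequent
# itemsets under the consecutive-probe constraint)
naive_exact_maximal <- function(B, sup_min) {
  m <- nrow(B$cells); n <- ncol(B$cells)
  quota <- ceiling(sup_min * n - 1e-9)
  freq <- matrix(FALSE, m, m)
  for (a in seq_len(m)) for (b in a:m)
    freq[a, b] <- exact_interval_support(B, a, b) >= quota
  out <- which(freq, arr.ind = TRUE)
  keep <- vapply(seq_len(nrow(out)), function(i) {
    a <- out[i, 1L]; b <- out[i, 2L]
    !((a > 1L && freq[a - 1L, b]) || (b < m && freq[a, b + 1L]))
  }, logical(1))
  iv <- out[keep, , drop = FALSE]
  iv <- iv[order(iv[, 1L], iv[, 2L]), , drop = FALSE]
  unname(iv)
}
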