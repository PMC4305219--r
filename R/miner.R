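#' Mining hyper-parameters
#'
#' The three user parameters governing the interval search.
#'
#' @param sup_min minimum support as a fraction of samples in (0, 1]; an
#'   interval is frequent when at least `ceiling(sup_min * n)` samples
#'   support it.
#' @param epsilon error tolerance of the weak density condition, in [0, 1):
#'   a sample subset supports an interval when the average of the 0/1 cells
#'   over the interval-by-subset submatrix is at least `1 - epsilon`.
#'   Singletons are always evaluated exactly (no tolerance).
#' @param delta maximum allowed dissimilarity between the support sets of
#'   two intervals being merged, in [0, 1]: 0 requires identical support
#'   sets, 1 removes the constraint.
#' @return A `mining_params` list.
#' @export
mining_params <- function(sup_min, epsilon = 0, delta = 1) {
  chk <- function(v, nm, lo, hi, lo_open, hi_open) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        (if (lo_open) v <= lo else v < lo) ||
        (if (hi_open) v >= hi else v > hi))
      stop(sprintf("`%s` must be a single number in %s%g, %g%s", nm,
                   if (lo_open) "(" else "[", lo, hi,
                   if (hi_open) ")" else "]"), call. = FALSE)
    v
  }
  structure(list(sup_min = chk(sup_min, "sup_min", 0, 1, TRUE, FALSE),
                 epsilon = chk(epsilon, "epsilon", 0, 1, FALSE, TRUE),
                 delta = chk(delta, "delta", 0, 1, FALSE, FALSE)),
            class = "mining_params")
}

# minimum number of supporting samples implied by sup_min (small FP guard so
# e.g. 0.3 * 10 never rounds up to 4)
support_quota <- function(sup_min, n) as.integer(ceiling(sup_min * n - 1e-9))

#' Exact support of a single probe
#'
#' Support of a singleton itemset: the fraction of samples with a 1 at the
#' probe, computed with no error tolerance. Probes below `sup_min` are
#' pruned from the search before any merging.
#'
#' @param B a [binary_matrix()].
#' @param probe probe (row) index, 1-based.
#' @param sup_min minimum support fraction.
#' @return A list with `start`, `end`, `support`, `support_count`,
#'   `support_set` (ascending 1-based sample indices), or `NULL` when
#'   support is below `sup_min`.
#' @export
singleton_support <- function(B, probe, sup_min) {
  stopifnot(inherits(B, "binary_matrix"))
  m <- nrow(B$cells); n <- ncol(B$cells)
  if (probe < 1L || probe > m) stop("probe index out of bounds", call. = FALSE)
  set <- unname(which(B$cells[probe, ] == 1L))
  if (length(set) < support_quota(sup_min, n)) return(NULL)
  list(start = probe, end = probe, support = length(set) / n,
       support_count = length(set), support_set = set)
}

#' Weak error-tolerant support of a probe interval
#'
#' The weak error-tolerant itemset (ETI) criterion: an interval is supported
#' by a sample subset T' when the mean of the 0/1 cells over the
#' interval-by-T' submatrix is at least `1 - epsilon`. This function returns
#' the maximum achievable `|T'| / n` together with one maximizing subset.
#'
#' The maximizing subset is found greedily: samples are ranked by their
#' count of 1s within the interval (descending, ties broken by ascending
#' sample index) and the longest feasible prefix is taken. The prefix scheme
#' is exactly optimal — for every subset size k the top-k prefix maximizes
#' the total number of 1s, and the cumulative density of the ranked prefix
#' is non-increasing in k — so the greedy answer equals the exhaustive
#' maximum over all 2^n subsets (see [bruteforce_weak_support()] for the
#' independent check).
#'
#' Size-1 intervals are evaluated exactly (`epsilon` forced to 0): error
#' tolerance on a single probe would let arbitrary samples join the support
#' set.
#'
#' @param B a [binary_matrix()].
#' @param start,end 1-based inclusive probe indices of the interval.
#' @param epsilon tolerance in [0, 1).
#' @return A list with `support` (fraction), `support_count`, and
#'   `support_set` (ascending 1-based sample indices; empty when no
#'   non-empty subset meets the density bound).
#' @examples
#' # probe A in all 10 samples, probe B in 5 nested samples:
#' cells <- rbind(rep(1, 10), rep(c(1, 0), each = 5))
#' B <- binary_matrix(cells)
#' weak_eti_support(B, 1, 2, epsilon = 0.2)$support  # 0.8
#' @export
weak_eti_support <- function(B, start, end, epsilon) {
  stopifnot(inherits(B, "binary_matrix"))
  m <- nrow(B$cells); n <- ncol(B$cells)
  if (start < 1L || end > m || start > end)
    stop("invalid probe interval", call. = FALSE)
  size <- end - start + 1L
  if (size == 1L) epsilon <- 0
  counts <- if (size == 1L) B$cells[start, ] else
    colSums(B$cells[start:end, , drop = FALSE])
  ord <- order(-counts, seq_len(n))
  cum <- cumsum(counts[ord])
  k_seq <- seq_len(n)
  feasible <- cum + 1e-9 >= (1 - epsilon) * size * k_seq
  k <- if (any(feasible)) as.integer(max(k_seq[feasible])) else 0L
  set <- if (k > 0L) sort(ord[seq_len(k)]) else integer(0)
  # a ranked prefix has non-increasing cumulative density, so the largest
  # feasible k is the overall optimum
  list(support = k / n, support_count = k, support_set = set)
}

#' Are two equal-size intervals mergeable neighbors?
#'
#' Two size-k intervals pass the positional criterion when they differ only
#' in their first and last probe, i.e. they are `[s, s+k-1]` and
#' `[s+1, s+k]`: their union is then the contiguous size-(k+1) candidate.
#'
#' @param a,b intervals as `c(start, end)` (1-based inclusive) or lists with
#'   `start`/`end`.
#' @return `TRUE` or `FALSE`.
#' @export
is_adjacent <- function(a, b) {
  iv <- function(x) if (is.list(x)) c(x$start, x$end) else x
  a <- iv(a); b <- iv(b)
  if ((a[2] - a[1]) != (b[2] - b[1])) return(FALSE)
  abs(a[1] - b[1]) == 1
}

#' Support-set dissimilarity governing merges
#'
#' The fraction of non-overlapping samples between two support sets:
#' symmetric difference over union (Jaccard distance). 0 iff the sets are
#' identical, 1 iff disjoint. A merge is permitted when the dissimilarity is
#' at most `delta`; the check guards against absorbing a weakly supported
#' neighbor into a strongly supported one, which would blur two distinct
#' sample signatures into one pattern.
#'
#' @param s1,s2 non-empty integer vectors of sample indices.
#' @return Dissimilarity in [0, 1].
#' @examples
#' merge_dissimilarity(1:10, 1:5)  # 0.5
#' @export
merge_dissimilarity <- function(s1, s2) {
  if (length(s1) == 0L || length(s2) == 0L)
    stop("support sets must be non-empty", call. = FALSE)
  u <- union(s1, s2)
  1 - length(intersect(s1, s2)) / length(u)
}

#' Mine one chromosome for maximal frequent CNV intervals
#'
#' Level-wise search over consecutive-probe intervals. Round 1 keeps every
#' probe whose exact support reaches `sup_min`. In each later round, every
#' adjacent pair of frequent size-k intervals whose support sets differ by
#' at most `delta` proposes the size-(k+1) union; the candidate is frequent
#' when its weak error-tolerant support reaches `sup_min` (its two parents
#' being frequent certifies, inductively, that all consecutive sub-intervals
#' are — the recursive-weak criterion). On success both parents are marked
#' consumed; on failure the parents stay as individual frequent intervals.
#' The search stops when a round yields nothing new, and all frequent
#' intervals never consumed by a successful merge are reported as maximal
#' patterns with their maximizing support sets, sorted by (start, end).
#'
#' @param B a [binary_matrix()]; all probes are treated as one ordered
#'   chromosome (use [mine_cnv()] for multi-chromosome input).
#' @param params a [mining_params()].
#' @return A data frame with columns `chromosome`, `direction`, `start`,
#'   `end`, `size`, `support_count`, `support` and a list column
#'   `support_set` of ascending 1-based sample indices.
#' @export
mine_chromosome <- function(B, params) {
  stopifnot(inherits(B, "binary_matrix"))
  if (!inherits(params, "mining_params"))
    params <- do.call(mining_params, as.list(params))
  m <- nrow(B$cells); n <- ncol(B$cells)
  quota <- support_quota(params$sup_min, n)

  counts1 <- rowSums(B$cells)
  cur <- lapply(which(counts1 >= quota), function(p)
    list(start = p, end = p, support_count = as.integer(counts1[[p]]),
         support_set = unname(which(B$cells[p, ] == 1L))))
  kept <- list()  # frequent intervals from finished rounds, never consumed

  while (length(cur) > 0L) {
    consumed <- rep(FALSE, length(cur))
    nxt <- list()
    starts <- vapply(cur, `[[`, integer(1), "start")
    right_of <- match(starts + 1L, starts)  # neighbor with start+1, same size
    for (i in seq_along(cur)) {
      j <- right_of[i]
      if (is.na(j)) next
      left <- cur[[i]]; right <- cur[[j]]
      if (merge_dissimilarity(left$support_set, right$support_set) >
          params$delta) next
      ws <- weak_eti_support(B, left$start, right$end, params$epsilon)
      if (ws$support_count >= quota) {
        consumed[i] <- TRUE; consumed[j] <- TRUE
        nxt[[length(nxt) + 1L]] <- list(
          start = left$start, end = right$end,
          support_count = ws$support_count, support_set = ws$support_set)
      }
    }
    kept <- c(kept, cur[!consumed])
    cur <- nxt
  }

  if (length(kept) == 0L)
    return(empty_pattern_frame())
  ord <- order(vapply(kept, `[[`, integer(1), "start"),
               vapply(kept, `[[`, integer(1), "end"))
  kept <- kept[ord]
  chrom <- unique(B$track$chromosome)
  data.frame(
    chromosome = if (length(chrom) == 1L) chrom else NA_character_,
    direction = B$direction,
    start = vapply(kept, `[[`, integer(1), "start"),
    end = vapply(kept, `[[`, integer(1), "end"),
    size = vapply(kept, function(p) p$end - p$start + 1L, integer(1)),
    support_count = vapply(kept, `[[`, integer(1), "support_count"),
    support = vapply(kept, `[[`, integer(1), "support_count") / n,
    support_set = I(lapply(kept, `[[`, "support_set")),
    stringsAsFactors = FALSE)
}

empty_pattern_frame <- function() {
  data.frame(chromosome = character(0), direction = character(0),
             start = integer(0), end = integer(0), size = integer(0),
             support_count = integer(0), support = numeric(0),
             support_set = I(list()), stringsAsFactors = FALSE)
}

#' Mine a set of per-chromosome binary matrices
#'
#' Applies [mine_chromosome()] independently to each matrix and concatenates
#' the results; intervals never span a chromosome boundary. All matrices
#' must share the same samples in the same order.
#'
#' @param matrices list of [binary_matrix()] objects, one per chromosome
#'   (and per direction).
#' @param params a [mining_params()].
#' @return Combined pattern data frame (see [mine_chromosome()]).
#' @export
mine_genome <- function(matrices, params) {
  if (inherits(matrices, "binary_matrix")) matrices <- list(matrices)
  ids <- lapply(matrices, `[[`, "sample_ids")
  if (length(unique(lapply(ids, paste, collapse = "\r"))) > 1L)
    stop("sample IDs differ across chromosome matrices", call. = FALSE)
  res <- lapply(matrices, function(B) {
    chroms <- unique(B$track$chromosome)
    if (length(chroms) > 1L) {
      do.call(rbind, lapply(chroms, function(chr)
        mine_chromosome(subset_chromosome(B, chr), params)))
    } else mine_chromosome(B, params)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) empty_pattern_frame() else out
}

# restrict a binary matrix to one chromosome; probe indices in the result
# are local to that chromosome
subset_chromosome <- function(B, chr) {
  idx <- which(B$track$chromosome == chr)
  binary_matrix(B$cells[idx, , drop = FALSE], B$sample_ids,
                probe_track(B$track$probe_id[idx], chr,
                            B$track$position_bp[idx]),
                B$direction)
}

#' Mine CNV patterns from an intensity or binary matrix
#'
#' The main entry point. Continuous input is binarized first (gain and loss
#' separately, either at a supplied threshold `tau` or at a threshold chosen
#' by [select_tau()] from `target_density`), then each chromosome and
#' direction is mined independently for maximal frequent intervals.
#'
#' @param x an [intensity_matrix()] or a [binary_matrix()].
#' @param sup_min,epsilon,delta mining parameters, see [mining_params()].
#' @param tau binarization threshold (intensity input only).
#' @param target_density alternative to `tau`: desired overall CNV cell
#'   density, see [select_tau()]. Exactly one of `tau` / `target_density`
#'   may be given; with neither, a 10% target density is used.
#' @param directions directions to mine on intensity input.
#' @return A `cnv_patterns` object: list with `patterns` (data frame of
#'   maximal patterns), `params`, `tau`, `n_samples`, `n_probes`,
#'   `sample_ids` and the matched call. Probe and sample indices in
#'   `patterns` are 1-based; [write_patterns()] emits the 0-based on-disk
#'   convention.
#' @examples
#' toy <- toy_cohort()
#' fit <- mine_cnv(toy$matrix, sup_min = 0.5, epsilon = 0.2, delta = 0.4)
#' fit
#' @export
mine_cnv <- function(x, sup_min, epsilon = 0, delta = 1, tau = NULL,
                     target_density = NULL,
                     directions = c("gain", "loss")) {
  params <- mining_params(sup_min, epsilon, delta)
  directions <- match.arg(directions, several.ok = TRUE)
  used_tau <- NA_real_
  if (inherits(x, "intensity_matrix")) {
    if (!is.null(tau) && !is.null(target_density))
      stop("supply only one of `tau` and `target_density`", call. = FALSE)
    if (is.null(tau))
      tau <- select_tau(x, if (is.null(target_density)) 0.1 else
        target_density)
    used_tau <- as.numeric(tau)
    mats <- lapply(directions, function(d) binarize(x, used_tau, d))
    sample_ids <- x$sample_ids
    np <- nrow(x$values); ns <- ncol(x$values)
  } else if (inherits(x, "binary_matrix")) {
    mats <- list(x)
    sample_ids <- x$sample_ids
    np <- nrow(x$cells); ns <- ncol(x$cells)
  } else stop("`x` must be an intensity_matrix or binary_matrix",
              call. = FALSE)
  pat <- mine_genome(mats, params)
  structure(list(patterns = pat, params = params, tau = used_tau,
                 n_probes = np, n_samples = ns, sample_ids = sample_ids,
                 call = match.call()),
            class = "cnv_patterns")
}

#' @export
print.cnv_patterns <- function(x, ...) {
  p <- x$patterns
  cat(sprintf(
    "CNV pattern mining: %d probes x %d samples (sup_min=%g, epsilon=%g, delta=%g)\n",
    x$n_probes, x$n_samples, x$params$sup_min, x$params$epsilon,
    x$params$delta))
  if (!is.na(x$tau)) cat(sprintf("binarization threshold tau = %g\n", x$tau))
  cat(sprintf("%d maximal pattern(s)", nrow(p)))
  if (nrow(p) > 0L)
    cat(sprintf("; sizes %d-%d, support %.2f-%.2f", min(p$size), max(p$size),
                min(p$support), max(p$support)))
  cat("\n")
  invisible(x)
}

#' @export
summary.cnv_patterns <- function(object, ...) {
  p <- object$patterns
  out <- list(
    n_patterns = nrow(p),
    by_direction = if (nrow(p)) table(p$direction) else table(character(0)),
    total_probe_length = sum(p$size),
    size = if (nrow(p)) summary(p$size) else NULL,
    support = if (nrow(p)) summary(p$support) else NULL,
    density = pattern_density(p, object$n_probes, object$n_samples))
  class(out) <- "summary.cnv_patterns"
  out
}

#' @export
print.summary.cnv_patterns <- function(x, ...) {
  cat(sprintf("%d maximal pattern(s); total probe length %d\n",
              x$n_patterns, x$total_probe_length))
  if (x$n_patterns > 0L) {
    cat("by direction: ")
    print(x$by_direction)
    cat("pattern sizes:\n"); print(x$size)
    cat("support fractions:\n"); print(x$support)
  }
  cat(sprintf("pattern cell density: %.4f\n", x$density))
  invisible(x)
}

#' @export
as.data.frame.cnv_patterns <- function(x, ...) x$patterns

#' Heatmap of a mined binary matrix with pattern outlines
#'
#' Plots the 0/1 matrix (probes on the x-axis in genomic order, samples on
#' the y-axis) and overlays each reported pattern as a rectangle spanning
#' its probe interval and support samples.
#'
#' @param x a `cnv_patterns` object.
#' @param B the [binary_matrix()] that was mined (kept separate so large
#'   matrices need not live inside the result object).
#' @param ... passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.cnv_patterns <- function(x, B, ...) {
  stopifnot(inherits(B, "binary_matrix"))
  cells <- B$cells
  graphics::image(seq_len(nrow(cells)), seq_len(ncol(cells)), cells,
                  col = c("grey95", "grey20"), xlab = "probe (genomic order)",
                  ylab = "sample", ...)
  p <- x$patterns[x$patterns$direction == B$direction, , drop = FALSE]
  for (i in seq_len(nrow(p))) {
    ss <- p$support_set[[i]]
    graphics::rect(p$start[i] - 0.5, min(ss) - 0.5, p$end[i] + 0.5,
                   max(ss) + 0.5, border = "red", lwd = 2)
  }
  invisible(x)
}
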