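#' Group-specificity test for one pattern
#'
#' Splits the cohort into the pattern's support group and non-support group
#' and tests association with sample group labels (e.g. populations) by a
#' Pearson chi-squared test on the 2 x K contingency table, K - 1 degrees
#' of freedom, no continuity correction. Patterns whose table has a zero
#' column margin (a group with no samples) are flagged rather than tested;
#' small expected counts trigger a warning but no method switch.
#'
#' @param support_set 1-based sample indices supporting the pattern.
#' @param labels group label per sample (character or factor, length = total
#'   sample count); at least two groups.
#' @return A `specificity_result` list: `table` (2 x K), `statistic`, `dof`,
#'   `p_value`, `flagged`.
#' @examples
#' labels <- rep(c("YRI", "CEU", "ASN"), each = 30)
#' specificity_test(1:30, labels)  # support = one whole group
#' @export
specificity_test <- function(support_set, labels) {
  labels <- as.factor(labels)
  n <- length(labels)
  if (nlevels(labels) < 2L)
    stop("at least two sample groups are required", call. = FALSE)
  if (length(support_set) == 0L || any(support_set < 1L | support_set > n))
    stop("`support_set` must be non-empty 1-based indices into `labels`",
         call. = FALSE)
  in_support <- factor(seq_len(n) %in% support_set,
                       levels = c(TRUE, FALSE),
                       labels = c("support", "non-support"))
  tab <- table(in_support, labels)
  out <- list(table = tab, statistic = NA_real_,
              dof = nlevels(labels) - 1L, p_value = NA_real_,
              flagged = FALSE)
  if (any(colSums(tab) == 0L) || any(rowSums(tab) == 0L)) {
    out$flagged <- TRUE
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    if (any(ct$expected < 5))
      warning("expected counts below 5; chi-squared approximation may be poor",
              call. = FALSE)
    out$statistic <- unname(ct$statistic)
    out$p_value <- unname(ct$p.value)
  }
  class(out) <- "specificity_result"
  out
}

#' @export
print.specificity_result <- function(x, ...) {
  if (x$flagged) {
    cat("specificity test flagged (degenerate margin); not tested\n")
  } else {
    cat(sprintf("chi-squared = %.4g, df = %d, p = %.4g\n", x$statistic,
                x$dof, x$p_value))
  }
  invisible(x)
}

#' Group-specificity tests for all mined patterns
#'
#' Runs [specificity_test()] on every pattern and returns one row per
#' pattern with the statistic and p-value appended.
#'
#' @param x a `cnv_patterns` object or pattern data frame.
#' @param labels group label per sample.
#' @return The pattern data frame with `chisq`, `dof`, `p_value`, `flagged`
#'   columns added.
#' @export
specificity_tests <- function(x, labels) {
  pat <- if (inherits(x, "cnv_patterns")) x$patterns else x
  res <- lapply(pat$support_set, specificity_test, labels = labels)
  pat$chisq <- vapply(res, `[[`, numeric(1), "statistic")
  pat$dof <- vapply(res, `[[`, integer(1), "dof")
  pat$p_value <- vapply(res, `[[`, numeric(1), "p_value")
  pat$flagged <- vapply(res, `[[`, logical(1), "flagged")
  pat
}

#' Retain group-specific patterns
#'
#' Keeps patterns with `p_value < alpha`. By default no multiplicity
#' adjustment is applied, matching the common convention of reporting
#' patterns below a fixed threshold such as 1e-3; Bonferroni correction is
#' available but off by default. Flagged (untested) patterns are dropped.
#'
#' @param results data frame from [specificity_tests()].
#' @param alpha significance level.
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return The retained subset of `results`.
#' @export
filter_specific <- function(results, alpha, adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  p <- results$p_value
  if (adjust == "bonferroni") p <- stats::p.adjust(p, "bonferroni")
  keep <- !is.na(p) & p < alpha
  results[keep, , drop = FALSE]
}

#' Map a pattern to genomic coordinates
#'
#' Translates a pattern's probe interval into chromosome and base-pair
#' coordinates using the probe track: the position of its first and last
#' probe, 1-based inclusive.
#'
#' @param pattern one row of a pattern data frame (or a list with
#'   `chromosome`, `start`, `end`).
#' @param track a [probe_track()] covering the pattern's chromosome; probe
#'   indices are interpreted within that chromosome, in track order.
#' @return A list with `chromosome`, `bp_start`, `bp_stop`.
#' @export
pattern_to_region <- function(pattern, track) {
  stopifnot(inherits(track, "probe_track"))
  chr <- as.character(pattern$chromosome)
  idx <- which(track$chromosome == chr)
  if (length(idx) == 0L)
    stop("chromosome ", chr, " not present in track", call. = FALSE)
  start <- pattern$start; end <- pattern$end
  if (end > length(idx))
    stop("pattern probes exceed track extent on ", chr, call. = FALSE)
  list(chromosome = chr,
       bp_start = track$position_bp[idx[start]],
       bp_stop = track$position_bp[idx[end]])
}

#' Fraction of matrix cells covered by patterns
#'
#' The union of all pattern cells (probe x supporting sample, unioned
#' within each direction so overlapping patterns count once) divided by the
#' total number of cells `m * n`.
#'
#' @param patterns pattern data frame.
#' @param m,n probe and sample counts of the mined matrix.
#' @return Fraction in [0, 1] (per direction summed; directions are
#'   disjoint by construction when mined from one intensity matrix).
#' @export
pattern_density <- function(patterns, m, n) {
  if (nrow(patterns) == 0L) return(0)
  covered <- 0L
  for (dir in unique(patterns$direction)) {
    sub <- patterns[patterns$direction == dir, , drop = FALSE]
    cells <- unique(unlist(lapply(seq_len(nrow(sub)), function(i)
      pattern_cells(sub$start[i], sub$end[i], sub$support_set[[i]]))))
    covered <- covered + length(cells)
  }
  covered / (m * n)
}
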