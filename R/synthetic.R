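# run expr with a temporary RNG state so generators are pure functions of
# their seed and never disturb the caller's random stream
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of one implanted aberrant region
#'
#' Describes a ground-truth CNV event to implant in a synthetic cohort: a
#' consecutive probe interval carried by a random sample subset. In binary
#' mode each implanted cell is 1 with probability `presence_prob` (flip-out
#' noise); in continuous mode each implanted cell is shifted by
#' `shift_mean` log-ratio units (sign by direction) with Gaussian jitter
#' `shift_sd`.
#'
#' Defaults emulate a clean single-copy event on a SNP array: 90% per-cell
#' presence, a 0.5 log-ratio shift with 0.1 jitter.
#'
#' @param start,end 1-based inclusive probe interval.
#' @param sample_fraction fraction of samples carrying the event; at least
#'   one sample must result.
#' @param direction `"gain"` or `"loss"`.
#' @param presence_prob per-cell presence probability in (0, 1].
#' @param shift_mean,shift_sd continuous-mode shift magnitude (log-ratio
#'   units) and jitter standard deviation.
#' @return An `implant_spec` list.
#' @export
implant_spec <- function(start, end, sample_fraction,
                         direction = c("gain", "loss"),
                         presence_prob = 0.9,
                         shift_mean = 0.5, shift_sd = 0.1) {
  direction <- match.arg(direction)
  if (start < 1L || end < start) stop("invalid implant interval", call. = FALSE)
  if (sample_fraction <= 0 || sample_fraction > 1)
    stop("`sample_fraction` must be in (0, 1]", call. = FALSE)
  if (presence_prob <= 0 || presence_prob > 1)
    stop("`presence_prob` must be in (0, 1]", call. = FALSE)
  if (shift_sd < 0) stop("`shift_sd` must be non-negative", call. = FALSE)
  structure(list(start = as.integer(start), end = as.integer(end),
                 sample_fraction = sample_fraction, direction = direction,
                 presence_prob = presence_prob, shift_mean = shift_mean,
                 shift_sd = shift_sd),
            class = "implant_spec")
}

draw_implant_samples <- function(implants, n) {
  lapply(implants, function(sp) {
    k <- max(1L, round(sp$sample_fraction * n))
    sort(sample.int(n, k))
  })
}

#' Generate a sparse binary cohort with implanted blocks
#'
#' Background cells are i.i.d. Bernoulli(`background_density`); each
#' implant's sample subset is drawn uniformly without replacement and its
#' cells are set to Bernoulli(`presence_prob`), overwriting the background.
#' Cells covered by several implants are 1 if any implant realizes them
#' (OR). Fully reproducible from `seed`.
#'
#' @param m,n probe and sample counts.
#' @param background_density background 1-density in [0, 1). The default
#'   0.02 emulates scattered spurious CNV calls well below a typical 10%
#'   genome-wide CNV density concentrated in real events.
#' @param implants list of [implant_spec()] objects with intervals inside
#'   `[1, m]`.
#' @param seed integer seed.
#' @param direction direction label of the returned matrix.
#' @return A list with `matrix` (a [binary_matrix()]) and `truth` (a
#'   `cohort_truth` list: `implants` with their realized `samples`,
#'   `background_density`, `seed`).
#' @export
generate_binary_cohort <- function(m, n, background_density = 0.02,
                                   implants = list(), seed,
                                   direction = "gain") {
  if (background_density < 0 || background_density >= 1)
    stop("`background_density` must be in [0, 1)", call. = FALSE)
  if (inherits(implants, "implant_spec")) implants <- list(implants)
  for (sp in implants)
    if (sp$end > m) stop("implant interval exceeds probe count", call. = FALSE)
  with_seed(seed, {
    cells <- matrix(rbinom(m * n, 1L, background_density), m, n)
    sets <- draw_implant_samples(implants, n)
    covered <- matrix(FALSE, m, n)
    impl <- matrix(0L, m, n)
    for (i in seq_along(implants)) {
      sp <- implants[[i]]
      rows <- sp$start:sp$end
      draw <- matrix(rbinom(length(rows) * length(sets[[i]]), 1L,
                            sp$presence_prob),
                     length(rows), length(sets[[i]]))
      impl[rows, sets[[i]]] <- pmax(impl[rows, sets[[i]]], draw)
      covered[rows, sets[[i]]] <- TRUE
    }
    cells[covered] <- impl[covered]
    truth <- structure(list(
      implants = Map(function(sp, s) c(sp, list(samples = s)),
                     implants, sets),
      background_density = background_density, seed = seed),
      class = "cohort_truth")
    list(matrix = binary_matrix(cells, direction = direction), truth = truth)
  })
}

#' Generate a continuous log-ratio cohort with implanted shifts
#'
#' Background cells are N(0, `noise_sd`^2), emulating log R ratio noise
#' around normal copy number; implanted cells additionally receive a shift
#' of `+shift_mean` (gain) or `-shift_mean` (loss) with N(0, `shift_sd`^2)
#' jitter, drawn independently per cell. Overlapping implants add their
#' shifts.
#'
#' @param m,n probe and sample counts.
#' @param noise_sd background noise standard deviation (log-ratio units;
#'   default 0.15, a typical array LRR noise level).
#' @param implants list of [implant_spec()] objects.
#' @param seed integer seed.
#' @return A list with `matrix` (an [intensity_matrix()]) and `truth` as in
#'   [generate_binary_cohort()].
#' @export
generate_intensity_cohort <- function(m, n, noise_sd = 0.15,
                                      implants = list(), seed) {
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  if (inherits(implants, "implant_spec")) implants <- list(implants)
  for (sp in implants)
    if (sp$end > m) stop("implant interval exceeds probe count", call. = FALSE)
  with_seed(seed, {
    values <- matrix(rnorm(m * n, 0, noise_sd), m, n)
    sets <- draw_implant_samples(implants, n)
    for (i in seq_along(implants)) {
      sp <- implants[[i]]
      rows <- sp$start:sp$end
      sign <- if (sp$direction == "gain") 1 else -1
      shift <- matrix(rnorm(length(rows) * length(sets[[i]]),
                            sign * sp$shift_mean, sp$shift_sd),
                      length(rows), length(sets[[i]]))
      values[rows, sets[[i]]] <- values[rows, sets[[i]]] + shift
    }
    truth <- structure(list(
      implants = Map(function(sp, s) c(sp, list(samples = s)),
                     implants, sets),
      noise_sd = noise_sd, seed = seed),
      class = "cohort_truth")
    list(matrix = intensity_matrix(values), truth = truth)
  })
}

#' Toy worked example
#'
#' A small 7-probe x 10-sample binary matrix, reconstructed so that the
#' level-wise search exercises every branch of the algorithm at
#' `sup_min = 0.5`, `epsilon = 0.2`, `delta = 0.4`:
#'
#' * probe 1 is carried by 4 of 10 samples (support 0.4) and is pruned at
#'   round 1;
#' * probes 2-5 share the identical 5-sample support set and merge into the
#'   maximal pattern `[2, 5]`;
#' * probe 6 is carried by all samples (support 1.0) and probe 7 by a nested
#'   5-sample subset (support 0.5); their candidate union has weak support
#'   0.8 at `epsilon = 0.2`, yet the merge is rejected because the support
#'   sets have dissimilarity 0.5 > `delta`, so probes 6 and 7 are reported
#'   individually.
#'
#' This is a reconstruction built to those support values, useful as a
#' deterministic fixture for tests and CLI demonstrations.
#'
#' @return A list with `matrix` (a [binary_matrix()]) and `params` (a
#'   [mining_params()] with `sup_min = 0.5`, `epsilon = 0.2`,
#'   `delta = 0.4`).
#' @export
toy_cohort <- function() {
  cells <- rbind(
    c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),  # probe 1: support 0.4, pruned
    c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
    c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
    c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
    c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),  # probes 2-5: identical sets, merge
    c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1),  # probe 6: support 1.0
    c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0))  # probe 7: support 0.5, nested in 6
  track <- probe_track(paste0("i", 1:7), "chr1",
                       seq(1000L, by = 1000L, length.out = 7L))
  list(matrix = binary_matrix(cells, track = track, direction = "gain"),
       params = mining_params(sup_min = 0.5, epsilon = 0.2, delta = 0.4))
}

pattern_cells <- function(start, end, samples) {
  # linearized probe x sample cell ids for set arithmetic
  as.vector(outer(start:end, (samples - 1) * 1e7, `+`))
}

#' Score recovery of implanted regions by mined patterns
#'
#' For each implanted region, computes the best Jaccard index between its
#' realized cell set (probe interval x realized samples) and the cell set
#' of any reported pattern of the same direction. Summaries: `recall` is
#' the fraction of implants recovered at Jaccard >= `threshold`,
#' `precision` the fraction of patterns matching some implant at that
#' level, and `f1` their harmonic mean.
#'
#' @param patterns pattern data frame (from [mine_chromosome()] /
#'   [mine_cnv()]'s `$patterns`).
#' @param truth `cohort_truth` from a generator.
#' @param threshold Jaccard level counting as recovered (default 0.8).
#' @return A list with `per_implant` (best Jaccard per implant), `recall`,
#'   `precision`, `f1`, `mean_jaccard`.
#' @export
recovery_score <- function(patterns, truth, threshold = 0.8) {
  stopifnot(inherits(truth, "cohort_truth"))
  imp_cells <- lapply(truth$implants, function(im)
    pattern_cells(im$start, im$end, im$samples))
  pat_cells <- lapply(seq_len(nrow(patterns)), function(i)
    pattern_cells(patterns$start[i], patterns$end[i],
                  patterns$support_set[[i]]))
  jac <- function(a, b)
    length(intersect(a, b)) / length(union(a, b))
  best <- vapply(seq_along(imp_cells), function(i) {
    same_dir <- which(patterns$direction ==
                        truth$implants[[i]]$direction)
    if (length(same_dir) == 0L) return(0)
    max(vapply(pat_cells[same_dir], jac, numeric(1), imp_cells[[i]]))
  }, numeric(1))
  pat_best <- vapply(seq_along(pat_cells), function(j) {
    same_dir <- which(vapply(truth$implants, `[[`, character(1),
                             "direction") == patterns$direction[j])
    if (length(same_dir) == 0L) return(0)
    max(vapply(imp_cells[same_dir], jac, numeric(1), pat_cells[[j]]))
  }, numeric(1))
  recall <- if (length(best)) mean(best >= threshold) else NA_real_
  precision <- if (length(pat_best)) mean(pat_best >= threshold) else
    NA_real_
  f1 <- if (isTRUE(recall + precision > 0))
    2 * precision * recall / (precision + recall) else 0
  list(per_implant = best, recall = recall, precision = precision, f1 = f1,
       mean_jaccard = if (length(best)) mean(best) else NA_real_)
}
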