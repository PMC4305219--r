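#' Probe annotation track
#'
#' Positional annotation for the probe (row) dimension of an intensity or
#' binary matrix: probe identifiers, chromosome labels and base-pair
#' coordinates. Within each chromosome, probes must appear in genomic order
#' (non-decreasing base-pair position); the interval constraint of the miner
#' is meaningless on unsorted probes, so disorder is an error, not a warning.
#'
#' @param probe_ids character vector of unique probe identifiers.
#' @param chromosome chromosome label per probe (recycled if length 1).
#' @param position_bp non-negative integer base-pair coordinate per probe,
#'   1-based as in standard array annotation files.
#' @return A `probe_track` object (a data frame with columns `probe_id`,
#'   `chromosome`, `position_bp`).
#' @examples
#' probe_track(paste0("p", 1:4), "chr1", c(100L, 200L, 350L, 900L))
#' @export
probe_track <- function(probe_ids, chromosome, position_bp) {
  probe_ids <- as.character(probe_ids)
  chromosome <- rep_len(as.character(chromosome), length(probe_ids))
  position_bp <- as.numeric(position_bp)
  if (length(position_bp) != length(probe_ids))
    stop("`position_bp` must have one entry per probe", call. = FALSE)
  if (anyDuplicated(probe_ids))
    stop("duplicate probe IDs: ", probe_ids[duplicated(probe_ids)][1L],
         call. = FALSE)
  if (any(!is.finite(position_bp)) || any(position_bp < 0))
    stop("`position_bp` must be finite and non-negative", call. = FALSE)
  for (chr in unique(chromosome)) {
    pos <- position_bp[chromosome == chr]
    if (is.unsorted(pos))
      stop("probes on ", chr, " are not in genomic order; sort the input ",
           "before mining", call. = FALSE)
  }
  structure(
    data.frame(probe_id = probe_ids, chromosome = chromosome,
               position_bp = position_bp, stringsAsFactors = FALSE),
    class = c("probe_track", "data.frame"))
}

#' Continuous CNV intensity matrix
#'
#' Container for a probes x samples matrix of log intensity ratios (LRR):
#' each entry is the log ratio of a sample's hybridization intensity to a
#' reference, so values near 0 indicate normal copy number, positive values
#' candidate gains and negative values candidate losses.
#'
#' @param values numeric matrix, probes in rows, samples in columns. All
#'   entries must be finite: missing values must be imputed or the probes
#'   dropped before construction (silent imputation would corrupt support
#'   counts downstream).
#' @param sample_ids sample identifiers; defaults to `colnames(values)` or
#'   `s1..sn`.
#' @param track optional [probe_track()] of length `nrow(values)`. When
#'   absent, all probes are placed on a single unnamed chromosome at their
#'   index position.
#' @return An `intensity_matrix` object.
#' @export
intensity_matrix <- function(values, sample_ids = NULL, track = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("intensity matrix must have at least one probe and one sample",
         call. = FALSE)
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf(
      "non-finite intensity at probe %d, sample %d; impute or drop missing values first",
      bad[1L, 1L], bad[1L, 2L]), call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- colnames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != ncol(values))
    stop("`sample_ids` length must equal the number of columns", call. = FALSE)
  if (is.null(track)) {
    ids <- rownames(values)
    if (is.null(ids)) ids <- paste0("p", seq_len(nrow(values)))
    track <- probe_track(ids, "chrU", seq_len(nrow(values)))
  }
  if (!inherits(track, "probe_track"))
    stop("`track` must be a probe_track", call. = FALSE)
  if (nrow(track) != nrow(values))
    stop("track length (", nrow(track), ") does not match probe count (",
         nrow(values), ")", call. = FALSE)
  dimnames(values) <- list(track$probe_id, sample_ids)
  structure(list(values = values, sample_ids = sample_ids, track = track),
            class = "intensity_matrix")
}

#' Binary CNV indicator matrix
#'
#' Probes x samples 0/1 matrix marking candidate CNV cells for one direction
#' (gain or loss). This is the transaction format the miner consumes: probes
#' are items, samples are transactions. Gain and loss matrices derived from
#' the same intensity matrix are cell-wise disjoint because a finite value
#' cannot exceed `tau` and fall below `-tau` at once.
#'
#' @param cells matrix of 0/1 values, probes in rows.
#' @param sample_ids,track as in [intensity_matrix()].
#' @param direction `"gain"` or `"loss"`.
#' @return A `binary_matrix` object.
#' @export
binary_matrix <- function(cells, sample_ids = NULL, track = NULL,
                          direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  cells <- as.matrix(cells)
  if (nrow(cells) < 1L || ncol(cells) < 1L)
    stop("binary matrix must have at least one probe and one sample",
         call. = FALSE)
  if (!all(cells %in% c(0, 1)))
    stop("binary matrix entries must be 0 or 1", call. = FALSE)
  storage.mode(cells) <- "integer"
  if (is.null(sample_ids)) sample_ids <- colnames(cells)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(cells)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != ncol(cells))
    stop("`sample_ids` length must equal the number of columns", call. = FALSE)
  if (is.null(track)) {
    ids <- rownames(cells)
    if (is.null(ids)) ids <- paste0("p", seq_len(nrow(cells)))
    track <- probe_track(ids, "chrU", seq_len(nrow(cells)))
  }
  if (nrow(track) != nrow(cells))
    stop("track length does not match probe count", call. = FALSE)
  dimnames(cells) <- list(track$probe_id, sample_ids)
  structure(list(cells = cells, sample_ids = sample_ids, track = track,
                 direction = direction),
            class = "binary_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d probes x %d samples, %d chromosome(s)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$track$chromosome))))
  invisible(x)
}

#' @export
print.binary_matrix <- function(x, ...) {
  cat(sprintf(
    "binary_matrix (%s): %d probes x %d samples, density %.4f\n",
    x$direction, nrow(x$cells), ncol(x$cells), mean(x$cells)))
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' @export
dim.binary_matrix <- function(x) dim(x$cells)

#' Binarize a CNV intensity matrix
#'
#' Thresholds log intensity ratios into the 0/1 transaction matrix mined for
#' one direction: a cell is a candidate gain when its value is strictly
#' greater than `tau`, a candidate loss when strictly less than `-tau`.
#' Values exactly at the threshold stay 0. Gains and losses are binarized
#' and mined separately.
#'
#' @param x an [intensity_matrix()].
#' @param tau non-negative threshold on the log intensity ratio. The value
#'   0.192 used for 500k SNP-array LRR data (chosen so that roughly 10% of
#'   entries are candidate CNVs) is a typical order of magnitude; use
#'   [select_tau()] to derive `tau` from a target density.
#' @param direction `"gain"` or `"loss"`.
#' @return A [binary_matrix()] with the same dimensions and annotation.
#' @seealso [select_tau()]
#' @examples
#' x <- intensity_matrix(matrix(c(0.25, -0.3, 0.05, 0), 2, 2))
#' binarize(x, tau = 0.192, direction = "gain")$cells
#' binarize(x, tau = 0.192, direction = "loss")$cells
#' @export
binarize <- function(x, tau, direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  if (!inherits(x, "intensity_matrix"))
    stop("`x` must be an intensity_matrix", call. = FALSE)
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau < 0)
    stop("`tau` must be a single non-negative number", call. = FALSE)
  cells <- if (direction == "gain") (x$values > tau) else (x$values < -tau)
  binary_matrix(cells + 0L, x$sample_ids, x$track, direction)
}

#' Choose a binarization threshold from a target CNV density
#'
#' Picks `tau` as the empirical `(1 - target_density)` quantile of the
#' absolute log ratios pooled over the whole matrix, so that the fraction of
#' cells flagged as candidate CNV (gain plus loss together) is at most
#' `target_density` and as close to it as ties at the threshold allow. A
#' single global quantile is used rather than per-probe or per-sample
#' thresholds, matching the practice of fixing one genome-wide CNV sparsity
#' level (e.g. 10%).
#'
#' @param x an [intensity_matrix()].
#' @param target_density desired fraction of cells exceeding the threshold,
#'   in (0, 1).
#' @return `tau` (numeric scalar) with attribute `achieved_density`, the
#'   realized fraction of entries with `|value| > tau`.
#' @examples
#' x <- intensity_matrix(matrix(c(-3, -1, 0, 1, 3), 1))
#' select_tau(x, 0.4)  # tau = 1, achieved density 0.4
#' @export
select_tau <- function(x, target_density) {
  if (!inherits(x, "intensity_matrix"))
    stop("`x` must be an intensity_matrix", call. = FALSE)
  if (!is.numeric(target_density) || length(target_density) != 1L ||
      target_density <= 0 || target_density >= 1)
    stop("`target_density` must be in (0, 1)", call. = FALSE)
  av <- sort(abs(as.vector(x$values)), decreasing = TRUE)
  mn <- length(av)
  if (av[1L] == av[mn]) {
    warning("all |values| identical; no threshold separates any cells",
            call. = FALSE)
    tau <- av[1L]
    return(structure(tau, achieved_density = 0))
  }
  k <- floor(target_density * mn + 1e-9)  # at most k cells may exceed tau
  tau <- if (k >= mn) av[mn] else av[k + 1L]
  structure(tau, achieved_density = sum(av > tau) / mn)
}
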