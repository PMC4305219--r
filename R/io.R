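#' Read a per-chromosome binary CNV file
#'
#' Parses the tab- or whitespace-delimited binary ("chr_data") dialect: one
#' row per probe, first column the probe ID, remaining columns 0/1 cells,
#' with an optional first header line of sample IDs. The header is
#' auto-detected: it is taken to be present when the second token of the
#' first line is not a number. Probe order in the file is genomic order and
#' is preserved.
#'
#' @param path file path.
#' @param chromosome chromosome label to attach (default: the file name
#'   without extension).
#' @param direction direction label of the matrix.
#' @param positions optional base-pair positions per probe; defaults to the
#'   probe index.
#' @return A [binary_matrix()].
#' @export
read_chr_data <- function(path, chromosome = NULL,
                          direction = c("gain", "loss"), positions = NULL) {
  direction <- match.arg(direction)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop("empty file: ", path, call. = FALSE)
  toks <- strsplit(trimws(lines), "[ \t]+")
  has_header <- length(toks[[1L]]) >= 2L &&
    is.na(suppressWarnings(as.numeric(toks[[1L]][2L])))
  sample_ids <- NULL
  if (has_header) {
    hdr <- toks[[1L]]
    # header may or may not carry a leading probe-ID column name
    sample_ids <- if (length(toks) > 1L &&
                      length(hdr) == length(toks[[2L]])) hdr[-1L] else hdr
    toks <- toks[-1L]
    if (length(toks) == 0L) stop("no data rows in ", path, call. = FALSE)
  }
  ncol_expect <- length(toks[[1L]])
  rows <- vector("list", length(toks))
  ids <- character(length(toks))
  for (i in seq_along(toks)) {
    line_no <- i + has_header
    tk <- toks[[i]]
    if (length(tk) != ncol_expect)
      stop(sprintf("%s: line %d has %d fields, expected %d", path, line_no,
                   length(tk), ncol_expect), call. = FALSE)
    ids[i] <- tk[1L]
    v <- suppressWarnings(as.numeric(tk[-1L]))
    if (any(is.na(v)) || !all(v %in% c(0, 1)))
      stop(sprintf("%s: line %d contains a non-binary entry", path, line_no),
           call. = FALSE)
    rows[[i]] <- as.integer(v)
  }
  if (anyDuplicated(ids))
    stop(sprintf("%s: duplicate probe ID '%s'", path,
                 ids[duplicated(ids)][1L]), call. = FALSE)
  cells <- do.call(rbind, rows)
  if (!is.null(sample_ids) && length(sample_ids) != ncol(cells))
    stop(path, ": header sample count does not match data columns",
         call. = FALSE)
  if (is.null(chromosome))
    chromosome <- sub("\\.[^.]*$", "", basename(path))
  if (is.null(positions)) positions <- seq_len(nrow(cells))
  binary_matrix(cells, sample_ids,
                probe_track(ids, chromosome, positions), direction)
}

#' Read a continuous intensity matrix file
#'
#' Same layout as [read_chr_data()] but with real-valued log intensity
#' ratios in the cells: first column probe ID, optional auto-detected
#' header of sample IDs, tab- or whitespace-delimited.
#'
#' @param path file path.
#' @param track optional [probe_track()] giving chromosome and position per
#'   probe; matched by probe ID. Without it, probes are placed on one
#'   chromosome named after the file, at index positions.
#' @return An [intensity_matrix()].
#' @export
read_intensity_data <- function(path, track = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop("empty file: ", path, call. = FALSE)
  toks <- strsplit(trimws(lines), "[ \t]+")
  has_header <- length(toks[[1L]]) >= 2L &&
    is.na(suppressWarnings(as.numeric(toks[[1L]][2L])))
  sample_ids <- NULL
  if (has_header) {
    hdr <- toks[[1L]]
    sample_ids <- if (length(toks) > 1L &&
                      length(hdr) == length(toks[[2L]])) hdr[-1L] else hdr
    toks <- toks[-1L]
    if (length(toks) == 0L) stop("no data rows in ", path, call. = FALSE)
  }
  ncol_expect <- length(toks[[1L]])
  ids <- vapply(toks, `[[`, character(1), 1L)
  rows <- lapply(seq_along(toks), function(i) {
    tk <- toks[[i]]
    if (length(tk) != ncol_expect)
      stop(sprintf("%s: line %d has %d fields, expected %d", path,
                   i + has_header, length(tk), ncol_expect), call. = FALSE)
    v <- suppressWarnings(as.numeric(tk[-1L]))
    if (any(is.na(v)))
      stop(sprintf("%s: line %d contains a non-numeric entry", path,
                   i + has_header), call. = FALSE)
    v
  })
  values <- do.call(rbind, rows)
  rownames(values) <- ids
  if (!is.null(track)) {
    idx <- match(ids, track$probe_id)
    if (anyNA(idx))
      stop(path, ": probe ", ids[which(is.na(idx))[1L]],
           " absent from probe track", call. = FALSE)
    track <- probe_track(ids, track$chromosome[idx],
                         track$position_bp[idx])
  } else {
    track <- probe_track(ids, sub("\\.[^.]*$", "", basename(path)),
                         seq_along(ids))
  }
  intensity_matrix(values, sample_ids, track)
}

#' Write a binary matrix in the per-chromosome dialect
#'
#' Inverse of [read_chr_data()]: a header line of sample IDs, then one
#' tab-separated row per probe (probe ID first, 0/1 cells after), newline
#' line endings regardless of platform.
#'
#' @param B a [binary_matrix()].
#' @param path output file path or connection.
#' @return Invisibly, `path`.
#' @export
write_chr_data <- function(B, path) {
  stopifnot(inherits(B, "binary_matrix"))
  lines <- c(paste(c("probe_id", B$sample_ids), collapse = "\t"),
             vapply(seq_len(nrow(B$cells)), function(i)
               paste(c(B$track$probe_id[i], B$cells[i, ]), collapse = "\t"),
               character(1)))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Read a probe position table
#'
#' Tab-delimited, three columns: probe ID, chromosome, base-pair position.
#' A header line is auto-detected (third token non-numeric).
#'
#' @param path file path.
#' @return A [probe_track()].
#' @export
read_probe_track <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  toks <- strsplit(trimws(lines), "[ \t]+")
  if (length(toks[[1L]]) < 3L)
    stop(path, ": expected columns probe_id, chromosome, position_bp",
         call. = FALSE)
  if (is.na(suppressWarnings(as.numeric(toks[[1L]][3L])))) toks <- toks[-1L]
  probe_track(vapply(toks, `[[`, character(1), 1L),
              vapply(toks, `[[`, character(1), 2L),
              as.numeric(vapply(toks, `[[`, character(1), 3L)))
}

#' Read sample group labels
#'
#' Tab-delimited, two columns: sample ID, group label; optional auto-
#' detected header.
#'
#' @param path file path.
#' @param sample_ids if given, labels are returned in this sample order and
#'   every sample must be labeled exactly once.
#' @return Named character vector of group labels.
#' @export
read_group_labels <- function(path, sample_ids = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  toks <- strsplit(trimws(lines), "[ \t]+")
  if (tolower(toks[[1L]][1L]) %in% c("sample", "sample_id", "id"))
    toks <- toks[-1L]
  ids <- vapply(toks, `[[`, character(1), 1L)
  grp <- vapply(toks, `[[`, character(1), 2L)
  if (anyDuplicated(ids))
    stop(path, ": duplicate sample ID", call. = FALSE)
  names(grp) <- ids
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, ids)
    if (length(missing) > 0L)
      stop(path, ": no group label for sample ", missing[1L], call. = FALSE)
    grp <- grp[sample_ids]
  }
  grp
}

pattern_output_version <- "cnvminer-patterns/1"

#' Write mined patterns as text
#'
#' One line per pattern, tab-separated: chromosome, direction, start probe
#' index, end probe index, size, support count, support fraction (6 decimal
#' places), comma-separated supporting sample indices in ascending order.
#' Probe and sample indices are written 0-based (the header comment states
#' the convention; in-memory objects are 1-based). Patterns are ordered by
#' (chromosome, start, end, direction) and the output is byte-identical
#' across runs and platforms (newline endings only).
#'
#' @param x a `cnv_patterns` object or pattern data frame.
#' @param path file path or connection (default standard output).
#' @return Invisibly, the formatted lines.
#' @export
write_patterns <- function(x, path = stdout()) {
  pat <- if (inherits(x, "cnv_patterns")) x$patterns else x
  header <- c(
    paste0("# ", pattern_output_version),
    "# chromosome direction start end size support_count support sample_indices",
    "# probe and sample indices are 0-based; intervals inclusive")
  if (nrow(pat) > 0L) {
    ord <- order(pat$chromosome, pat$start, pat$end, pat$direction,
                 method = "radix")
    pat <- pat[ord, , drop = FALSE]
    body <- vapply(seq_len(nrow(pat)), function(i) paste(
      pat$chromosome[i], pat$direction[i], pat$start[i] - 1L,
      pat$end[i] - 1L, pat$size[i], pat$support_count[i],
      sprintf("%.6f", pat$support[i]),
      paste(sort(pat$support_set[[i]]) - 1L, collapse = ","),
      sep = "\t"), character(1))
  } else body <- character(0)
  writeLines(c(header, body), path, sep = "\n")
  invisible(c(header, body))
}

#' Read patterns written by [write_patterns()]
#'
#' @param path file path or connection.
#' @return A pattern data frame with 1-based indices (round-trip inverse of
#'   [write_patterns()]).
#' @export
read_patterns <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty_pattern_frame())
  toks <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    chromosome = vapply(toks, `[[`, character(1), 1L),
    direction = vapply(toks, `[[`, character(1), 2L),
    start = as.integer(vapply(toks, `[[`, character(1), 3L)) + 1L,
    end = as.integer(vapply(toks, `[[`, character(1), 4L)) + 1L,
    size = as.integer(vapply(toks, `[[`, character(1), 5L)),
    support_count = as.integer(vapply(toks, `[[`, character(1), 6L)),
    support = as.numeric(vapply(toks, `[[`, character(1), 7L)),
    support_set = I(lapply(toks, function(tk)
      as.integer(strsplit(tk[[8L]], ",", fixed = TRUE)[[1L]]) + 1L)),
    stringsAsFactors = FALSE)
}
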