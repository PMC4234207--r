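#' Read a FASTA file into a tibble
#'
#' Reads records in file order, uppercases sequences and validates them
#' against the IUPAC DNA alphabet. Structural problems (a sequence line
#' before any header, an empty record) are reported with the offending line
#' number.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   the header) and `seq`.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines) | grepl("^>", lines)
  header_at <- grepl("^>", lines)
  if (length(lines) == 0L || !any(header_at)) {
    stop(sprintf("%s: no FASTA records found", path), call. = FALSE)
  }
  first_content <- which(keep & !header_at)
  if (length(first_content) && first_content[1] < which(header_at)[1]) {
    stop(sprintf("%s: sequence data before first header at line %d",
                 path, first_content[1]), call. = FALSE)
  }
  rec_idx <- cumsum(header_at)
  ids <- sub("^>\\s*", "", lines[header_at])
  ids <- sub("\\s.*$", "", ids)
  if (any(ids == "")) {
    ln <- which(header_at)[ids == ""][1]
    stop(sprintf("%s: malformed header at line %d", path, ln), call. = FALSE)
  }
  body <- lines[!header_at & keep]
  body_rec <- rec_idx[!header_at & keep]
  seqs <- vapply(seq_along(ids), function(i) {
    paste(body[body_rec == i], collapse = "")
  }, character(1))
  empty <- seqs == ""
  if (any(empty)) {
    ln <- which(header_at)[empty][1]
    stop(sprintf("%s: empty record '%s' at line %d", path, ids[empty][1], ln),
         call. = FALSE)
  }
  seqs <- toupper(gsub("\\s", "", seqs))
  assert_iupac(seqs, what = sprintf("FASTA file %s", path))
  tibble::tibble(id = ids, seq = seqs)
}

#' Write sequences to FASTA
#'
#' @param x A data frame with columns `id` and `seq` (e.g. a peak tibble).
#' @param path Output path.
#' @param wrap Line width for sequence wrapping; `Inf` writes one line per
#'   record.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, wrap = 70) {
  stopifnot(all(c("id", "seq") %in% names(x)))
  out <- unlist(purrr::map2(x$id, x$seq, function(id, s) {
    if (is.finite(wrap) && nchar(s) > wrap) {
      starts <- seq(1L, nchar(s), by = wrap)
      s <- substring(s, starts, pmin(starts + wrap - 1L, nchar(s)))
    }
    c(paste0(">", id), s)
  }))
  writeLines(out, path)
  invisible(path)
}

#' Read a ChIP-Seq peak table and join sequences from a FASTA file
#'
#' Accepts either a headered TSV with at least `id` and `height` columns
#' (optionally `chrom`, `start`, `end`) or a headerless BED6+1 file whose
#' 7th column is the peak height (read coverage). Coordinates are 0-based
#' half-open throughout.
#'
#' @param table_path Path to the peak table.
#' @param fasta_path Path to the companion FASTA; every table id must be
#'   present.
#' @return A peak tibble with columns `id`, `seq`, `height` and, when
#'   available, `chrom`, `start`, `end`.
#' @export
read_peak_table <- function(table_path, fasta_path) {
  first <- readLines(table_path, n = 1L)
  if (grepl("\\bid\\b", first) && grepl("\\bheight\\b", first)) {
    tab <- readr::read_tsv(table_path, show_col_types = FALSE, progress = FALSE)
  } else {
    tab <- readr::read_tsv(table_path,
                           col_names = c("chrom", "start", "end", "id",
                                         "score", "strand", "height"),
                           show_col_types = FALSE, progress = FALSE)
    tab <- dplyr::select(tab, "id", "chrom", "start", "end", "height")
  }
  if (!all(c("id", "height") %in% names(tab))) {
    stop("peak table must provide 'id' and 'height' columns", call. = FALSE)
  }
  tab$height <- as.numeric(tab$height)
  if (anyNA(tab$height) || any(tab$height < 0)) {
    stop("peak heights must be non-negative numbers", call. = FALSE)
  }
  fa <- read_fasta(fasta_path)
  missing <- setdiff(tab$id, fa$id)
  if (length(missing)) {
    stop(sprintf("peak ids missing from FASTA: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- dplyr::left_join(tab, fa, by = "id")
  if (all(c("start", "end") %in% names(out))) {
    bad <- !is.na(out$start) & (out$end - out$start != nchar(out$seq))
    if (any(bad)) {
      stop(sprintf("end - start does not match sequence length for: %s",
                   paste(out$id[bad], collapse = ", ")), call. = FALSE)
    }
  }
  dplyr::relocate(tibble::as_tibble(out), "id", "seq", "height")
}

#' Write a peak tibble as BED6+1
#'
#' Column 7 carries the peak height. Peaks without coordinates are written
#' on a placeholder chromosome `.` with `start = 0`.
#'
#' @param peaks A peak tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  chrom <- if ("chrom" %in% names(peaks)) peaks$chrom else rep(".", nrow(peaks))
  start <- if ("start" %in% names(peaks)) peaks$start else rep(0L, nrow(peaks))
  end <- if ("end" %in% names(peaks)) peaks$end else start + nchar(peaks$seq)
  out <- data.frame(chrom = chrom, start = start, end = end, id = peaks$id,
                    score = 0L, strand = ".", height = peaks$height)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BED3/BED6 interval file
#'
#' @param path Path to a BED file (0-based half-open).
#' @return A tibble with columns `chrom`, `start`, `end` and, for BED6,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  tab <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)
  nms <- c("chrom", "start", "end", "name", "score", "strand")
  names(tab) <- nms[seq_len(min(ncol(tab), 6L))]
  if (any(tab$start >= tab$end)) {
    stop("intervals must satisfy start < end", call. = FALSE)
  }
  tibble::as_tibble(tab)
}

#' Filter peaks by minimum read coverage
#'
#' Retains peaks whose summary coverage (`height`) is at least `min_height`,
#' preserving input order. Typical cut-offs in FoxA2 ChIP-Seq studies are 15
#' (mouse liver) and 10 (human HepG2).
#'
#' @param peaks A peak tibble with a `height` column.
#' @param min_height Non-negative threshold.
#' @return The filtered peak tibble.
#' @export
filter_peaks_by_height <- function(peaks, min_height) {
  stopifnot(min_height >= 0)
  dplyr::filter(peaks, .data$height >= min_height)
}

#' Keep peaks overlapping a set of genomic intervals
#'
#' Half-open interval semantics: a peak is kept when it shares at least one
#' base with any interval (e.g. 1 kb upstream promoter windows).
#'
#' @param peaks A peak tibble carrying `chrom`, `start`, `end`.
#' @param intervals A tibble with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [read_bed()].
#' @return The subset of `peaks` overlapping at least one interval.
#' @export
overlap_filter <- function(peaks, intervals) {
  if (!all(c("chrom", "start", "end") %in% names(peaks)) ||
      anyNA(peaks$start) || anyNA(peaks$end)) {
    stop("peaks must carry chrom/start/end coordinates", call. = FALSE)
  }
  if (nrow(intervals) == 0L) return(peaks[0, ])
  pk <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L, peaks$end))
  iv <- GenomicRanges::GRanges(intervals$chrom,
                               IRanges::IRanges(intervals$start + 1L,
                                                intervals$end))
  hit <- GenomicRanges::countOverlaps(pk, iv, minoverlap = 1L) > 0L
  peaks[hit, ]
}
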