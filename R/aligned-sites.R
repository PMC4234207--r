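#' Construct an aligned binding-site set
#'
#' A fixed-width alignment of confirmed binding sites, anchored on a core
#' consensus (the FoxA training set, for example, is aligned on TRTTTRYH).
#'
#' @param seqs Character vector of equal-width ACGT strings.
#' @param core_offset 0-based offset of the core within each sequence.
#' @param core_len Length of the core pattern.
#' @return A tibble of class `aligned_sites` with one `seq` column and
#'   attributes `width`, `core_offset`, `core_len`.
#' @export
aligned_sites <- function(seqs, core_offset = 0L, core_len = nchar(seqs[1])) {
  stopifnot(length(seqs) >= 1L)
  seqs <- toupper(seqs)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    stop("all aligned sites must have equal width", call. = FALSE)
  }
  if (any(grepl("[^ACGT]", seqs))) {
    stop("aligned sites must be over {A,C,G,T}", call. = FALSE)
  }
  width <- widths[1]
  stopifnot(core_offset >= 0L, core_offset + core_len <= width)
  out <- tibble::tibble(seq = seqs)
  attr(out, "width") <- as.integer(width)
  attr(out, "core_offset") <- as.integer(core_offset)
  attr(out, "core_len") <- as.integer(core_len)
  class(out) <- c("aligned_sites", class(out))
  out
}

#' @export
print.aligned_sites <- function(x, ...) {
  cat(sprintf("<aligned_sites> %d sites, width %d, core [%d, %d)\n",
              nrow(x), attr(x, "width"), attr(x, "core_offset"),
              attr(x, "core_offset") + attr(x, "core_len")))
  NextMethod()
}

#' Trim an alignment symmetrically around its core
#'
#' Cuts each site down to `length_out` columns, keeping the core pattern and
#' as symmetric a flank extension as the alignment width allows.
#'
#' @param sites An [aligned_sites()] object.
#' @param length_out Target width (>= core length, <= alignment width).
#' @return A trimmed [aligned_sites()] object.
#' @export
trim_aligned_sites <- function(sites, length_out) {
  width <- attr(sites, "width")
  core_offset <- attr(sites, "core_offset")
  core_len <- attr(sites, "core_len")
  if (length_out > width) stop("candidate length exceeds alignment width", call. = FALSE)
  if (length_out < core_len) stop("candidate length shorter than the core", call. = FALSE)
  extra <- length_out - core_len
  left <- min(core_offset, extra %/% 2L + extra %% 2L)
  left <- max(left, extra - (width - core_offset - core_len))
  start <- core_offset - left
  aligned_sites(substring(sites$seq, start + 1L, start + length_out),
                core_offset = core_offset - start, core_len = core_len)
}

#' Read/write aligned site sets as plain text
#'
#' One sequence per line with a `#core offset len` header line.
#'
#' @param sites An `aligned_sites` object.
#' @param path File path.
#' @return For the reader, an `aligned_sites` object; the writer returns
#'   `path` invisibly.
#' @export
write_aligned_sites <- function(sites, path) {
  writeLines(c(sprintf("#core %d %d", attr(sites, "core_offset"),
                       attr(sites, "core_len")),
               sites$seq), path)
  invisible(path)
}

#' @rdname write_aligned_sites
#' @export
read_aligned_sites <- function(path) {
  lines <- readLines(path)
  if (!grepl("^#core ", lines[1])) {
    stop("aligned site file must start with a '#core offset len' line",
         call. = FALSE)
  }
  meta <- as.integer(strsplit(lines[1], "\\s+")[[1]][2:3])
  aligned_sites(lines[-1][nzchar(lines[-1])], meta[1], meta[2])
}
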