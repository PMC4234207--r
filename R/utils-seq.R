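#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

## Internal sequence encoding: A=1, C=2, G=3, T=4; anything else NA.
.BASES <- c("A", "C", "G", "T")
.DINUCS <- as.vector(t(outer(.BASES, .BASES, paste0)))  # index = 4*(a-1)+b

.BASE_LOOKUP <- local({
  lk <- rep(NA_integer_, 128L)
  lk[utf8ToInt("A")] <- 1L
  lk[utf8ToInt("C")] <- 2L
  lk[utf8ToInt("G")] <- 3L
  lk[utf8ToInt("T")] <- 4L
  lk
})

# Integer encoding of one DNA string; non-ACGT letters become NA.
seq_to_int <- function(seq) {
  .BASE_LOOKUP[utf8ToInt(seq)]
}

int_to_seq <- function(v) {
  paste(.BASES[v], collapse = "")
}

# Adjacent dinucleotide codes (1..16) for an integer-encoded sequence.
dinuc_codes <- function(v) {
  n <- length(v)
  if (n < 2L) return(integer(0))
  4L * (v[-n] - 1L) + v[-1L]
}

# Fast reverse complement on the ACGT integer encoding.
rc_int <- function(v) {
  rev(5L - v)
}

.IUPAC_CHARS <- names(Biostrings::IUPAC_CODE_MAP)

assert_iupac <- function(seqs, what = "sequence") {
  bad <- stringr::str_detect(seqs, paste0("[^", paste(.IUPAC_CHARS, collapse = ""), "]"))
  if (any(bad)) {
    chars <- unique(unlist(stringr::str_extract_all(
      seqs[bad], paste0("[^", paste(.IUPAC_CHARS, collapse = ""), "]")
    )))
    stop(sprintf("invalid character %s in %s", paste(chars, collapse = ", "), what),
         call. = FALSE)
  }
  invisible(seqs)
}

#' Reverse complement of IUPAC DNA strings
#'
#' Vectorised reverse complement covering the full IUPAC alphabet (including
#' the degenerate codes R, Y, H, D used in binding-site consensus patterns
#' such as TRTTTRYH). An involution: applying it twice returns the input.
#'
#' @param seq Character vector of DNA strings over the IUPAC alphabet.
#' @return Character vector of reverse-complemented strings.
#' @examples
#' reverse_complement("TRTTTRYH")
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(seq)
  assert_iupac(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# Derive a reproducible child seed (< 2^31) from a base seed and a salt.
derive_seed <- function(seed, salt) {
  x <- (as.numeric(seed) * 69069 + sum(utf8ToInt(as.character(salt))) * 9973) %% 2147483629
  as.integer(x) + 1L
}

# Match an ACGT string against an IUPAC pattern of the same length.
matches_iupac <- function(seq, pattern) {
  stopifnot(nchar(seq) == nchar(pattern))
  codes <- Biostrings::IUPAC_CODE_MAP
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  all(vapply(seq_along(s),
             function(i) grepl(s[i], codes[[p[i]]], fixed = TRUE),
             logical(1)))
}
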