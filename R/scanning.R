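## Apply trained models to peak sets: both-strand sliding-window scoring,
## hit extraction at a threshold with greedy non-overlap pruning, per-peak
## summaries and hit-overlap utilities.

## All rescaled window scores of one integer-encoded peak on both strands.
## Offsets are 0-based positions of the window start on the forward
## sequence for both strands.
.peak_all_scores <- function(model, v) {
  L <- model_width(model)
  n <- length(v)
  if (n < L) return(NULL)
  fwd <- .window_scores_int(model, v)
  rev_ <- .window_scores_int(model, rc_int(v))
  ## window at forward offset i (0-based) maps to offset n - L - i on the
  ## reverse-complemented sequence
  noff <- n - L + 1L
  tibble::tibble(start = rep(0:(noff - 1L), 2L),
                 strand = rep(c("+", "-"), each = noff),
                 score = c(fwd, rev(rev_)))
}

#' Score every window of every peak with a model
#'
#' Both strands are scanned; windows containing non-ACGT letters are
#' unscorable and omitted. Scores are on the rescaled \[0, 1\] model scale.
#'
#' @param peaks Peak tibble.
#' @param model A fitted binding-site model (`mono_pwm`, `di_pwm`,
#'   `sitega_model`).
#' @return Tibble (`peak_id`, `start`, `strand`, `score`), `start` 0-based
#'   on the forward strand.
#' @export
score_windows <- function(peaks, model) {
  rows <- purrr::map2(peaks$id, peaks$seq, function(id, s) {
    sc <- .peak_all_scores(model, seq_to_int(toupper(s)))
    if (is.null(sc)) return(NULL)
    sc$peak_id <- id
    sc[!is.na(sc$score), c("peak_id", "start", "strand", "score")]
  })
  dplyr::bind_rows(rows)
}

## Greedy best-score-first pruning so reported same-model hits never
## overlap; ties go to the leftmost start, then '+' strand.
.prune_hits <- function(hits, L) {
  if (nrow(hits) < 2L) return(hits)
  ord <- order(-hits$score, hits$start, hits$strand)
  hits <- hits[ord, ]
  kept <- integer(0)
  for (i in seq_len(nrow(hits))) {
    s <- hits$start[i]
    if (!length(kept) ||
        !any(s < hits$start[kept] + L & hits$start[kept] < s + L)) {
      kept <- c(kept, i)
    }
  }
  out <- hits[kept, ]
  out[order(out$start, out$strand), ]
}

#' Scan peaks for threshold-passing hits
#'
#' Scores every window on both strands and reports hits with
#' `score >= threshold`, pruned greedily best-score-first so that reported
#' hits of one model never overlap each other (multiple sites per peak are
#' kept, supporting homotypic-cluster analysis).
#'
#' @inheritParams score_windows
#' @param threshold Rescaled score threshold in \[0, 1\].
#' @param strict Require `score > threshold` rather than `>=`; use `TRUE`
#'   with EMSA-calibrated thresholds, whose value belongs to a non-site.
#' @return Tibble (`peak_id`, `start`, `strand`, `model_id`, `score`).
#' @export
scan_peaks <- function(peaks, model, threshold, strict = FALSE) {
  stopifnot(threshold >= 0, threshold <= 1)
  L <- model_width(model)
  all_scores <- score_windows(peaks, model)
  if (nrow(all_scores) == 0L) {
    return(tibble::tibble(peak_id = character(0), start = integer(0),
                          strand = character(0), model_id = character(0),
                          score = numeric(0)))
  }
  hits <- if (strict) dplyr::filter(all_scores, .data$score > threshold)
          else dplyr::filter(all_scores, .data$score >= threshold)
  hits <- dplyr::group_modify(dplyr::group_by(hits, .data$peak_id),
                              function(df, key) .prune_hits(df, L))
  hits <- dplyr::ungroup(hits)
  hits$model_id <- model_id(model)
  dplyr::select(hits, "peak_id", "start", "strand", "model_id", "score")
}

#' Per-peak scan summary
#'
#' The per-model best score over the full scan (independent of the
#' threshold) plus the number of threshold-passing hits.
#'
#' @inheritParams scan_peaks
#' @return Tibble (`peak_id`, `model_id`, `best_score`, `n_hits`).
#' @export
scan_summary <- function(peaks, model, threshold = 1) {
  all_scores <- score_windows(peaks, model)
  hits <- scan_peaks(peaks, model, threshold)
  best <- dplyr::summarise(dplyr::group_by(all_scores, .data$peak_id),
                           best_score = max(.data$score), .groups = "drop")
  nh <- dplyr::summarise(dplyr::group_by(hits, .data$peak_id),
                         n_hits = dplyr::n(), .groups = "drop")
  out <- dplyr::left_join(tibble::tibble(peak_id = peaks$id), best,
                          by = "peak_id")
  out <- dplyr::left_join(out, nh, by = "peak_id")
  out$n_hits <- dplyr::coalesce(out$n_hits, 0L)
  out$model_id <- model_id(model)
  dplyr::select(out, "peak_id", "model_id", "best_score", "n_hits")
}

## Per-peak best rescaled score, NA when no window is scorable.
.best_scores <- function(peaks, model) {
  vapply(peaks$seq, function(s) {
    sc <- .peak_all_scores(model, seq_to_int(toupper(s)))
    if (is.null(sc) || all(is.na(sc$score))) NA_real_
    else max(sc$score, na.rm = TRUE)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Fraction of peaks recognized by a model
#'
#' A peak is recognized when at least one window on either strand scores at
#' or above the threshold.
#'
#' @inheritParams scan_peaks
#' @return Fraction in \[0, 1\].
#' @export
recognized_fraction <- function(peaks, model, threshold, strict = FALSE) {
  if (nrow(peaks) == 0L) stop("empty peak set", call. = FALSE)
  best <- .best_scores(peaks, model)
  if (strict) mean(!is.na(best) & best > threshold)
  else mean(!is.na(best) & best >= threshold)
}

#' Do two hits on the same peak overlap?
#'
#' Half-open interval test, strand-agnostic: ``[start, start + L)`` windows
#' overlap when they share at least one base.
#'
#' @param hit_a,hit_b One-row hit tibbles (must share `peak_id`).
#' @param model_len_a,model_len_b Window lengths of the two models.
#' @return Logical.
#' @export
hits_overlap <- function(hit_a, hit_b, model_len_a, model_len_b) {
  if (hit_a$peak_id != hit_b$peak_id) {
    stop("hits are on different peaks", call. = FALSE)
  }
  hit_a$start < hit_b$start + model_len_b &
    hit_b$start < hit_a$start + model_len_a
}

#' Write hits as BED6 or TSV
#'
#' BED scores are the rescaled score times 1000, as integers per BED
#' convention; the TSV keeps full precision.
#'
#' @param hits Hit tibble from [scan_peaks()].
#' @param path Output path.
#' @param L Model window length (for BED end coordinates).
#' @param peaks Optional peak tibble supplying chrom/start offsets; without
#'   it, coordinates are peak-local.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path, L, peaks = NULL) {
  chrom <- hits$peak_id
  start <- hits$start
  if (!is.null(peaks) && all(c("chrom", "start") %in% names(peaks))) {
    i <- match(hits$peak_id, peaks$id)
    chrom <- peaks$chrom[i]
    start <- peaks$start[i] + hits$start
  }
  bed <- data.frame(chrom = chrom, start = start, end = start + L,
                    name = hits$model_id,
                    score = as.integer(round(hits$score * 1000)),
                    strand = hits$strand)
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_hits_bed
#' @export
write_hits_tsv <- function(hits, path) {
  readr::write_tsv(hits, path, progress = FALSE)
  invisible(path)
}
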