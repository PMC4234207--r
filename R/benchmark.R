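## Model evaluation and comparison: Markov-shuffled background construction,
## peak-level ROC and Matthews CC, pairwise combination categories with
## homotypic-cluster counting, and the chance-overlap chi-squared test.

#' Confusion counts at a fixed threshold
#'
#' TP/FN count real peaks recognized/missed; FP/TN count shuffled background
#' peaks recognized/rejected.
#'
#' @param tp,fn,fp,tn Non-negative integer counts.
#' @return A `confusion_counts` list.
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn),
            class = "confusion_counts")
}

#' Matthews correlation coefficient of a confusion table
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, balancing true-
#' and false-positive rates in a single number. A zero marginal makes the
#' coefficient undefined; it is returned as 0 with a warning.
#'
#' @param counts A [confusion_counts()] object.
#' @return CC in \[-1, 1\].
#' @export
correlation_coefficient <- function(counts) {
  tp <- counts$tp; fn <- counts$fn; fp <- counts$fp; tn <- counts$tn
  den <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  if (den == 0) {
    warning("zero marginal: correlation coefficient undefined, returning 0",
            call. = FALSE)
    return(0)
  }
  (tp * tn - fp * fn) / den
}

#' Generate Markov-shuffled background peak sets
#'
#' For each fold and each peak, a chain of the requested order is fitted to
#' that peak alone and one background sequence of identical length is drawn
#' from it — shuffling full-length peak sequences while preserving per-peak
#' length and (di)nucleotide composition. Heights are copied from the source
#' peaks.
#'
#' @param peaks Peak tibble.
#' @param order Markov order, 0 or 1.
#' @param n_fold Number of shuffled replicates per peak (the study design
#'   uses a tenfold simulation).
#' @param seed Integer seed.
#' @return Peak tibble with columns `id`, `seq`, `height`, `fold`,
#'   `source_id`; ids are `<source>_shuf<fold>`.
#' @export
make_shuffled_background <- function(peaks, order = 1L, n_fold = 10L,
                                     seed = 1L) {
  stopifnot(order %in% c(0L, 1L), n_fold >= 1L)
  if (any(nchar(peaks$seq) < order + 1L)) {
    stop("peak shorter than the Markov order allows", call. = FALSE)
  }
  models <- lapply(peaks$seq, fit_markov, order = order)
  lens <- nchar(peaks$seq)
  withr::with_seed(seed, {
    rows <- purrr::map(seq_len(n_fold), function(fold) {
      seqs <- vapply(seq_along(models), function(i) {
        int_to_seq(.draw_markov_int(models[[i]], 1L, lens[i])[1, ])
      }, character(1))
      tibble::tibble(id = sprintf("%s_shuf%d", peaks$id, fold),
                     seq = seqs, height = peaks$height,
                     fold = fold, source_id = peaks$id)
    })
  })
  dplyr::bind_rows(rows)
}

#' Peak-level ROC curve and AUC
#'
#' Sweeps the threshold over the union of per-peak best scores; each point
#' is (fraction of recognized shuffled peaks, fraction of recognized real
#' peaks) — peak-level FP and TP rates. AUC by the trapezoid rule.
#'
#' @param real_peaks,background_peaks Peak tibbles.
#' @param model A fitted binding-site model.
#' @return An object of class `roc_result`: a list with `points` (tibble
#'   `threshold`, `fpr`, `tpr`), `auc` and `model_id`.
#' @export
roc_curve <- function(real_peaks, background_peaks, model) {
  stopifnot(nrow(real_peaks) > 0L, nrow(background_peaks) > 0L)
  best_real <- .best_scores(real_peaks, model)
  best_bg <- .best_scores(background_peaks, model)
  thr <- sort(unique(c(best_real, best_bg)), decreasing = TRUE)
  thr <- thr[!is.na(thr)]
  tpr <- vapply(thr, function(t) mean(!is.na(best_real) & best_real >= t),
                numeric(1))
  fpr <- vapply(thr, function(t) mean(!is.na(best_bg) & best_bg >= t),
                numeric(1))
  pts <- tibble::tibble(threshold = c(Inf, thr, -Inf),
                        fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, model_id = model_id(model)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> '%s', AUC %.4f, %d points\n",
              x$model_id, x$auc, nrow(x$points)))
  invisible(x)
}

## Cross-model overlapping hit pairs within one peak (half-open windows).
.any_cross_overlap <- function(starts1, L1, starts2, L2) {
  if (!length(starts1) || !length(starts2)) return(FALSE)
  any(outer(starts1, starts2, function(a, b) a < b + L2 & b < a + L1))
}

#' Pairwise model combination analysis
#'
#' Classifies each peak by the joint pattern of two models' hits:
#' category `a` — at least one cross-model overlapping hit pair;
#' `b`/`c` — hits from only the first / only the second model;
#' `d` — both models hit but no pair overlaps; `neither` — no hits.
#' Also reports the homotypic-cluster fraction: among peaks detected by at
#' least one model, the fraction carrying two or more sites in total.
#'
#' @param peaks Peak tibble.
#' @param hits_model_1,hits_model_2 Hit tibbles from [scan_peaks()].
#' @param len_1,len_2 Window lengths of the two models.
#' @return An object of class `combination_summary`: per-peak category
#'   tibble plus category counts, fractions, per-model site totals and the
#'   cluster fraction.
#' @export
combination_analysis <- function(peaks, hits_model_1, hits_model_2,
                                 len_1, len_2) {
  unknown <- setdiff(c(hits_model_1$peak_id, hits_model_2$peak_id), peaks$id)
  if (length(unknown)) {
    stop(sprintf("hits reference unknown peaks: %s",
                 paste(utils::head(unknown, 5), collapse = ", ")),
         call. = FALSE)
  }
  h1 <- split(hits_model_1$start, hits_model_1$peak_id)
  h2 <- split(hits_model_2$start, hits_model_2$peak_id)
  category <- vapply(peaks$id, function(id) {
    s1 <- h1[[id]]; s2 <- h2[[id]]
    n1 <- length(s1); n2 <- length(s2)
    if (n1 == 0L && n2 == 0L) return("neither")
    if (n1 > 0L && n2 == 0L) return("b")
    if (n1 == 0L && n2 > 0L) return("c")
    if (.any_cross_overlap(s1, len_1, s2, len_2)) "a" else "d"
  }, character(1), USE.NAMES = FALSE)
  per_peak <- tibble::tibble(
    peak_id = peaks$id, category = category,
    n_sites_1 = vapply(peaks$id, function(id) length(h1[[id]]), integer(1),
                       USE.NAMES = FALSE),
    n_sites_2 = vapply(peaks$id, function(id) length(h2[[id]]), integer(1),
                       USE.NAMES = FALSE))
  counts <- vapply(c(a = "a", b = "b", c = "c", d = "d",
                     neither = "neither"),
                   function(k) sum(category == k), integer(1))
  detected <- per_peak$category != "neither"
  cluster_fraction <- if (any(detected)) {
    mean((per_peak$n_sites_1 + per_peak$n_sites_2)[detected] >= 2L)
  } else NA_real_
  structure(list(per_peak = per_peak, counts = counts,
                 fractions = counts / nrow(peaks),
                 total_sites = c(model_1 = nrow(hits_model_1),
                                 model_2 = nrow(hits_model_2)),
                 cluster_fraction = cluster_fraction),
            class = "combination_summary")
}

#' @export
print.combination_summary <- function(x, ...) {
  cat("<combination_summary>\n")
  cat(sprintf("  a (both, overlapping)     %d\n", x$counts["a"]))
  cat(sprintf("  b (only model 1)          %d\n", x$counts["b"]))
  cat(sprintf("  c (only model 2)          %d\n", x$counts["c"]))
  cat(sprintf("  d (both, non-overlapping) %d\n", x$counts["d"]))
  cat(sprintf("  neither                   %d\n", x$counts["neither"]))
  cat(sprintf("  cluster fraction (>=2 sites | detected): %.3f\n",
              x$cluster_fraction))
  invisible(x)
}

#' Chance-overlap test for non-overlapping co-detections
#'
#' Observed statistic: among real peaks detected by both models, the
#' fraction whose sites never overlap, `d / (a + d)`. The expectation under
#' chance co-location is the same statistic pooled over `n_fold`
#' Markov-shuffled replicates of the peaks. The two are compared by a
#' chi-squared test (1 df, no continuity correction) on the 2x2 table
#' `[[d, a], [d', a']]`.
#'
#' @param peaks Real peak tibble.
#' @param model_1,model_2 Fitted models.
#' @param thresholds Numeric vector of two calibrated thresholds
#'   (model 1, model 2), applied strictly.
#' @param n_fold Number of shuffle folds (default 10).
#' @param seed Integer seed for the shuffles.
#' @param order Markov order of the shuffles.
#' @return A list of class `chance_overlap_test` with `observed_frac`,
#'   `expected_frac`, `chi2`, `p`, the underlying counts and the per-fold
#'   background counts.
#' @export
chance_overlap_test <- function(peaks, model_1, model_2, thresholds,
                                n_fold = 10L, seed = 1L, order = 1L) {
  stopifnot(length(thresholds) == 2L)
  L1 <- model_width(model_1); L2 <- model_width(model_2)
  comb_counts <- function(pks) {
    h1 <- scan_peaks(pks, model_1, thresholds[1], strict = TRUE)
    h2 <- scan_peaks(pks, model_2, thresholds[2], strict = TRUE)
    combination_analysis(pks, h1, h2, L1, L2)$counts
  }
  real <- comb_counts(peaks)
  bg_peaks <- make_shuffled_background(peaks, order = order, n_fold = n_fold,
                                       seed = seed)
  folds <- lapply(split(bg_peaks, bg_peaks$fold), comb_counts)
  bg <- Reduce(`+`, folds)
  undefined <- (real["a"] + real["d"]) == 0L || (bg["a"] + bg["d"]) == 0L
  observed <- unname(real["d"] / (real["a"] + real["d"]))
  expected <- unname(bg["d"] / (bg["a"] + bg["d"]))
  if (undefined) {
    warning("no peaks detected by both models in one of the sets; test undefined",
            call. = FALSE)
    chi2 <- NA_real_; p <- NA_real_
  } else {
    tab <- rbind(real = c(d = real[["d"]], a = real[["a"]]),
                 shuffled = c(d = bg[["d"]], a = bg[["a"]]))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      chi2 <- 0; p <- 1
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      chi2 <- unname(ct$statistic); p <- ct$p.value
    }
  }
  structure(list(observed_frac = observed, expected_frac = expected,
                 chi2 = chi2, df = 1L, p = p,
                 real_counts = real, background_counts = bg,
                 n_fold = n_fold),
            class = "chance_overlap_test")
}

#' @export
print.chance_overlap_test <- function(x, ...) {
  cat(sprintf(paste0("<chance_overlap_test> observed d/(a+d) = %.3f, ",
                     "expected (pooled %d-fold shuffle) = %.3f\n",
                     "  chi2(1) = %.4f, p = %.3g\n"),
              x$observed_frac, x$n_fold, x$expected_frac, x$chi2, x$p))
  invisible(x)
}
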