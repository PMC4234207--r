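## Turn competition-curve measurements into EMSA scores, classify oligos
## into non-site / weak / strong affinity bins, and derive per-model
## recognition thresholds from the non-site bin.

.fit_slope <- function(conc, intensity) {
  if (length(conc) < 2L || length(conc) != length(intensity)) {
    stop("need >= 2 (concentration, intensity) pairs", call. = FALSE)
  }
  if (any(conc <= 0)) stop("concentrations must be positive", call. = FALSE)
  x <- log(conc)
  if (stats::var(x) < 1e-12) {
    stop("concentrations must span more than one value", call. = FALSE)
  }
  unname(stats::coef(stats::lm(intensity ~ x))[2])
}

#' EMSA score of one competitor relative to the positive control
#'
#' Band intensity is regressed on the natural log of competitor
#' concentration by ordinary least squares (the standard 2/5/20 ng series is
#' log-spaced); the score is the competitor's slope divided by the
#' self-competition control's slope. A negative ratio is clamped to 0 with a
#' warning.
#'
#' @param record,control_record Data frames with columns `conc_ng` and
#'   `intensity` for the competitor and the positive control.
#' @return EMSA score (non-negative scalar).
#' @export
emsa_score <- function(record, control_record) {
  s <- .fit_slope(record$conc_ng, record$intensity)
  s0 <- .fit_slope(control_record$conc_ng, control_record$intensity)
  if (abs(s0) < 1e-12) stop("control slope is zero", call. = FALSE)
  score <- s / s0
  if (score < 0) {
    warning("negative slope ratio clamped to 0", call. = FALSE)
    score <- 0
  }
  score
}

#' Classify an EMSA score into affinity bins
#'
#' Scores strictly below 0.25 are non-sites (the bin edge reflects 1.5 times
#' the assay's technical error), 0.25 to 0.75 weak sites, above 0.75 strong
#' sites.
#'
#' @param score Numeric vector of non-negative EMSA scores.
#' @param non_site_edge,strong_edge Bin edges.
#' @return Character vector in `{"non-site", "weak", "strong"}`.
#' @export
classify_affinity <- function(score, non_site_edge = 0.25, strong_edge = 0.75) {
  stopifnot(all(score >= 0))
  dplyr::case_when(score < non_site_edge ~ "non-site",
                   score <= strong_edge ~ "weak",
                   TRUE ~ "strong")
}

#' Score a whole EMSA panel
#'
#' Fits per-oligo slopes of intensity against log concentration, normalises
#' to the control's slope and assigns affinity classes.
#'
#' @param curves Long tibble (`oligo_id`, `conc_ng`, `intensity`), e.g. from
#'   [simulate_emsa_panel()] or [read_emsa_curves()].
#' @param control_id Id of the self-competition control; defaults to the
#'   tibble's `control_id` attribute.
#' @param non_site_edge Non-site bin edge (default 0.25).
#' @return Tibble (`oligo_id`, `slope`, `emsa_score`, `affinity_class`).
#' @export
emsa_scores <- function(curves, control_id = NULL, non_site_edge = 0.25) {
  if (is.null(control_id)) control_id <- attr(curves, "control_id")
  if (is.null(control_id) || !control_id %in% curves$oligo_id) {
    stop("control oligo not found in panel", call. = FALSE)
  }
  ctl <- curves[curves$oligo_id == control_id, ]
  out <- dplyr::summarise(
    dplyr::group_by(curves, .data$oligo_id),
    slope = .fit_slope(.data$conc_ng, .data$intensity),
    .groups = "drop")
  s0 <- out$slope[out$oligo_id == control_id]
  if (abs(s0) < 1e-12) stop("control slope is zero", call. = FALSE)
  score <- out$slope / s0
  if (any(score < 0)) {
    warning("negative slope ratios clamped to 0", call. = FALSE)
    score <- pmax(score, 0)
  }
  out$emsa_score <- score
  out$affinity_class <- classify_affinity(score, non_site_edge)
  out
}

#' Derive a model's recognition threshold from EMSA non-sites
#'
#' The threshold is the highest model score among the oligos whose EMSA
#' score falls in the non-site bin; a sequence counts as a site only when
#' its model score exceeds the threshold strictly (the threshold value
#' itself belongs to a non-site).
#'
#' @param model The model being calibrated (used for its id only).
#' @param oligo_scores Tibble with columns `oligo_id`, `model_score` and
#'   `affinity_class` (from [emsa_scores()] joined with model scores).
#' @return One-row tibble of class `calibrated_threshold`
#'   (`model_id`, `threshold`, `n_non_sites`) with the non-site oligo ids in
#'   attribute `provenance`.
#' @export
derive_threshold <- function(model, oligo_scores) {
  ns <- oligo_scores[oligo_scores$affinity_class == "non-site", ]
  if (nrow(ns) == 0L) {
    stop("no non-site oligos in panel; extend the panel below the non-site edge",
         call. = FALSE)
  }
  out <- tibble::tibble(model_id = model_id(model),
                        threshold = max(ns$model_score),
                        n_non_sites = nrow(ns))
  attr(out, "provenance") <- ns$oligo_id
  class(out) <- c("calibrated_threshold", class(out))
  out
}

#' Sensitivity of the calibration to the non-site bin edge
#'
#' Re-derives the model threshold for each candidate bin edge (non-site =
#' EMSA score strictly below the edge) and reports the benchmark Matthews
#' correlation coefficient at that threshold against a shuffled background.
#'
#' @param oligo_scores Tibble with `oligo_id`, `emsa_score`, `model_score`.
#' @param peaks Real peak tibble.
#' @param background_peaks Shuffled background peak tibble.
#' @param model The model under evaluation.
#' @param edges Candidate bin edges, default `c(0.17, 0.25, 0.34)`.
#' @return Tibble (`edge`, `threshold`, `cc`, `defined`); an edge leaving no
#'   non-sites is marked undefined.
#' @export
sensitivity_of_bin_edge <- function(oligo_scores, peaks, background_peaks,
                                    model, edges = c(0.17, 0.25, 0.34)) {
  stopifnot(all(edges > 0), all(edges < 1))
  best_real <- .best_scores(peaks, model)
  best_bg <- .best_scores(background_peaks, model)
  rows <- purrr::map(edges, function(edge) {
    ns <- oligo_scores[oligo_scores$emsa_score < edge, ]
    if (nrow(ns) == 0L) {
      return(tibble::tibble(edge = edge, threshold = NA_real_, cc = NA_real_,
                            defined = FALSE))
    }
    thr <- max(ns$model_score)
    counts <- confusion_counts(
      tp = sum(best_real > thr, na.rm = TRUE),
      fn = sum(!(best_real > thr), na.rm = TRUE) + sum(is.na(best_real)),
      fp = sum(best_bg > thr, na.rm = TRUE),
      tn = sum(!(best_bg > thr), na.rm = TRUE) + sum(is.na(best_bg)))
    tibble::tibble(edge = edge, threshold = thr,
                   cc = correlation_coefficient(counts), defined = TRUE)
  })
  dplyr::bind_rows(rows)
}

#' Read / write EMSA competition curves as TSV
#'
#' Long format `oligo_id`, `conc_ng`, `intensity`; the control oligo is
#' flagged by a logical `control` column or named via `control_id`.
#'
#' @param path File path.
#' @param control_id Control oligo id (overrides any `control` column).
#' @return A tibble of class `emsa_curves` with attribute `control_id`.
#' @export
read_emsa_curves <- function(path, control_id = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("oligo_id", "conc_ng", "intensity") %in% names(tab)))
  if (is.null(control_id) && "control" %in% names(tab)) {
    control_id <- unique(tab$oligo_id[as.logical(tab$control)])
    if (length(control_id) != 1L) {
      stop("exactly one control oligo must be flagged", call. = FALSE)
    }
  }
  out <- tibble::as_tibble(tab[, c("oligo_id", "conc_ng", "intensity")])
  attr(out, "control_id") <- control_id
  class(out) <- c("emsa_curves", class(out))
  out
}

#' @rdname read_emsa_curves
#' @param curves An `emsa_curves` tibble.
#' @export
write_emsa_curves <- function(curves, path) {
  control_id <- attr(curves, "control_id")
  out <- tibble::as_tibble(curves)
  out$control <- out$oligo_id == control_id
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
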