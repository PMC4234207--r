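## Pattern-matching models trained on curated alignments: mononucleotide and
## dinucleotide position weight matrices with min-max score rescaling and
## leave-one-out matrix-length optimisation.

.site_strings <- function(sites) {
  s <- if (is.data.frame(sites)) sites$seq else as.character(sites)
  if (length(s) < 1L) stop("no site sequences supplied", call. = FALSE)
  toupper(s)
}

.site_matrix <- function(seqs) {
  m <- do.call(rbind, lapply(seqs, seq_to_int))
  if (anyNA(m)) stop("site sequences must be over {A,C,G,T}", call. = FALSE)
  m
}

#' Build a mononucleotide position weight matrix
#'
#' Column frequencies are estimated with a background-distributed pseudocount,
#' `f_ja = (n_ja + pc * q_a) / (N + pc)`, and converted to natural-log odds
#' `w_ja = ln(f_ja / q_a)`. The attainable raw-score extremes `s_min`/`s_max`
#' support min-max rescaling to a common \[0, 1\] scale.
#'
#' @param sites An [aligned_sites()] object (or data frame with a `seq`
#'   column) of at least two equal-width ACGT sequences.
#' @param q Background base composition (A, C, G, T), positive, summing to 1.
#' @param pseudocount Total pseudocount mass, distributed as `pc * q`.
#' @param id Model identifier used in hit tables.
#' @return An object of class `mono_pwm` (also `pwm_model`).
#' @export
build_mono_pwm <- function(sites, q = rep(0.25, 4), pseudocount = 1,
                           id = "mono_pwm") {
  seqs <- .site_strings(sites)
  if (length(seqs) < 2L) stop("need at least two training sites", call. = FALSE)
  stopifnot(length(q) == 4L, all(q > 0), abs(sum(q) - 1) < 1e-9)
  m <- .site_matrix(seqs)
  L <- ncol(m)
  if (L == 0L) stop("site width must be positive", call. = FALSE)
  N <- nrow(m)
  counts <- t(apply(m, 2, tabulate, nbins = 4L))
  f <- (counts + pseudocount * matrix(q, L, 4, byrow = TRUE)) / (N + pseudocount)
  w <- log(f / matrix(q, L, 4, byrow = TRUE))
  s_min <- sum(apply(w, 1, min))
  s_max <- sum(apply(w, 1, max))
  if (s_max - s_min < 1e-12) {
    stop("degenerate matrix: all columns at background composition", call. = FALSE)
  }
  structure(list(type = "mono", L = L, weights = w, q = q,
                 s_min = s_min, s_max = s_max, id = id),
            class = c("mono_pwm", "pwm_model", "tfbs_model"))
}

#' Build a dinucleotide position weight matrix
#'
#' As [build_mono_pwm()], over the 16-letter alphabet of adjacent
#' dinucleotides: an L-bp site yields L-1 dinucleotide columns, capturing
#' nearest-neighbour dependence that a mononucleotide matrix cannot.
#'
#' @inheritParams build_mono_pwm
#' @param Q Background dinucleotide composition (16 values, AA..TT row-major
#'   by first base), positive, summing to 1.
#' @return An object of class `di_pwm` (also `pwm_model`).
#' @export
build_di_pwm <- function(sites, Q = rep(1 / 16, 16), pseudocount = 1,
                         id = "di_pwm") {
  seqs <- .site_strings(sites)
  if (length(seqs) < 2L) stop("need at least two training sites", call. = FALSE)
  stopifnot(length(Q) == 16L, all(Q > 0), abs(sum(Q) - 1) < 1e-9)
  m <- .site_matrix(seqs)
  L <- ncol(m)
  if (L < 2L) stop("dinucleotide matrix needs width >= 2", call. = FALSE)
  N <- nrow(m)
  d <- t(apply(m, 1, dinuc_codes))
  if (L == 2L) d <- matrix(d, ncol = 1L)
  counts <- t(apply(d, 2, tabulate, nbins = 16L))
  f <- (counts + pseudocount * matrix(Q, L - 1L, 16, byrow = TRUE)) /
    (N + pseudocount)
  w <- log(f / matrix(Q, L - 1L, 16, byrow = TRUE))
  s_min <- sum(apply(w, 1, min))
  s_max <- sum(apply(w, 1, max))
  if (s_max - s_min < 1e-12) {
    stop("degenerate matrix: all columns at background composition", call. = FALSE)
  }
  structure(list(type = "di", L = L, weights = w, Q = Q,
                 s_min = s_min, s_max = s_max, id = id),
            class = c("di_pwm", "pwm_model", "tfbs_model"))
}

#' Model width (scored window length)
#' @param model A fitted binding-site model.
#' @return Integer window length.
#' @export
model_width <- function(model) UseMethod("model_width")
#' @export
model_width.pwm_model <- function(model) model$L
#' @export
model_id <- function(model) UseMethod("model_id")
#' @export
model_id.default <- function(model) model$id

#' Raw additive score of a single window
#'
#' Sums per-position log-odds over the window (mononucleotide) or over its
#' adjacent dinucleotides. Strand `-` scores the reverse complement. A window
#' containing N (or any non-ACGT letter) is unscorable and returns `NA`.
#'
#' @param model A `mono_pwm` or `di_pwm`.
#' @param window ACGT string of length `model_width(model)`.
#' @param strand `"+"` or `"-"`.
#' @return Raw score (numeric), or `NA` for an unscorable window.
#' @export
score_window <- function(model, window, strand = "+") {
  UseMethod("score_window")
}

#' @export
score_window.pwm_model <- function(model, window, strand = "+") {
  if (nchar(window) != model$L) {
    stop("window length must equal model width", call. = FALSE)
  }
  v <- seq_to_int(toupper(window))
  if (strand == "-") v <- rc_int(v)
  if (anyNA(v)) return(NA_real_)
  if (model$type == "mono") {
    sum(model$weights[cbind(seq_len(model$L), v)])
  } else {
    d <- dinuc_codes(v)
    sum(model$weights[cbind(seq_len(model$L - 1L), d)])
  }
}

#' Rescale a raw model score to \[0, 1\]
#'
#' Min-max rescaling `(raw - s_min) / (s_max - s_min)` over the attainable
#' score range, putting all models on a common score scale.
#'
#' @param model A fitted model carrying `s_min`, `s_max`.
#' @param raw Raw score(s) within `[s_min, s_max]`.
#' @return Rescaled score(s) in \[0, 1\]; `NA` passes through.
#' @export
rescale_score <- function(model, raw) {
  ok <- is.na(raw) | (raw >= model$s_min - 1e-9 & raw <= model$s_max + 1e-9)
  if (!all(ok)) stop("raw score outside [s_min, s_max]", call. = FALSE)
  pmin(1, pmax(0, (raw - model$s_min) / (model$s_max - model$s_min)))
}

## Vectorised rescaled scores of all length-L forward windows of an
## integer-encoded sequence. Returns numeric(n - L + 1), NA = unscorable.
.window_scores_int <- function(model, v) UseMethod(".window_scores_int")

#' @export
.window_scores_int.pwm_model <- function(model, v) {
  L <- model$L
  noff <- length(v) - L + 1L
  if (noff < 1L) return(numeric(0))
  if (model$type == "mono") {
    s <- numeric(noff)
    for (j in seq_len(L)) s <- s + model$weights[j, ][v[seq_len(noff) + j - 1L]]
  } else {
    d <- dinuc_codes(v)
    s <- numeric(noff)
    for (j in seq_len(L - 1L)) {
      s <- s + model$weights[j, ][d[seq_len(noff) + j - 1L]]
    }
  }
  (pmin(model$s_max, pmax(model$s_min, s)) - model$s_min) /
    (model$s_max - model$s_min)
}

#' Optimise matrix length by leave-one-out cross-validation
#'
#' For each candidate length (a symmetric extension around the alignment
#' core), every site is scored by a matrix trained on the remaining sites;
#' the score threshold is set so that at least `tp_anchor` of held-out sites
#' pass, and the false-positive rate is the fraction of background windows
#' passing that threshold. The best length minimises the FP rate, ties broken
#' toward the shorter (more parsimonious) matrix.
#'
#' @param sites An [aligned_sites()] alignment.
#' @param background_peaks Peak tibble supplying background windows.
#' @param candidate_lengths Integer vector of matrix lengths to try.
#' @param tp_anchor Target true-positive fraction among held-out sites.
#' @param type `"mono"` or `"di"`.
#' @param q Background composition (length 4 or 16 to match `type`).
#' @param pseudocount Pseudocount mass.
#' @return A list with `best_length`, `model` (trained at the best length on
#'   all sites) and `table`, a tibble of (length, threshold, fp_rate).
#' @export
optimize_length <- function(sites, background_peaks, candidate_lengths,
                            tp_anchor = 0.9, type = c("mono", "di"),
                            q = NULL, pseudocount = 1) {
  type <- match.arg(type)
  stopifnot(tp_anchor > 0, tp_anchor <= 1)
  width <- attr(sites, "width")
  if (any(candidate_lengths > width)) {
    stop("candidate length exceeds alignment width", call. = FALSE)
  }
  build <- function(trimmed) {
    if (type == "mono") {
      if (is.null(q)) build_mono_pwm(trimmed, pseudocount = pseudocount)
      else build_mono_pwm(trimmed, q = q, pseudocount = pseudocount)
    } else {
      if (is.null(q)) build_di_pwm(trimmed, pseudocount = pseudocount)
      else build_di_pwm(trimmed, Q = q, pseudocount = pseudocount)
    }
  }
  bg_int <- lapply(toupper(background_peaks$seq), seq_to_int)
  rows <- purrr::map(sort(unique(as.integer(candidate_lengths))), function(L) {
    trimmed <- trim_aligned_sites(sites, L)
    N <- nrow(trimmed)
    loo <- vapply(seq_len(N), function(i) {
      mdl <- build(trimmed[-i, , drop = FALSE])
      rescale_score(mdl, pmin(mdl$s_max, pmax(mdl$s_min,
        score_window(mdl, trimmed$seq[i]))))
    }, numeric(1))
    k <- ceiling(tp_anchor * N)
    thr <- sort(loo, decreasing = TRUE)[k]
    full <- build(trimmed)
    bg_scores <- unlist(lapply(bg_int, function(v) {
      c(.window_scores_int(full, v), .window_scores_int(full, rc_int(v)))
    }))
    bg_scores <- bg_scores[!is.na(bg_scores)]
    fp <- if (length(bg_scores)) mean(bg_scores >= thr) else NA_real_
    tibble::tibble(length = L, threshold = thr, fp_rate = fp)
  })
  table <- dplyr::bind_rows(rows)
  best <- table$length[which.min(table$fp_rate)]  # ties: shorter (sorted)
  list(best_length = best,
       model = build(trim_aligned_sites(sites, best)),
       table = table)
}

#' Write / read PWMs in a plain-text matrix format
#'
#' Header line `#type mono|di <length> <background...>`, then one
#' whitespace-separated row of log-odds weights per column. The same format
#' imports externally supplied matrices.
#'
#' @param model A `mono_pwm` or `di_pwm`.
#' @param path File path.
#' @return The reader returns the model; the writer returns `path`
#'   invisibly.
#' @export
write_pwm <- function(model, path) {
  bg <- if (model$type == "mono") model$q else model$Q
  header <- sprintf("#type %s %d %s %s", model$type, model$L, model$id,
                    paste(format(bg, digits = 17), collapse = " "))
  rows <- apply(model$weights, 1, function(r) {
    paste(format(r, digits = 17), collapse = " ")
  })
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_pwm
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  h <- strsplit(sub("^#type\\s+", "", lines[1]), "\\s+")[[1]]
  type <- h[1]
  L <- as.integer(h[2])
  id <- h[3]
  bg <- as.numeric(h[-(1:3)])
  w <- do.call(rbind, lapply(lines[-1][nzchar(lines[-1])], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  s_min <- sum(apply(w, 1, min))
  s_max <- sum(apply(w, 1, max))
  if (type == "mono") {
    structure(list(type = "mono", L = L, weights = w, q = bg,
                   s_min = s_min, s_max = s_max, id = id),
              class = c("mono_pwm", "pwm_model", "tfbs_model"))
  } else {
    structure(list(type = "di", L = L, weights = w, Q = bg,
                   s_min = s_min, s_max = s_max, id = id),
              class = c("di_pwm", "pwm_model", "tfbs_model"))
  }
}

#' @export
print.pwm_model <- function(x, ...) {
  cat(sprintf("<%s> '%s', width %d, raw score range [%.3f, %.3f]\n",
              class(x)[1], x$id, x$L, x$s_min, x$s_max))
  invisible(x)
}
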