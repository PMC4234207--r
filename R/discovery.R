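## De-novo motif discovery in peak sets: greedy gapless multiple local
## alignment maximising Kullback Discrete Information Content in the mono-
## (KDIC) or dinucleotide (KDDIC) alphabet, with multi-start bootstrapping
## and optional peak-shape positional weighting.

.occurrence_windows <- function(occurrences, peaks, L) {
  idx <- match(occurrences$peak_id, peaks$id)
  if (anyNA(idx)) stop("occurrence references unknown peak", call. = FALSE)
  lens <- nchar(peaks$seq[idx])
  if (any(occurrences$offset < 0L) || any(occurrences$offset + L > lens)) {
    stop("occurrence out of peak bounds", call. = FALSE)
  }
  win <- substring(peaks$seq[idx], occurrences$offset + 1L,
                   occurrences$offset + L)
  neg <- occurrences$strand == "-"
  if (any(neg)) win[neg] <- reverse_complement(win[neg])
  win
}

.weighted_counts <- function(windows, weights, nbins, codes_fun) {
  ncol_ <- length(codes_fun(seq_to_int(windows[1])))
  counts <- matrix(0, ncol_, nbins)
  for (i in seq_along(windows)) {
    v <- codes_fun(seq_to_int(windows[i]))
    counts[cbind(seq_len(ncol_), v)] <-
      counts[cbind(seq_len(ncol_), v)] + weights[i]
  }
  counts
}

.kl_sum <- function(counts, total, q, pseudocount) {
  qm <- matrix(q, nrow(counts), length(q), byrow = TRUE)
  f <- (counts + pseudocount * qm) / (total + pseudocount)
  sum(f * log(f / qm))
}

#' Kullback Discrete Information Content of an alignment
#'
#' `sum_j sum_a f_ja ln(f_ja / q_a)` over the mononucleotide columns of the
#' occurrence windows, with pseudocounted frequencies. Non-negative by the
#' Gibbs inequality; a fully conserved column contributes `ln 4` nats under a
#' uniform background as the pseudocount vanishes.
#'
#' @param occurrences Tibble (`peak_id`, `offset`, `strand`, optional
#'   `weight`).
#' @param peaks Peak tibble the occurrences index into.
#' @param L Motif length.
#' @param q Background base composition.
#' @param pseudocount Pseudocount mass.
#' @return Information content in nats.
#' @export
kdic <- function(occurrences, peaks, L, q = rep(0.25, 4), pseudocount = 1) {
  if (nrow(occurrences) < 2L) stop("need at least two occurrences", call. = FALSE)
  win <- .occurrence_windows(occurrences, peaks, L)
  w <- if ("weight" %in% names(occurrences)) occurrences$weight else
    rep(1, nrow(occurrences))
  counts <- .weighted_counts(win, w, 4L, function(v) v)
  .kl_sum(counts, sum(w), q, pseudocount)
}

#' Kullback Dinucleotide Discrete Information Content
#'
#' As [kdic()] over the `L - 1` adjacent-dinucleotide columns in the
#' 16-letter alphabet; a fully conserved alignment approaches
#' `(L - 1) ln 16` under a uniform background.
#'
#' @inheritParams kdic
#' @param Q Background dinucleotide composition (16 values).
#' @return Information content in nats.
#' @export
kddic <- function(occurrences, peaks, L, Q = rep(1 / 16, 16), pseudocount = 1) {
  if (nrow(occurrences) < 2L) stop("need at least two occurrences", call. = FALSE)
  win <- .occurrence_windows(occurrences, peaks, L)
  w <- if ("weight" %in% names(occurrences)) occurrences$weight else
    rep(1, nrow(occurrences))
  counts <- .weighted_counts(win, w, 16L, dinuc_codes)
  .kl_sum(counts, sum(w), Q, pseudocount)
}

## Candidate occurrence windows for one peak: letter-code matrix plus
## offset/strand bookkeeping, NA-containing windows dropped. Rows are ordered
## by (offset, '+' before '-') so that which.max realises the tie rule.
.peak_candidates <- function(v, L, mode, weight_profile = NULL) {
  n <- length(v)
  noff <- n - L + 1L
  if (noff < 1L) return(NULL)
  ncols <- if (mode == "mono") L else L - 1L
  offs <- rep(0:(noff - 1L), each = 2L)
  strands <- rep(c("+", "-"), noff)
  M <- matrix(NA_integer_, 2L * noff, ncols)
  for (i in seq_len(noff)) {
    wv <- v[i:(i + L - 1L)]
    if (!anyNA(wv)) {
      fw <- if (mode == "mono") wv else dinuc_codes(wv)
      rv <- rc_int(wv)
      rw <- if (mode == "mono") rv else dinuc_codes(rv)
      M[2L * i - 1L, ] <- fw
      M[2L * i, ] <- rw
    }
  }
  keep <- !is.na(M[, 1])
  if (!any(keep)) return(NULL)
  w <- if (is.null(weight_profile)) rep(1, sum(keep)) else {
    mid <- offs + L %/% 2L
    round(pmax(weight_profile[mid + 1L], 1e-3), 2)[keep]
  }
  list(M = M[keep, , drop = FALSE], offset = offs[keep],
       strand = strands[keep], weight = w)
}

## Column-score table: T[j, a] = column j's KL contribution if a letter a
## with weight w is added to base counts C.
.add_letter_table <- function(C, N, q, pseudocount, w) {
  nb <- length(q)
  qm <- matrix(q, nrow(C), nb, byrow = TRUE)
  B <- C + pseudocount * qm
  tot <- N + pseudocount + w
  T <- matrix(0, nrow(C), nb)
  for (a in seq_len(nb)) {
    Ba <- B
    Ba[, a] <- Ba[, a] + w
    F <- Ba / tot
    T[, a] <- rowSums(F * log(F / qm))
  }
  T
}

#' Greedy KDIC/KDDIC motif discovery with bootstrapped multi-starts
#'
#' Each start seeds a gapless alignment from a bootstrap subsample of peaks
#' and then sweeps: for every peak, the (offset, strand) whose inclusion
#' maximises the alignment objective is swapped in, or the peak is dropped
#' when every placement lowers the objective (one occurrence per retained
#' peak). Sweeps stop at convergence or after `max_sweeps`. With
#' `use_shape`, each occurrence's column counts are weighted by the peak's
#' max-normalised coverage profile at the occurrence midpoint. The best
#' result over all starts is returned.
#'
#' @param peaks Peak tibble; an optional `profile` list-column holds
#'   per-base coverage for shape weighting.
#' @param L Motif length.
#' @param mode `"mono"` (KDIC, emits a `mono_pwm`) or `"di"` (KDDIC, emits a
#'   `di_pwm`).
#' @param n_starts Number of bootstrapped starts.
#' @param bootstrap_frac Fraction of peaks seeding each start.
#' @param use_shape Weight occurrences by the coverage profile.
#' @param seed Integer seed; deterministic under a fixed seed.
#' @param max_sweeps Sweep cap per start.
#' @param pseudocount Pseudocount mass for column frequencies.
#' @param id Identifier for the emitted matrix model.
#' @return An object of class `discovery_result`: `occurrences` tibble
#'   (`peak_id`, `offset`, `strand`, `weight`), `objective` (nats), `model`,
#'   `consensus`, and per-start objective `traces` (a list of monotone
#'   segments per start, one segment per accepted greedy/refinement
#'   phase).
#' @export
greedy_discover <- function(peaks, L, mode = c("mono", "di"), n_starts = 10,
                            bootstrap_frac = 0.5, use_shape = FALSE,
                            seed = 1L, max_sweeps = 100L, pseudocount = 1,
                            id = NULL) {
  mode <- match.arg(mode)
  if (is.null(id)) id <- if (mode == "mono") "kdic_pwm" else "kddic_dipwm"
  if (any(nchar(peaks$seq) < L)) stop("motif length exceeds a peak length", call. = FALSE)
  n <- nrow(peaks)
  ints <- lapply(toupper(peaks$seq), seq_to_int)
  ## background composition pooled over the peaks (smoothed)
  allv <- unlist(ints)
  allv <- allv[!is.na(allv)]
  if (mode == "mono") {
    q <- (tabulate(allv, 4L) + 1) / (length(allv) + 4)
  } else {
    alld <- unlist(lapply(ints, dinuc_codes))
    alld <- alld[!is.na(alld)]
    q <- (tabulate(alld, 16L) + 1) / (length(alld) + 16)
  }
  profiles <- if (use_shape && "profile" %in% names(peaks)) {
    lapply(peaks$profile, function(p) if (is.null(p)) NULL else p / max(p))
  } else {
    vector("list", n)
  }
  cands <- lapply(seq_len(n), function(i) {
    .peak_candidates(ints[[i]], L, mode, profiles[[i]])
  })
  usable <- which(!vapply(cands, is.null, logical(1)))
  if (length(usable) < 2L) stop("fewer than two peaks admit a window", call. = FALSE)
  ncols <- if (mode == "mono") L else L - 1L
  nb <- length(q)

  counts_of <- function(cur_cand) {
    C <- matrix(0, ncols, nb)
    N <- 0
    for (p in which(!is.na(cur_cand))) {
      ci <- cur_cand[p]
      w <- cands[[p]]$weight[ci]
      C[cbind(seq_len(ncols), cands[[p]]$M[ci, ])] <-
        C[cbind(seq_len(ncols), cands[[p]]$M[ci, ])] + w
      N <- N + w
    }
    list(C = C, N = N)
  }

  sweep_to_convergence <- function(cur_cand, trace) {
    cn <- counts_of(cur_cand)
    C <- cn$C; N <- cn$N
    prev <- NULL
    for (sweep in seq_len(max_sweeps)) {
      for (p in usable) {
        cp <- cands[[p]]
        if (!is.na(cur_cand[p])) {
          ci <- cur_cand[p]
          w <- cp$weight[ci]
          C[cbind(seq_len(ncols), cp$M[ci, ])] <-
            C[cbind(seq_len(ncols), cp$M[ci, ])] - w
          N <- N - w
          cur_cand[p] <- NA_integer_
        }
        obj_without <- (N + pseudocount) * .kl_sum(C, N, q, pseudocount)
        best_ci <- NA_integer_
        best_obj <- -Inf
        for (w in unique(cp$weight)) {
          rows <- which(cp$weight == w)
          T <- .add_letter_table(C, N, q, pseudocount, w)
          S <- numeric(length(rows))
          for (j in seq_len(ncols)) S <- S + T[j, cp$M[rows, j]]
          S <- (N + w + pseudocount) * S
          bi <- which.max(S)
          if (S[bi] > best_obj + 1e-12) {
            best_obj <- S[bi]
            best_ci <- rows[bi]
          }
        }
        force_in <- sum(!is.na(cur_cand)) < 2L
        if (force_in || best_obj >= obj_without - 1e-12) {
          cur_cand[p] <- best_ci
          w <- cp$weight[best_ci]
          C[cbind(seq_len(ncols), cp$M[best_ci, ])] <-
            C[cbind(seq_len(ncols), cp$M[best_ci, ])] + w
          N <- N + w
        }
      }
      trace <- c(trace, (N + pseudocount) * .kl_sum(C, N, q, pseudocount))
      if (!is.null(prev) && identical(prev, cur_cand)) break
      prev <- cur_cand
    }
    list(cur = cur_cand, obj = trace[length(trace)], trace = trace)
  }

  ## coherent phase shift of the whole alignment by delta motif columns;
  ## occurrences that cannot shift keep their place, candidates are looked
  ## up by (offset, strand)
  shift_alignment <- function(cur_cand, delta) {
    out <- cur_cand
    for (p in which(!is.na(cur_cand))) {
      cp <- cands[[p]]
      ci <- cur_cand[p]
      off <- cp$offset[ci]
      str <- cp$strand[ci]
      new_off <- if (str == "+") off + delta else off - delta
      j <- which(cp$offset == new_off & cp$strand == str)
      if (length(j) == 1L) out[p] <- j
    }
    out
  }

  run_start <- function() {
    seedset <- sample(usable, max(2L, ceiling(bootstrap_frac * length(usable))))
    cur_cand <- rep(NA_integer_, n)   # candidate row index per peak, NA = out
    for (p in seedset) {
      cur_cand[p] <- sample.int(nrow(cands[[p]]$M), 1L)
    }
    res <- sweep_to_convergence(cur_cand, numeric(0))
    segments <- list(res$trace)
    ## phase-shift refinement: escape frame-shifted local optima; each
    ## accepted refinement opens a new monotone trace segment
    repeat {
      improved <- FALSE
      for (delta in c(-2L, -1L, 1L, 2L)) {
        cand <- sweep_to_convergence(shift_alignment(res$cur, delta),
                                     numeric(0))
        if (cand$obj > res$obj + 1e-9) {
          res <- cand
          segments <- c(segments, list(cand$trace))
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    res$segments <- segments
    res
  }

  withr::with_seed(seed, {
    starts <- lapply(seq_len(n_starts), function(s) run_start())
  })
  objs <- vapply(starts, `[[`, numeric(1), "obj")
  best <- starts[[which.max(objs)]]
  inp <- which(!is.na(best$cur))
  occurrences <- tibble::tibble(
    peak_id = peaks$id[inp],
    offset = vapply(inp, function(p) cands[[p]]$offset[best$cur[p]], integer(1)),
    strand = vapply(inp, function(p) cands[[p]]$strand[best$cur[p]], character(1)),
    weight = vapply(inp, function(p) cands[[p]]$weight[best$cur[p]], numeric(1)))
  win <- .occurrence_windows(occurrences, peaks, L)
  model <- if (mode == "mono") {
    build_mono_pwm(win, q = q, pseudocount = pseudocount, id = id)
  } else {
    build_di_pwm(win, Q = q, pseudocount = pseudocount, id = id)
  }
  counts <- .weighted_counts(win, occurrences$weight, 4L, function(v) v)
  consensus <- paste(.BASES[apply(counts, 1, which.max)], collapse = "")
  objective <- if (mode == "mono") {
    kdic(occurrences, peaks, L, q = q, pseudocount = pseudocount)
  } else {
    kddic(occurrences, peaks, L, Q = q, pseudocount = pseudocount)
  }
  structure(list(occurrences = occurrences, objective = objective,
                 objective_total = best$obj,
                 mode = mode, L = as.integer(L), q = q,
                 pseudocount = pseudocount, model = model,
                 consensus = consensus,
                 traces = lapply(starts, `[[`, "segments")),
            class = "discovery_result")
}

#' @export
print.discovery_result <- function(x, ...) {
  cat(sprintf("<discovery_result> %s, L=%d, %d occurrences, KDIC %.3f nats (total %.1f), consensus %s\n",
              x$mode, x$L, nrow(x$occurrences), x$objective,
              x$objective_total, x$consensus))
  invisible(x)
}

#' Optimise discovered motif length by held-out false-positive rate
#'
#' Runs [greedy_discover()] at each candidate length and selects the length
#' minimising the leave-one-out false-positive rate at a fixed true-positive
#' anchor, with the discovered occurrence windows as positives (the same
#' scheme as [optimize_length()]). Ties go to the shorter motif.
#'
#' @inheritParams greedy_discover
#' @param L_range Candidate motif lengths.
#' @param background_peaks Background peaks for FP estimation; by default a
#'   1-fold order-1 Markov shuffle of `peaks`.
#' @param tp_anchor Held-out true-positive fraction anchoring the threshold.
#' @param ... Passed to [greedy_discover()].
#' @return List with `best_length`, `result` (the discovery at that length)
#'   and the per-length `table`.
#' @export
optimize_discovered_length <- function(peaks, L_range, mode = c("mono", "di"),
                                       seed = 1L, background_peaks = NULL,
                                       tp_anchor = 0.9, ...) {
  mode <- match.arg(mode)
  stopifnot(length(L_range) >= 1L)
  if (is.null(background_peaks)) {
    background_peaks <- make_shuffled_background(peaks, order = 1L,
                                                 n_fold = 1L,
                                                 seed = derive_seed(seed, "bg"))
  }
  bg_int <- lapply(toupper(background_peaks$seq), seq_to_int)
  results <- list()
  rows <- purrr::map(sort(unique(as.integer(L_range))), function(L) {
    res <- greedy_discover(peaks, L, mode = mode,
                           seed = derive_seed(seed, paste0("L", L)), ...)
    results[[as.character(L)]] <<- res
    win <- .occurrence_windows(res$occurrences, peaks, L)
    N <- length(win)
    loo <- vapply(seq_len(N), function(i) {
      mdl <- if (mode == "mono") {
        build_mono_pwm(win[-i], q = res$q, pseudocount = res$pseudocount)
      } else {
        build_di_pwm(win[-i], Q = res$q, pseudocount = res$pseudocount)
      }
      rescale_score(mdl, pmin(mdl$s_max, pmax(mdl$s_min,
        score_window(mdl, win[i]))))
    }, numeric(1))
    thr <- sort(loo, decreasing = TRUE)[ceiling(tp_anchor * N)]
    bg_scores <- unlist(lapply(bg_int, function(v) {
      c(.window_scores_int(res$model, v),
        .window_scores_int(res$model, rc_int(v)))
    }))
    bg_scores <- bg_scores[!is.na(bg_scores)]
    tibble::tibble(length = L, objective = res$objective, threshold = thr,
                   fp_rate = if (length(bg_scores)) mean(bg_scores >= thr)
                             else NA_real_)
  })
  table <- dplyr::bind_rows(rows)
  best <- table$length[which.min(table$fp_rate)]
  list(best_length = best, result = results[[as.character(best)]],
       table = table)
}

#' Write discovered occurrences as TSV
#'
#' @param result A `discovery_result`.
#' @param path Output path (`peak_id`, `offset`, `strand`, `weight`).
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(result, path) {
  readr::write_tsv(result$occurrences, path, progress = FALSE)
  invisible(path)
}

#' Text sequence-logo summary of a discovery result
#'
#' @param result A `discovery_result`.
#' @param peaks The peak tibble the discovery ran on.
#' @return Character vector: consensus line plus one line per column with
#'   base frequencies and the column's information contribution (nats).
#' @export
discovery_logo <- function(result, peaks) {
  win <- .occurrence_windows(result$occurrences, peaks, result$L)
  counts <- .weighted_counts(win, result$occurrences$weight, 4L,
                             function(v) v)
  W <- sum(result$occurrences$weight)
  qmono <- if (result$mode == "mono") result$q else rep(0.25, 4)
  f <- (counts + result$pseudocount * matrix(qmono, result$L, 4, byrow = TRUE)) /
    (W + result$pseudocount)
  ic <- rowSums(f * log(f / matrix(qmono, result$L, 4, byrow = TRUE)))
  cons <- strsplit(result$consensus, "")[[1]]
  c(sprintf("consensus %s (objective %.3f nats, %d occurrences)",
            result$consensus, result$objective, nrow(result$occurrences)),
    sprintf("col %2d %s  A %.2f C %.2f G %.2f T %.2f  IC %.3f",
            seq_len(result$L), cons, f[, 1], f[, 2], f[, 3], f[, 4], ic))
}
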