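## Synthetic data with known ground truth: Markov background peaks with
## implanted motif instances, aligned training sites, and noisy EMSA
## competition curves.

.IUPAC_LETTERS <- Biostrings::IUPAC_CODE_MAP

#' Ground-truth motif for simulations
#'
#' Builds a probabilistic motif from per-column probabilities, recording the
#' IUPAC core consensus the columns are anchored on.
#'
#' @param column_probs L x 4 matrix of column probabilities (columns A,C,G,T),
#'   each row summing to 1.
#' @param core_consensus IUPAC string locating the conserved core.
#' @param core_offset 0-based offset of the core within the motif.
#' @param dinuc_probs Optional (L-1) x 16 matrix of conditional dinucleotide
#'   probabilities `P(next | current)` arranged as 16 columns AA..TT; when
#'   present, sites are drawn as a first-order chain instead of
#'   column-independently.
#' @return An object of class `ground_truth_motif`.
#' @export
ground_truth_motif <- function(column_probs,
                               core_consensus = "TRTTTRYH",
                               core_offset = 0L,
                               dinuc_probs = NULL) {
  column_probs <- as.matrix(column_probs)
  stopifnot(ncol(column_probs) == 4L,
            all(abs(rowSums(column_probs) - 1) < 1e-9))
  L <- nrow(column_probs)
  stopifnot(core_offset >= 0L, core_offset + nchar(core_consensus) <= L)
  ## high-probability letters must be compatible with the consensus
  for (j in seq_len(nchar(core_consensus))) {
    code <- substr(core_consensus, j, j)
    allowed <- match(strsplit(.IUPAC_LETTERS[[code]], "")[[1]], .BASES)
    if (sum(column_probs[core_offset + j, allowed]) < 0.5) {
      stop(sprintf("core column %d incompatible with consensus letter %s",
                   j, code), call. = FALSE)
    }
  }
  structure(list(L = L, column_probs = column_probs,
                 core_consensus = core_consensus,
                 core_offset = as.integer(core_offset),
                 dinuc_probs = dinuc_probs),
            class = "ground_truth_motif")
}

#' @export
print.ground_truth_motif <- function(x, ...) {
  cat(sprintf("<ground_truth_motif> length %d, core %s at offset %d%s\n",
              x$L, x$core_consensus, x$core_offset,
              if (is.null(x$dinuc_probs)) "" else ", first-order generator"))
  invisible(x)
}

#' Default FoxA-like ground-truth motif
#'
#' Twelve columns: an 8-bp TRTTTRYH core (consensus-compatible letters
#' sharing probability mass `core_mass`, split evenly over the degenerate
#' letters) flanked by two mildly informative columns on each side. At the
#' default core mass 0.85 the motif carries about 6.3 bits; the
#' consensus-concentrated variants used for recovery studies
#' (`core_mass = 0.95`-`0.97`) carry 9-10 bits.
#'
#' @param core_mass Probability mass on consensus-compatible letters in core
#'   columns.
#' @return A `ground_truth_motif` of length 12.
#' @export
default_foxa_motif <- function(core_mass = 0.85) {
  core <- "TRTTTRYH"
  rows <- lapply(strsplit(core, "")[[1]], function(code) {
    allowed <- match(strsplit(.IUPAC_LETTERS[[code]], "")[[1]], .BASES)
    p <- rep((1 - core_mass) / (4 - length(allowed)), 4)
    p[allowed] <- core_mass / length(allowed)
    p
  })
  ## flank preferences are deliberately non-self-complementary as a set
  ## (A,G ... G,A), so the reverse-complement motif has a different flank
  ## signature and strand-mixed alignments gain nothing from the flanks
  flank_left <- list(c(0.4, 0.2, 0.2, 0.2),  # mild A preference
                     c(0.2, 0.2, 0.4, 0.2))  # mild G preference
  flank_right <- list(c(0.2, 0.2, 0.4, 0.2), # mild G preference
                      c(0.4, 0.2, 0.2, 0.2)) # mild A preference
  probs <- do.call(rbind, c(flank_left, rows, flank_right))
  ground_truth_motif(probs, core_consensus = core, core_offset = 2L)
}

#' Fit a Markov chain to a set of sequences
#'
#' Order 0 or 1, with add-one smoothing of transition counts. Positions with
#' non-ACGT letters are skipped.
#'
#' @param seqs Character vector of DNA strings.
#' @param order Chain order, 0 or 1.
#' @return An object of class `markov_model` with fields `order`, `p0`
#'   (initial/marginal distribution) and, for order 1, a 4 x 4 row-stochastic
#'   `transition` matrix.
#' @export
fit_markov <- function(seqs, order = 1L) {
  if (length(seqs) == 0L || all(nchar(seqs) == 0L)) {
    stop("cannot fit a Markov model to empty input", call. = FALSE)
  }
  if (!order %in% c(0L, 1L)) stop("unsupported order (must be 0 or 1)", call. = FALSE)
  ints <- lapply(toupper(seqs), seq_to_int)
  mono <- tabulate(unlist(ints)[!is.na(unlist(ints))], nbins = 4L)
  p0 <- (mono + 1) / sum(mono + 1)
  if (order == 0L) {
    return(structure(list(order = 0L, p0 = p0), class = "markov_model"))
  }
  counts <- matrix(0, 4, 4, dimnames = list(.BASES, .BASES))
  for (v in ints) {
    if (length(v) < 2L) next
    d <- dinuc_codes(v)
    d <- d[!is.na(d)]
    if (length(d)) {
      t16 <- tabulate(d, nbins = 16L)
      counts <- counts + matrix(t16, 4, 4, byrow = TRUE)
    }
  }
  trans <- (counts + 1) / rowSums(counts + 1)
  structure(list(order = 1L, p0 = p0, transition = trans),
            class = "markov_model")
}

# Draw n sequences of the given length from a markov_model (integer matrix
# n x length).
.draw_markov_int <- function(model, n, length) {
  out <- matrix(0L, n, length)
  out[, 1] <- sample.int(4L, n, replace = TRUE, prob = model$p0)
  if (model$order == 0L) {
    if (length > 1L) {
      out[, -1] <- sample.int(4L, n * (length - 1L), replace = TRUE,
                              prob = model$p0)
    }
    return(out)
  }
  if (length > 1L) {
    u <- matrix(stats::runif(n * (length - 1L)), n, length - 1L)
    cum <- t(apply(model$transition, 1, cumsum))
    for (j in 2:length) {
      prev <- out[, j - 1L]
      uu <- u[, j - 1L]
      nxt <- 1L + (uu > cum[prev, 1]) + (uu > cum[prev, 2]) + (uu > cum[prev, 3])
      out[, j] <- nxt
    }
  }
  out
}

#' Generate Markov background peaks
#'
#' Draws `n` sequences from a fitted Markov chain and attaches read-coverage
#' heights sampled from a shifted negative binomial, emulating ChIP-Seq peak
#' sets after a coverage filter.
#'
#' @param model A `markov_model` from [fit_markov()].
#' @param n Number of peaks.
#' @param length Peak length in bp (scalar or vector of length `n`).
#' @param seed Integer seed; fixed seed gives identical output.
#' @param min_height Minimum height (the shift), default 15 as in
#'   coverage-filtered mouse liver data.
#' @param height_size,height_mu Negative binomial size and mean for the
#'   height excess above `min_height`.
#' @param id_prefix Prefix for generated peak ids.
#' @return A peak tibble (`id`, `seq`, `height`).
#' @export
generate_background <- function(model, n, length, seed = 1L,
                                min_height = 15, height_size = 2,
                                height_mu = 25, id_prefix = "peak") {
  stopifnot(n >= 1L)
  lens <- rep_len(as.integer(length), n)
  withr::with_seed(seed, {
    heights <- min_height + stats::rnbinom(n, size = height_size, mu = height_mu)
    seqs <- character(n)
    for (len in unique(lens)) {
      idx <- which(lens == len)
      m <- .draw_markov_int(model, length(idx), len)
      seqs[idx] <- apply(m, 1, int_to_seq)
    }
  })
  tibble::tibble(id = sprintf("%s%04d", id_prefix, seq_len(n)),
                 seq = seqs, height = as.numeric(heights))
}

# Draw one site string from a ground-truth motif.
.draw_site <- function(motif) {
  if (!is.null(motif$dinuc_probs)) {
    v <- integer(motif$L)
    v[1] <- sample.int(4L, 1L, prob = motif$column_probs[1, ])
    for (j in 2:motif$L) {
      p <- motif$dinuc_probs[j - 1L, 4L * (v[j - 1L] - 1L) + 1:4]
      v[j] <- sample.int(4L, 1L, prob = p)
    }
    return(int_to_seq(v))
  }
  v <- vapply(seq_len(motif$L), function(j) {
    sample.int(4L, 1L, prob = motif$column_probs[j, ])
  }, integer(1))
  int_to_seq(v)
}

#' Implant motif instances into background peaks
#'
#' Each peak receives a number of sites drawn from `sites_per_peak` (a single
#' count, or a named numeric vector of probabilities over counts, e.g.
#' `c("1" = 0.4, "2" = 0.4, "3" = 0.2)` for homotypic clusters). Sites are
#' drawn from the motif, placed uniformly at random without overlapping one
#' another, on a uniformly chosen strand; ground truth is recorded.
#'
#' @param peaks A peak tibble.
#' @param motif A `ground_truth_motif`, or a list of motifs sampled uniformly
#'   per site (motif subtypes).
#' @param sites_per_peak Scalar count or named probability vector.
#' @param seed Integer seed.
#' @param max_tries Placement attempts per site before giving up.
#' @return A list of class `synthetic_peak_set` with elements `peaks`
#'   (sequences with implants) and `truth`
#'   (tibble `peak_id`, `start`, `strand`, `site`, `motif`).
#' @export
implant_sites <- function(peaks, motif, sites_per_peak = 1, seed = 1L,
                          max_tries = 200L) {
  motifs <- if (inherits(motif, "ground_truth_motif")) list(motif) else motif
  stopifnot(all(vapply(motifs, inherits, logical(1), "ground_truth_motif")))
  Lmax <- max(vapply(motifs, `[[`, integer(1), "L"))
  if (any(nchar(peaks$seq) < Lmax)) {
    stop("motif length exceeds a peak length", call. = FALSE)
  }
  withr::with_seed(seed, {
    counts <- if (length(sites_per_peak) == 1L && is.null(names(sites_per_peak))) {
      rep.int(as.integer(sites_per_peak), nrow(peaks))
    } else {
      sample(as.integer(names(sites_per_peak)), nrow(peaks), replace = TRUE,
             prob = sites_per_peak)
    }
    truth <- vector("list", nrow(peaks))
    seqs <- peaks$seq
    for (i in seq_len(nrow(peaks))) {
      k <- counts[i]
      if (k == 0L) { truth[[i]] <- NULL; next }
      plen <- nchar(seqs[i])
      placed <- integer(0)      # starts (0-based)
      placed_len <- integer(0)
      rows <- vector("list", k)
      for (s in seq_len(k)) {
        mi <- if (length(motifs) == 1L) 1L else sample.int(length(motifs), 1L)
        m <- motifs[[mi]]
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          st <- sample.int(plen - m$L + 1L, 1L) - 1L
          if (!any(st < placed + placed_len & placed < st + m$L)) { ok <- TRUE; break }
        }
        if (!ok) {
          stop(sprintf("could not place %d non-overlapping sites in peak %s",
                       k, peaks$id[i]), call. = FALSE)
        }
        strand <- sample(c("+", "-"), 1L)
        site <- .draw_site(m)
        ins <- if (strand == "+") site else reverse_complement(site)
        substr(seqs[i], st + 1L, st + m$L) <- ins
        placed <- c(placed, st)
        placed_len <- c(placed_len, m$L)
        rows[[s]] <- tibble::tibble(peak_id = peaks$id[i], start = st,
                                    strand = strand, site = site, motif = mi)
      }
      truth[[i]] <- dplyr::bind_rows(rows)
    }
  })
  out_peaks <- peaks
  out_peaks$seq <- seqs
  structure(list(peaks = out_peaks,
                 truth = dplyr::bind_rows(truth)),
            class = "synthetic_peak_set")
}

#' @export
print.synthetic_peak_set <- function(x, ...) {
  cat(sprintf("<synthetic_peak_set> %d peaks, %d implanted sites\n",
              nrow(x$peaks), nrow(x$truth)))
  invisible(x)
}

#' Generate an aligned training-site set from a ground-truth motif
#'
#' Emulates a curated alignment of confirmed sites (such as the 53 FoxA sites
#' aligned on TRTTTRYH): core columns drawn from the motif, flanks from a
#' background chain.
#'
#' @param motif A `ground_truth_motif`.
#' @param n Number of sites (>= 2).
#' @param flank_len Background flank length added on each side.
#' @param seed Integer seed.
#' @param background Optional `markov_model` for the flanks (default uniform
#'   order 0).
#' @return An [aligned_sites()] object of width `motif$L + 2 * flank_len`.
#' @export
generate_training_sites <- function(motif, n, flank_len = 0L, seed = 1L,
                                    background = NULL) {
  stopifnot(n >= 2L)
  if (is.null(background)) {
    background <- structure(list(order = 0L, p0 = rep(0.25, 4)),
                            class = "markov_model")
  }
  withr::with_seed(seed, {
    cores <- vapply(seq_len(n), function(i) .draw_site(motif), character(1))
    if (flank_len > 0L) {
      lf <- apply(.draw_markov_int(background, n, flank_len), 1, int_to_seq)
      rf <- apply(.draw_markov_int(background, n, flank_len), 1, int_to_seq)
      seqs <- paste0(lf, cores, rf)
    } else {
      seqs <- cores
    }
  })
  aligned_sites(seqs, core_offset = flank_len + motif$core_offset,
                core_len = nchar(motif$core_consensus))
}

#' Simulate an EMSA competition panel
#'
#' For a competitor oligo with true relative affinity `A`, the band intensity
#' at competitor concentration `c` declines linearly in `ln c`:
#' `I(c) = I0 * (1 - A * s0 * ln c) * eps`, with one multiplicative
#' lognormal factor `eps` per competitor series (gel-to-gel variation
#' shared across the lanes of one curve). The positive control (affinity 1)
#' self-competition sets the slope scale, so the downstream slope-ratio
#' estimator recovers `A` exactly at zero noise, and noise enters the score
#' multiplicatively rather than through the slope itself.
#'
#' @param oligos Tibble with columns `id` and `affinity` (true relative
#'   affinity, >= 0), optionally `seq`. Exactly one row must have
#'   `id == control_id`, with affinity 1.
#' @param concentrations Competitor concentrations in ng (default the
#'   standard 2, 5, 20 series).
#' @param noise_sd Lognormal noise sd (0 for noiseless curves).
#' @param seed Integer seed.
#' @param control_id Id of the self-competition positive control.
#' @param I0 Baseline band intensity.
#' @param s0 Slope scale of the control; kept small enough that intensities
#'   stay positive over the concentration range.
#' @return A long tibble (`oligo_id`, `conc_ng`, `intensity`) of class
#'   `emsa_curves`, with the control id in attribute `control_id`.
#' @export
simulate_emsa_panel <- function(oligos, concentrations = c(2, 5, 20),
                                noise_sd = 0.05, seed = 1L,
                                control_id = "control", I0 = 100, s0 = 0.2) {
  stopifnot(length(concentrations) >= 2L, noise_sd >= 0)
  if (any(concentrations <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  if (sum(oligos$id == control_id) != 1L) {
    stop("exactly one control oligo required", call. = FALSE)
  }
  if (abs(oligos$affinity[oligos$id == control_id] - 1) > 1e-9) {
    stop("control oligo must have affinity 1", call. = FALSE)
  }
  stopifnot(all(oligos$affinity >= 0))
  grid <- tidyr::expand_grid(oligo_id = oligos$id, conc_ng = concentrations)
  grid <- dplyr::left_join(grid,
                           dplyr::select(oligos, oligo_id = "id", "affinity"),
                           by = "oligo_id")
  withr::with_seed(seed, {
    eps_oligo <- if (noise_sd > 0) {
      stats::setNames(stats::rlnorm(nrow(oligos), 0, noise_sd), oligos$id)
    } else {
      stats::setNames(rep(1, nrow(oligos)), oligos$id)
    }
    eps <- unname(eps_oligo[grid$oligo_id])
    intensity <- I0 * (1 - grid$affinity * s0 * log(grid$conc_ng)) * eps
  })
  intensity <- pmax(intensity, I0 * 1e-4)
  out <- tibble::tibble(oligo_id = grid$oligo_id, conc_ng = grid$conc_ng,
                        intensity = intensity)
  attr(out, "control_id") <- control_id
  class(out) <- c("emsa_curves", class(out))
  out
}

#' Design a synthetic EMSA oligo panel with known affinities
#'
#' Builds competitor oligos spanning the affinity range: strong sites are
#' intact motif draws, weak sites are draws degraded by a few core point
#' mutations, non-sites are background cores conditioned to carry low true
#' binding energy (random draws are rejected while their generator-motif
#' score exceeds `nonsite_max_score`, keeping the assigned affinity
#' consistent with the generator's energetics — a non-binder cannot look
#' like a perfect site when the model is the generator). True relative
#' affinities are drawn from class-specific ranges (strong > 0.75, weak
#' 0.3-0.7, non-site < 0.2), so the panel brackets the 0.25 non-site bin
#' edge. One extra control oligo (an intact draw with affinity exactly 1)
#' is appended.
#'
#' @param motif A `ground_truth_motif`.
#' @param n_strong,n_weak,n_nonsite Class sizes.
#' @param mut_weak Core mutations applied to weak oligos.
#' @param nonsite_max_score Upper bound on a non-site core's generator-motif
#'   rescaled score (better strand).
#' @param flank_len Background flank added on each side of the core.
#' @param seed Integer seed.
#' @param control_id Id given to the control oligo.
#' @return Tibble (`id`, `seq`, `core_start`, `affinity`, `class`) ready
#'   for [simulate_emsa_panel()]; `core_start` is the 0-based offset of the
#'   embedded candidate site.
#' @export
make_emsa_oligo_panel <- function(motif, n_strong = 5, n_weak = 5,
                                  n_nonsite = 6, mut_weak = 3L,
                                  nonsite_max_score = 0.7, flank_len = 6,
                                  seed = 1L, control_id = "control") {
  true_pwm <- motif_to_pwm(motif)
  core_score <- function(core) {
    max(rescale_score(true_pwm, score_window(true_pwm, core)),
        rescale_score(true_pwm, score_window(true_pwm, core, strand = "-")))
  }
  withr::with_seed(seed, {
    flanks <- function() {
      int_to_seq(sample.int(4L, flank_len, replace = TRUE))
    }
    mutate_core <- function(s, k) {
      pos <- sample.int(nchar(s), k)
      v <- seq_to_int(s)
      for (p in pos) v[p] <- sample(setdiff(1:4, v[p]), 1L)
      int_to_seq(v)
    }
    mk <- function(class, i) {
      core <- .draw_site(motif)
      if (class == "weak") core <- mutate_core(core, mut_weak)
      if (class == "nonsite") {
        for (try in 1:200) {
          core <- int_to_seq(sample.int(4L, motif$L, replace = TRUE))
          if (core_score(core) <= nonsite_max_score) break
        }
      }
      aff <- switch(class,
                    strong = stats::runif(1, 0.8, 1.2),
                    weak = stats::runif(1, 0.3, 0.7),
                    nonsite = stats::runif(1, 0, 0.2))
      tibble::tibble(id = sprintf("%s%02d", class, i),
                     seq = paste0(flanks(), core, flanks()),
                     core_start = as.integer(flank_len),
                     affinity = aff, class = class)
    }
    rows <- c(lapply(seq_len(n_strong), function(i) mk("strong", i)),
              lapply(seq_len(n_weak), function(i) mk("weak", i)),
              lapply(seq_len(n_nonsite), function(i) mk("nonsite", i)))
    ctl <- tibble::tibble(id = control_id,
                          seq = paste0(flanks(), .draw_site(motif), flanks()),
                          core_start = as.integer(flank_len),
                          affinity = 1, class = "control")
  })
  dplyr::bind_rows(c(rows, list(ctl)))
}

#' Score panel oligos at their embedded site
#'
#' Each verification oligo carries one candidate site at a known placement;
#' its model score is the rescaled score of that window on its better
#' strand (the per-site score a verification table lists, as opposed to the
#' best window anywhere in the oligo).
#'
#' @param panel Tibble from [make_emsa_oligo_panel()] (columns `id`, `seq`,
#'   `core_start`).
#' @param model A fitted model whose width matches the embedded site.
#' @return Tibble (`oligo_id`, `model_score`).
#' @export
score_panel_oligos <- function(panel, model) {
  L <- model_width(model)
  win <- substring(panel$seq, panel$core_start + 1L, panel$core_start + L)
  score1 <- function(w, strand) {
    raw <- score_window(model, w, strand)
    if (inherits(model, "pwm_model")) {
      rescale_score(model, pmin(model$s_max, pmax(model$s_min, raw)))
    } else {
      raw
    }
  }
  tibble::tibble(
    oligo_id = panel$id,
    model_score = vapply(win, function(w) {
      max(score1(w, "+"), score1(w, "-"))
    }, numeric(1), USE.NAMES = FALSE))
}

#' Exact PWM of a ground-truth motif
#'
#' Builds the mononucleotide log-odds matrix directly from the generator''s
#' true column probabilities (no training sample), useful as the
#' model-equals-generator reference in calibration studies.
#'
#' @param motif A `ground_truth_motif`.
#' @param q Background base composition.
#' @param id Model identifier.
#' @return A `mono_pwm`.
#' @export
motif_to_pwm <- function(motif, q = rep(0.25, 4), id = "true_motif_pwm") {
  w <- log(motif$column_probs / matrix(q, motif$L, 4, byrow = TRUE))
  s_min <- sum(apply(w, 1, min))
  s_max <- sum(apply(w, 1, max))
  structure(list(type = "mono", L = motif$L, weights = w, q = q,
                 s_min = s_min, s_max = s_max, id = id),
            class = c("mono_pwm", "pwm_model", "tfbs_model"))
}

#' Select verification oligos from model predictions
#'
#' Emulates the verification workflow of threshold calibration: candidate
#' binding sites are the models' own top-scoring predictions within the
#' peaks; each predicted window is classified against the implant ground
#' truth. Windows covering at least half of an implanted site are binders
#' (true relative affinity drawn from 0.3-1.2, spanning weak and strong
#' bins); predictions with no implant support are non-binders (affinity
#' below 0.2). Oligos carry the prediction plus flanking peak context, and
#' one strong binder is duplicated as the self-competition control with
#' affinity exactly 1.
#'
#' @param peak_set A `synthetic_peak_set` from [implant_sites()] (peaks plus
#'   truth).
#' @param models Named list of fitted models whose predictions seed the
#'   panel.
#' @param n_nonsite,n_binder Numbers of non-binder and binder oligos
#'   (capped by availability in the prediction pool).
#' @param flank_len Peak context added on each side of the predicted
#'   window.
#' @param seed Integer seed (oligo sampling and affinity draws).
#' @param control_id Id given to the control oligo.
#' @return Tibble (`id`, `seq`, `affinity`, `class`) ready for
#'   [simulate_emsa_panel()]; `class` is `binder`/`nonbinder`/`control`.
#' @export
select_verification_oligos <- function(peak_set, models, n_nonsite = 20,
                                       n_binder = 44, flank_len = 6,
                                       seed = 1L, control_id = "control") {
  peaks <- peak_set$peaks
  truth <- peak_set$truth
  ## one predicted site per peak per model: the locus-level best window
  cand <- purrr::imap(models, function(m, nm) {
    h <- scan_peaks(peaks, m, threshold = 0)
    h <- dplyr::slice_max(dplyr::group_by(h, .data$peak_id), .data$score,
                          n = 1L, with_ties = FALSE)
    h <- dplyr::ungroup(h)
    h$L <- model_width(m)
    h
  })
  cand <- dplyr::bind_rows(cand)
  ## classify predictions against implant ground truth
  site_len <- nchar(truth$site[1])
  cand$binder <- vapply(seq_len(nrow(cand)), function(i) {
    tr <- truth[truth$peak_id == cand$peak_id[i], ]
    if (nrow(tr) == 0L) return(FALSE)
    ov <- pmin(cand$start[i] + cand$L[i], tr$start + site_len) -
      pmax(cand$start[i], tr$start)
    any(ov >= ceiling(site_len / 2))
  }, logical(1))
  ## de-duplicate near-identical windows across models
  key <- paste(cand$peak_id, round(cand$start / 4))
  cand <- cand[!duplicated(key), ]
  withr::with_seed(seed, {
    pick <- function(df, n) {
      if (nrow(df) == 0L) return(df)
      df[sample.int(nrow(df), min(n, nrow(df))), ]
    }
    nb <- pick(cand[!cand$binder, ], n_nonsite)
    bd <- pick(cand[cand$binder, ], n_binder)
    if (nrow(nb) == 0L || nrow(bd) == 0L) {
      stop("prediction pool lacks binders or non-binders; enlarge the peak set",
           call. = FALSE)
    }
    max_w <- max(vapply(models, model_width, integer(1)))
    mk_seq <- function(df) {
      i <- match(df$peak_id, peaks$id)
      plen <- nchar(peaks$seq[i])
      need <- pmin(pmax(df$L, max_w) + 2L * flank_len, plen)
      centre <- df$start + df$L %/% 2L
      from <- pmax(0L, pmin(centre - need %/% 2L, plen - need))
      substring(peaks$seq[i], from + 1L, from + need)
    }
    out <- dplyr::bind_rows(
      tibble::tibble(id = sprintf("pred_ns%02d", seq_len(nrow(nb))),
                     seq = mk_seq(nb),
                     affinity = stats::runif(nrow(nb), 0, 0.2),
                     class = "nonbinder"),
      tibble::tibble(id = sprintf("pred_bd%02d", seq_len(nrow(bd))),
                     seq = mk_seq(bd),
                     affinity = stats::runif(nrow(bd), 0.3, 1.2),
                     class = "binder"),
      tibble::tibble(id = control_id, seq = mk_seq(bd[1, ]),
                     affinity = 1, class = "control"))
  })
  out
}

#' Write the ground truth of a synthetic peak set
#'
#' @param x A `synthetic_peak_set`.
#' @param path Output TSV path (`peak_id`, `start`, `strand`, `site`).
#' @return `path`, invisibly.
#' @export
write_truth <- function(x, path) {
  readr::write_tsv(x$truth, path, progress = FALSE)
  invisible(path)
}
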