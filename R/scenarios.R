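## Purpose-built simulation scenarios for the comparative questions the
## benchmark suite answers: nearest-neighbour dependence (di- vs
## mononucleotide matrices), distant-position dependence (SiteGA vs PWM),
## motif subtype mixtures (model combinations), and enforced homotypic
## clusters (chance-overlap test). Each scenario fixes its own study
## conditions; runners return the summary statistics of one seeded run.

#' Build a simple ground-truth motif from a consensus
#'
#' Core columns put `core_mass` on the consensus-compatible letters (split
#' over IUPAC degeneracy); flank columns are uniform.
#'
#' @param consensus IUPAC consensus of the core.
#' @param core_mass Probability mass on consensus-compatible letters.
#' @param flank Number of uniform flank columns on each side.
#' @return A `ground_truth_motif`.
#' @export
make_simple_motif <- function(consensus, core_mass = 0.95, flank = 2L) {
  rows <- lapply(strsplit(consensus, "")[[1]], function(code) {
    allowed <- match(strsplit(.IUPAC_LETTERS[[code]], "")[[1]], .BASES)
    p <- rep((1 - core_mass) / max(1L, 4 - length(allowed)), 4)
    if (length(allowed) == 4L) p <- rep(0, 4)
    p[allowed] <- core_mass / length(allowed) +
      if (length(allowed) == 4L) (1 - core_mass) / 4 else 0
    p
  })
  uni <- replicate(flank, rep(0.25, 4), simplify = FALSE)
  probs <- do.call(rbind, c(uni, rows, uni))
  ground_truth_motif(probs, core_consensus = consensus, core_offset = flank)
}

#' First-order dependent motif with uniform marginals
#'
#' Sites are drawn as a chain: each letter repeats the previous one with
#' probability `stay`, otherwise switches uniformly. The stationary
#' distribution is uniform, so every mononucleotide column is at
#' background — the signal lives entirely in adjacent-letter transitions.
#'
#' @param L Motif length.
#' @param stay Repeat probability (0.25 = independence).
#' @return A `ground_truth_motif` with a dinucleotide generator.
#' @export
make_dependent_motif <- function(L = 12L, stay = 0.6) {
  cols <- matrix(0.25, L, 4)
  dn <- matrix((1 - stay) / 3, L - 1L, 16)
  for (a in 1:4) dn[, 4L * (a - 1L) + a] <- stay
  ground_truth_motif(cols, core_consensus = strrep("N", L), core_offset = 0L,
                     dinuc_probs = dn)
}

## Uniform-background peaks of one length.
.uniform_peaks <- function(n, len, seed, id_prefix = "peak") {
  chain <- structure(list(order = 0L, p0 = rep(0.25, 4)),
                     class = "markov_model")
  generate_background(chain, n, len, seed = seed, id_prefix = id_prefix)
}

#' Dinucleotide-dependence benchmark run
#'
#' Trains a mononucleotide and a dinucleotide matrix on sites generated
#' with first-order dependence but uniform marginals, implants such sites
#' in uniform peaks, and compares peak-level ROC AUCs against an order-1
#' shuffled background. The dinucleotide matrix can see the transition
#' signal; the mononucleotide matrix cannot.
#'
#' @param seed Integer seed.
#' @param n_train Training sites.
#' @param n_peaks Real peaks (equally many shuffles).
#' @param peak_len Peak length (bp).
#' @param stay Repeat probability of the dependent motif generator.
#' @return List with `auc_mono`, `auc_di`.
#' @export
run_dinuc_dependence_experiment <- function(seed, n_train = 100L,
                                            n_peaks = 150L, peak_len = 100L,
                                            stay = 0.6) {
  motif <- make_dependent_motif(stay = stay)
  sites <- generate_training_sites(motif, n_train,
                                   seed = derive_seed(seed, "sites"))
  mono <- build_mono_pwm(sites, id = "mono")
  di <- build_di_pwm(sites, id = "di")
  bg <- .uniform_peaks(n_peaks, peak_len, derive_seed(seed, "peaks"))
  ps <- implant_sites(bg, motif, sites_per_peak = 1,
                      seed = derive_seed(seed, "implant"))
  shuf <- make_shuffled_background(ps$peaks, order = 1L, n_fold = 1L,
                                   seed = derive_seed(seed, "shuffle"))
  list(auc_mono = roc_curve(ps$peaks, shuf, mono)$auc,
       auc_di = roc_curve(ps$peaks, shuf, di)$auc)
}

#' Draw sites with a long-range position dependence
#'
#' Letters are uniform except for two distant, perfectly correlated
#' homopolymer runs: the run at `pos1` is four copies of a base X (drawn
#' stratified so the sample marginals are exactly uniform), the run at
#' `pos2` four copies of a paired base (A<->C, G<->T).
#' Every mononucleotide marginal stays uniform and the two runs use
#' different bases (balanced composition), so a matrix model sees pure
#' background, while locally positioned dinucleotide features pick up the
#' runs.
#'
#' @param n Number of sites.
#' @param L Site width.
#' @param pos1,pos2 0-based run start positions.
#' @param seed Integer seed.
#' @return Character vector of sites.
#' @export
draw_distant_dependent_sites <- function(n, L = 16L, pos1 = 2L, pos2 = 10L,
                                         seed = 1L) {
  sigma <- c(2L, 1L, 4L, 3L)  # A<->C, G<->T
  stopifnot(pos2 >= pos1 + 4L, pos2 + 4L <= L)
  withr::with_seed(seed, {
    m <- matrix(sample.int(4L, n * L, replace = TRUE), n, L)
    d <- sample(rep_len(1:4, n))  # stratified: marginals exactly uniform
    for (b in 0:3) {
      m[, pos1 + b + 1L] <- d
      m[, pos2 + b + 1L] <- sigma[d]
    }
    apply(m, 1, int_to_seq)
  })
}

#' Distant-dependence benchmark run
#'
#' Sites carry correlated homopolymer runs at two distant positions with uniform
#' marginals; a mononucleotide PWM sees background everywhere, while the
#' SiteGA discriminant can pick up the locally positioned dinucleotides.
#' Both models are trained on the same sites and compared by peak-level
#' ROC AUC on implanted versus order-1 shuffled peaks.
#'
#' @param seed Integer seed.
#' @param n_train Training sites.
#' @param n_peaks Real peaks.
#' @param peak_len Peak length (bp).
#' @param ga_params GA settings for [evolve_feature_set()] (desk-scale
#'   default).
#' @return List with `auc_mono`, `auc_sitega`.
#' @export
run_distant_dependence_experiment <- function(seed, n_train = 200L,
                                              n_peaks = 150L,
                                              peak_len = 100L,
                                              ga_params = list(pop_size = 50L,
                                                               generations = 120L,
                                                               mutation = 0.25)) {
  L <- 16L
  sites <- draw_distant_dependent_sites(n_train, L = L,
                                        seed = derive_seed(seed, "sites"))
  mono <- build_mono_pwm(sites, id = "mono")
  sitega <- evolve_feature_set(sites, K = 8L, ga_params = ga_params,
                               seed = derive_seed(seed, "ga"), id = "sitega")
  bg <- .uniform_peaks(n_peaks, peak_len, derive_seed(seed, "peaks"))
  withr::with_seed(derive_seed(seed, "implant"), {
    seqs <- bg$seq
    site_strings <- draw_distant_dependent_sites(
      n_peaks, L = L, seed = derive_seed(seed, "sitedraw"))
    for (i in seq_len(n_peaks)) {
      st <- sample.int(peak_len - L + 1L, 1L)
      substr(seqs[i], st, st + L - 1L) <- site_strings[i]
    }
    bg$seq <- seqs
  })
  shuf <- make_shuffled_background(bg, order = 1L, n_fold = 1L,
                                   seed = derive_seed(seed, "shuffle"))
  list(auc_mono = roc_curve(bg, shuf, mono)$auc,
       auc_sitega = roc_curve(bg, shuf, sitega)$auc)
}

## Background-quantile threshold: the score exceeded by a fraction
## `fp_target` of shuffled-peak best scores.
.background_threshold <- function(bg_peaks, model, fp_target = 0.05) {
  stats::quantile(.best_scores(bg_peaks, model), 1 - fp_target,
                  na.rm = TRUE, names = FALSE)
}

#' Motif-subtype union benchmark run
#'
#' Peaks carry one site of either of two motif subtypes (a TRTTTRYH-core
#' FoxA-like subtype in `frac_a` of peaks, a CACGTGAC-core subtype in the
#' rest). A pattern-matching PWM is trained on curated subtype-A sites; a
#' pattern-discovery matrix is learned from the peaks themselves (and finds
#' the majority subtype). Each model's threshold is set at the 5% FP
#' quantile of an order-1 shuffled background; recognition fractions of the
#' single models and their union are returned.
#'
#' @param seed Integer seed.
#' @param n_peaks Real peaks.
#' @param peak_len Peak length (bp).
#' @param frac_a Fraction of peaks carrying subtype A.
#' @param n_train Curated subtype-A training sites.
#' @param n_starts Discovery starts.
#' @return List with `frac_matching`, `frac_discovery`, `frac_union`.
#' @export
run_subtype_union_experiment <- function(seed, n_peaks = 200L,
                                         peak_len = 100L, frac_a = 0.4,
                                         n_train = 53L, n_starts = 5L) {
  motif_a <- make_simple_motif("TRTTTRYH", core_mass = 0.95)
  motif_b <- make_simple_motif("CACGTGAC", core_mass = 0.95)
  n_a <- round(frac_a * n_peaks)
  bg <- .uniform_peaks(n_peaks, peak_len, derive_seed(seed, "peaks"))
  ps_a <- implant_sites(bg[seq_len(n_a), ], motif_a, sites_per_peak = 1,
                        seed = derive_seed(seed, "implant_a"))
  ps_b <- implant_sites(bg[(n_a + 1L):n_peaks, ], motif_b,
                        sites_per_peak = 1,
                        seed = derive_seed(seed, "implant_b"))
  peaks <- dplyr::bind_rows(ps_a$peaks, ps_b$peaks)
  sites_a <- generate_training_sites(motif_a, n_train,
                                     seed = derive_seed(seed, "train"))
  matching <- build_mono_pwm(sites_a, id = "matching_pwm")
  disc <- greedy_discover(peaks, L = 12L, mode = "mono",
                          n_starts = n_starts,
                          seed = derive_seed(seed, "discover"))
  shuf <- make_shuffled_background(peaks, order = 1L, n_fold = 1L,
                                   seed = derive_seed(seed, "shuffle"))
  thr_m <- .background_threshold(shuf, matching)
  thr_d <- .background_threshold(shuf, disc$model)
  best_m <- .best_scores(peaks, matching)
  best_d <- .best_scores(peaks, disc$model)
  rec_m <- !is.na(best_m) & best_m > thr_m
  rec_d <- !is.na(best_d) & best_d > thr_d
  list(frac_matching = mean(rec_m), frac_discovery = mean(rec_d),
       frac_union = mean(rec_m | rec_d))
}

#' Homotypic-cluster chance-overlap run
#'
#' Every peak carries an enforced two-site cluster: one site of each of two
#' motif subtypes, placed without overlap. Two subtype-specific PWMs are
#' calibrated at the 25% FP background quantile — a deliberately permissive
#' threshold so that shuffled peaks yield enough co-detections to estimate
#' the chance expectation with useful precision — and the tenfold
#' chance-overlap test compares the observed fraction of co-detected peaks
#' with non-overlapping sites against the shuffled expectation.
#'
#' @param seed Integer seed.
#' @param n_peaks Real peaks.
#' @param peak_len Peak length (bp).
#' @param n_train Curated training sites per subtype.
#' @param n_fold Shuffle folds for the expectation.
#' @return [glance()]-style tibble of the underlying
#'   [chance_overlap_test()].
#' @export
run_cluster_overlap_experiment <- function(seed, n_peaks = 300L,
                                           peak_len = 100L, n_train = 53L,
                                           n_fold = 10L) {
  motif_a <- make_simple_motif("TRTTTRYH", core_mass = 0.95)
  motif_b <- make_simple_motif("CACGTGAC", core_mass = 0.95)
  L <- motif_a$L
  bg <- .uniform_peaks(n_peaks, peak_len, derive_seed(seed, "peaks"))
  withr::with_seed(derive_seed(seed, "implant"), {
    seqs <- bg$seq
    for (i in seq_len(n_peaks)) {
      repeat {
        st <- sort(sample.int(peak_len - L + 1L, 2L) - 1L)
        if (st[2] - st[1] >= L) break
      }
      ## one site of each subtype per peak, random order and strands
      ord <- sample(1:2)
      for (k in 1:2) {
        m <- list(motif_a, motif_b)[[ord[k]]]
        site <- .draw_site(m)
        if (sample(c(TRUE, FALSE), 1L)) site <- reverse_complement(site)
        substr(seqs[i], st[k] + 1L, st[k] + L) <- site
      }
    }
    bg$seq <- seqs
  })
  sites_a <- generate_training_sites(motif_a, n_train,
                                     seed = derive_seed(seed, "train_a"))
  sites_b <- generate_training_sites(motif_b, n_train,
                                     seed = derive_seed(seed, "train_b"))
  model_a <- build_mono_pwm(sites_a, id = "pwm_subtype_a")
  model_b <- build_mono_pwm(sites_b, id = "pwm_subtype_b")
  shuf <- make_shuffled_background(bg, order = 1L, n_fold = 1L,
                                   seed = derive_seed(seed, "thr_shuffle"))
  thr <- c(.background_threshold(shuf, model_a, fp_target = 0.25),
           .background_threshold(shuf, model_b, fp_target = 0.25))
  res <- chance_overlap_test(bg, model_a, model_b, thresholds = thr,
                             n_fold = n_fold,
                             seed = derive_seed(seed, "chance"))
  glance(res)
}
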