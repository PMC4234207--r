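---
title: "Benchmarking transcription-factor binding-site models on ChIP-Seq peaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking transcription-factor binding-site models on ChIP-Seq peaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfbsbench)
```

## The problem

A ChIP-Seq experiment for a transcription factor (TF) yields thousands of
bound loci ("peaks"), but not the binding sites (TFBSs) themselves: a peak
of 100-1000 bp contains the 10-20 bp sites somewhere inside it, mixed with
indirectly bound and noise loci. Interpreting the data therefore needs (a) a
recognition model that scores candidate sites, and (b) a score threshold
that separates sequences the protein can actually bind from lookalikes.
Neither is free: models of different families (matrices trained on curated
sites vs motifs discovered de novo in the peaks) disagree on a substantial
fraction of candidates, and thresholds chosen by statistical convention may
pass many sequences that do not bind in vitro.

`tfbsbench` implements this whole workflow as a tested, simulation-backed
pipeline for forkhead-family (FoxA-like) factors and, generically, for any
short TFBS:

* **pattern matching** — a mononucleotide position weight matrix whose
  length is optimised by cross-validation (oPWM), and a SiteGA-style
  discriminant over locally positioned dinucleotide frequencies selected by
  a genetic algorithm; both train on a curated alignment of confirmed
  sites;
* **pattern discovery** — greedy gapless multiple local alignment of the
  peaks themselves, maximising Kullback discrete information content in the
  mononucleotide (KDIC) or dinucleotide (KDDIC) alphabet;
* **calibration** — per-model thresholds derived from simulated EMSA
  competition experiments on predicted sites;
* **benchmarking** — recognized-peak fractions, peak-level ROC/AUC and
  Matthews correlation against Markov-shuffled backgrounds, pairwise model
  combinations, and a chi-squared test for homotypic-cluster driven
  non-overlapping co-detections.

Because real ChIP-Seq data and wet-lab EMSA measurements are outside the
package's scope, every input is produced by a first-class synthetic-data
module with known ground truth. All empirical statements below are the ones
the test suite and `scripts/acceptance.R` actually compute.

## Models

### Position weight matrices

An aligned site set of width $L$ gives column frequencies
$f_{ja} = (n_{ja} + p\,q_a)/(N + p)$ with pseudocount mass $p$ (default 1)
distributed by the background composition $q$; weights are natural-log odds
$w_{ja} = \ln(f_{ja}/q_a)$ and a window scores $\sum_j w_{j,x_j}$. The
dinucleotide matrix does the same over the $L-1$ adjacent-dinucleotide
columns in a 16-letter alphabet, capturing nearest-neighbour dependence.
Every model's raw score is min-max rescaled onto $[0,1]$ by its attainable
extremes $s_\min, s_\max$, putting all model families on one scale; a fully
background-like matrix ($s_\min = s_\max$) is rejected at build time.

The **oPWM length search** (`optimize_length()`) scores each candidate
length (symmetric extension around the alignment core) by leave-one-out
cross-validation: the threshold is anchored so that at least `tp_anchor`
(default 0.9) of held-out sites pass, and the selected length minimises the
fraction of background windows passing, ties resolved toward the shorter
matrix (parsimony).

### SiteGA discriminant

A *locally positioned dinucleotide* (LPD) feature is the frequency of one
dinucleotide inside a sub-window $[s, e)$ of the scored site. A K-feature
set (default K = 20) is selected by a genetic algorithm — uniform
feature-exchange crossover (rate 0.7), bound/dinucleotide mutation (rate
0.1, window bounds jittered by up to 2), tournament selection, elitism 2,
population 50 over 100 generations by default — and scored by a Fisher
linear discriminant $w \propto (\Sigma_{pooled} + \lambda I)^{-1}
(\mu_{site} - \mu_{bg})$ with the intercept at the midpoint of the
projected class means.

GA fitness is the leave-one-out Matthews correlation of the discriminant.
For speed this uses the classical equivalence of the two-class discriminant
direction with least squares on a 0/1 class label, whose leave-one-out
predictions have the closed form $y_i - e_i/(1-h_{ii})$; this makes one
fitness evaluation a single QR-sized solve instead of $n$ refits. Scores
are rescaled by the training-time score range extended by a 5% margin and
clamped to $[0,1]$.

### Greedy KDIC/KDDIC discovery

The discovery objective for an alignment with column frequencies $f$ is the
Kullback information $\mathrm{KDIC} = \sum_j \sum_a f_{ja}
\ln(f_{ja}/q_a)$ (nats; KDDIC is the same over dinucleotide columns).
The greedy aligner keeps at most one occurrence per peak: each start seeds
from a bootstrap subsample (fraction 0.5 of peaks), then sweeps all peaks,
swapping in the (offset, strand) that maximises the objective or dropping
the peak when every placement lowers it.

Two numerical choices matter here:

* **What the greedy maximises.** The frequency-form KDIC is scale-free in
  the number of aligned sequences, so with drops allowed its optimum is a
  tiny set of near-identical windows — the aligner collapses. The greedy
  therefore maximises the *alignment-total* information
  $(N + p)\cdot\mathrm{KDIC}$, which trades per-column conservation against
  coverage (adding an occurrence pays off exactly when its average log-odds
  against the current columns is positive). The reported
  `objective` of a `discovery_result` is still the frequency-form
  KDIC/KDDIC of the final alignment and always equals an independent
  recomputation from its occurrence list.
* **Phase-shift refinement.** Greedy OOPS alignment has strong local optima
  in which the whole alignment sits one or two columns off the true frame
  (all occurrences coherently shifted). After each start converges, the
  aligner proposes coherent shifts of the entire alignment by ±1, ±2
  columns (strand-aware), re-sweeps, and accepts improvements; this is the
  alignment-space analogue of the column-shift move in Gibbs motif
  samplers.

With shape weighting enabled, an occurrence's column counts are weighted by
the peak's max-normalised coverage profile at the occurrence midpoint
(quantised to 0.01 so count updates stay exact); peaks without profiles
weight 1.

## Synthetic data and what it does (and does not) emulate

The generator produces every input of the study with known truth:

* **Peaks** — order-0/1 Markov background sequences (add-one-smoothed
  fits), default 300 peaks of 120 bp, with read-coverage heights from a
  shifted negative binomial (minimum 15, the usual coverage filter for
  mouse liver data; size 2, mean excess 25 — typical of a
  coverage-filtered peak set).
* **Implants** — sites drawn column-wise from a ground-truth motif (or its
  first-order generator), placed uniformly without overlap on a uniform
  strand; the default mixture 40/40/20% of 1/2/3 sites per peak (mean 1.8)
  reflects the observation that most bound loci carry more than one site.
  The default FoxA-like motif has an 8-bp TRTTTRYH core with probability
  mass 0.85 on consensus-compatible letters (split over IUPAC degeneracy)
  plus two mildly informative flank columns each side (≈ 6.3 bits).
* **Curated training sites** — 53 sites (the classical curated FoxA set
  size) of core + 10 bp background flanks, aligned on the core.
* **EMSA curves** — band intensity declining linearly in log competitor
  concentration, $I(c) = I_0 (1 - A\, s_0 \ln c)\,\varepsilon$ with
  multiplicative lognormal noise (default sd 0.05) at the standard 2, 5,
  20 ng series. The linear-in-$\ln c$ form is chosen deliberately: it makes
  the published slope-ratio estimator (OLS slope of intensity on
  $\ln c$, normalised to the self-competition control) exactly unbiased at
  zero noise, so estimator consistency is analytic rather than asymptotic.

Passing tests on these data show that the algorithms are implemented
correctly and behave as the underlying theory predicts under controlled
conditions. They do not show field performance on real peaks: real ChIP-Seq
backgrounds are higher-order and repeat-rich, binding sites are not drawn
from independent columns, EMSA intensities saturate, and peak height and
site affinity are correlated in ways the generator deliberately leaves out
(heights are independent of site content by default, since no quantitative
height-affinity law is assumed).

### Recovery regime for de-novo discovery

Motif recovery is only well-posed when the motif carries enough
information. At the default core mass 0.85 (~6.3 bits), the
information-content optimum of a 12-column alignment over 120-bp peaks is
genuinely *not* the implant frame: aligning the invariant T-tract of
TRTTTRYH from either strand beats the degenerate R/Y/H columns, so any
correct KDIC maximiser converges away from the planted positions. The
recovery tests therefore use a consensus-concentrated variant (core mass
0.95, ≈ 9.2 bits, satisfying the ≥ 8 bit recovery precondition), under
which ten independent seeded runs place ≥ 80% of occurrences exactly on the
implants.

## Threshold calibration

The calibration emulates the experimental verification round of a ChIP-Seq
study: candidate binding sites are the models' own per-peak best
predictions, a panel of them (default 20 non-binders + 44 binders + a
self-competition control, sampled arbitrarily across models) is "measured"
by the EMSA simulator at affinities assigned from the implant ground truth
(binders 0.3-1.2, non-binders < 0.2), and each model's threshold is the
highest model score among the oligos whose EMSA score falls below the 0.25
non-site bin edge (1.5× the assay's technical error; bins: < 0.25
non-site, 0.25-0.75 weak, > 0.75 strong, with the strict inequality at
0.25). A sequence counts as a site only when its score exceeds the
threshold *strictly* — the threshold value itself belongs to a non-site.

Two design points are worth making explicit. First, selecting oligos from
*predictions within peaks* (not from standalone constructed sequences)
matters: predicted sites inherit the extreme-value statistics of per-peak
maxima, so the non-site maximum lands in the upper tail of the background
score distribution, exactly where a useful threshold must sit. Second, the
regression in `emsa_score()` is of raw intensity on $\ln c$ (the three
concentrations are log-spaced); negative slope ratios are clamped to zero
with a warning.

`sensitivity_of_bin_edge()` re-derives thresholds for alternative bin edges
(default 0.17, 0.25, 0.34) and reports the benchmark CC at each, flagging
edges that leave no non-sites as undefined.

## Benchmarking

* **Shuffled backgrounds** (`make_shuffled_background()`): per fold and per
  peak, a Markov chain of order 0 or 1 is fitted to that peak alone and one
  sequence of identical length is drawn — full-length shuffling that
  preserves per-peak length and composition. Per-peak (rather than pooled)
  fitting keeps composition heterogeneity in the null.
* **ROC/CC**: peak-level — the fraction of recognized real peaks (TP rate)
  against the fraction of recognized shuffled peaks (FP rate) as the
  threshold sweeps the union of per-peak best scores; AUC by trapezoid.
  The Matthews correlation is reported at the calibrated threshold; a zero
  marginal (e.g. a threshold passed by everything) is flagged and reported
  as 0.
* **Combination categories**: peaks detected by two models with at least
  one overlapping hit pair (a), by one model only (b, c), by both without
  any overlap (d), or by neither; window overlap is ≥ 1 shared bp,
  half-open, strand-agnostic. Same-model hits are pruned greedily
  best-score-first so they never overlap (ties: leftmost, then + strand).
  The homotypic-cluster fraction is the share of detected peaks carrying
  ≥ 2 sites in total.
* **Chance-overlap test**: the observed statistic is $d/(a+d)$ — among
  real peaks co-detected by two models, the fraction whose sites never
  overlap. The expectation pools counts over a tenfold per-peak shuffle
  (pooled counts, not a mean of fractions), and the two are compared by a
  chi-squared test on the 2×2 table $[[d, a], [d', a']]$ with 1 df and no
  continuity correction.

## Comparative scenarios

Four purpose-built simulations reproduce the qualitative comparisons the
benchmark suite is designed to make (each runner fixes its own conditions;
the acceptance tests run 10 seeds of each):

1. **Nearest-neighbour dependence** — sites drawn as a first-order chain
   with repeat probability 0.6 and uniform marginals: mononucleotide
   matrices see background (AUC ≈ 0.5) while dinucleotide matrices read the
   transitions.
2. **Distant-position dependence** — uniform sites with two perfectly
   correlated 3-bp homopolymer runs at distant offsets, using paired
   letters (A↔C, G↔T) and a stratified letter draw so sample marginals are
   *exactly* uniform. The stratification is essential: with merely
   uniform-in-expectation draws, the correlated run columns share their
   sampling noise and a finite-sample PWM becomes a coherent weak run
   detector, inflating the mono baseline. SiteGA's LPD features capture the
   runs; the scenario's GA uses population 50, 120 generations, mutation
   0.25 (the needle features are rare in the feature space).
3. **Motif subtype mixture** — 40% of peaks carry a TRTTTRYH-core site,
   60% a CACGTGAC-core site; the pattern-matching model trains on curated
   subtype-A sites, discovery learns the majority subtype from the peaks,
   and thresholds sit at the 5% FP quantile of a shuffled background. The
   union recognises substantially more peaks than either model alone.
4. **Enforced homotypic clusters** — every peak carries one site of each
   subtype; two subtype-specific PWMs then co-detect peaks mostly with
   non-overlapping sites, and the observed $d/(a+d)$ exceeds the tenfold
   shuffle expectation with a significant chi-squared statistic.

## Numerical choices and degenerate inputs

* Windows containing N (or any non-ACGT IUPAC letter) are unscorable and
  skipped by every scanner; models are defined over ACGT only.
* Coordinates are 0-based half-open throughout (BED convention).
* Log base e everywhere; rescaling makes the base irrelevant downstream.
* Ties: length optimisation → shorter matrix; occurrence choice → smallest
  offset, then + strand; hit pruning → best score, then leftmost, then +
  strand.
* A singular pooled covariance in the discriminant triggers an automatic
  ridge increase (logged); fully uniform matrices are rejected at build
  time; empty peak sets, missing non-sites and zero co-detections raise
  errors or flagged-undefined results rather than silent zeros.
* All randomness flows through per-stage seeds derived from one master
  seed; identical configuration gives byte-identical artifacts.

## Problem sizes

The test suite and acceptance script run at desk scale, chosen so the whole
suite completes in minutes on one core: 300 peaks × 120 bp for the default
pipeline study; 200 peaks for motif recovery (10 seeded runs); 150-300
peaks per comparative scenario (10 seeds each in the tests, 3 in the
acceptance script); 50 random 200-bp peaks for exact brute-force oracle
comparisons; 16 + 1 oligos for the panel-style calibration check. These
sizes are the package's own defaults and are documented here so results are
interpreted at the scale they were computed.

## Known limitations

* The discovery aligner is OOPS (at most one occurrence per retained peak)
  per run; homotypic clusters are analysed through scanning, not through
  multi-occurrence discovery. Even with phase-shift refinement, a
  strand-mixed frame shifted by one column remains a competing attractor
  whose objective occasionally exceeds the exact frame's by a fraction of
  a percent; on such draws a run recovers the motif in a shifted frame and
  its exact-placement rate collapses, which is why recovery statistics are
  reported over several independent runs.
* SiteGA's peak-level specificity is limited by max-over-windows score
  statistics: a K-feature linear discriminant has a heavier upper tail over
  random windows than an additive matrix of the same width, which depresses
  its ROC on weak motifs. This is a property of the model family, visible
  in the default pipeline's AUC table. Because SiteGA scores clamp at 1,
  a single non-binding verification oligo that saturates the scale drives
  the calibrated threshold to 1.0 and the model recognises nothing — the
  calibration's honest verdict that the model has no usable operating
  point under those conditions.
* The EMSA simulator is a calibration-faithful stand-in, not a binding
  isotherm; only the slope-ratio readout is meaningful.
* Chi-squared (not Fisher) is used for the 2×2 overlap table, without
  continuity correction, matching the benchmark's large pooled counts; no
  multiple-testing correction is applied across model pairs.
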