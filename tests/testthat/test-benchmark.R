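test_that("Matthews CC matches hand arithmetic and flags degeneracy", {
  expect_equal(correlation_coefficient(confusion_counts(40, 10, 5, 45)),
               1750 / sqrt(45 * 50 * 50 * 55), tolerance = 1e-12)
  expect_equal(correlation_coefficient(confusion_counts(50, 0, 0, 50)), 1)
  expect_warning(cc <- correlation_coefficient(confusion_counts(50, 0, 50, 0)),
                 "zero marginal")
  expect_equal(cc, 0)
  ## CC equals the Pearson correlation of binary label/prediction vectors
  withr::with_seed(61, {
    for (r in 1:10) {
      y <- rbinom(60, 1, 0.5)
      p <- rbinom(60, 1, 0.5)
      tp <- sum(y & p); fn <- sum(y & !p); fp <- sum(!y & p)
      tn <- sum(!y & !p)
      if (min(tp + fp, tp + fn, tn + fp, tn + fn) == 0) next
      expect_equal(correlation_coefficient(confusion_counts(tp, fn, fp, tn)),
                   stats::cor(y, p), tolerance = 1e-12)
    }
  })
})

test_that("shuffled backgrounds preserve length and per-peak composition", {
  peaks <- tibble::tibble(id = c("a", "b"),
                          seq = c(strrep("AC", 60), random_dna(1, 95, 3)),
                          height = c(20, 30))
  bg <- make_shuffled_background(peaks, order = 1L, n_fold = 10L, seed = 62)
  expect_equal(nrow(bg), 20)
  expect_equal(nchar(bg$seq[bg$source_id == "a"]), rep(120, 10))
  expect_equal(nchar(bg$seq[bg$source_id == "b"]), rep(95, 10))
  ## an AC-repeat source yields near-perfect AC alternation
  ac <- bg$seq[bg$source_id == "a"][1]
  di <- table(substring(ac, 1:119, 2:120))
  expect_gt(sum(di[c("AC", "CA")]) / 119, 0.9)
  expect_identical(bg, make_shuffled_background(peaks, 1L, 10L, seed = 62))
  expect_error(make_shuffled_background(
    tibble::tibble(id = "x", seq = "A", height = 1), order = 1L),
    "shorter")
})

test_that("ROC handles oracle, constant and random scorers", {
  ## stub model: looks up a fixed per-sequence score
  oracle <- local({
    structure(list(id = "oracle", width = 1L), class = "stub_model")
  })
  peaks_real <- tibble::tibble(id = sprintf("r%d", 1:500),
                               seq = "AAAA", height = 1)
  peaks_bg <- tibble::tibble(id = sprintf("b%d", 1:500),
                             seq = "CCCC", height = 1)
  ## register stub scoring: real sequences AAAA -> 1, CCCC -> 0
  registerS3method(".window_scores_int", "stub_model",
                   function(model, v) rep(if (v[1] == 1L) 1 else 0,
                                          length(v)),
                   envir = asNamespace("tfbsbench"))
  registerS3method("model_width", "stub_model", function(model) 1L,
                   envir = asNamespace("tfbsbench"))
  roc <- roc_curve(peaks_real, peaks_bg, oracle)
  expect_equal(roc$auc, 1)
  ## constant scorer: AUC 0.5 (single non-trivial point)
  peaks_bg2 <- tibble::tibble(id = sprintf("b%d", 1:500), seq = "AAAA",
                              height = 1)
  expect_equal(roc_curve(peaks_real, peaks_bg2, oracle)$auc, 0.5)
  ## random scores on both sets: AUC near 0.5
  sites <- random_dna(20, 8, seed = 63)
  pwm <- build_mono_pwm(sites)
  real <- tibble::tibble(id = sprintf("r%d", 1:500),
                         seq = random_dna(500, 60, seed = 64), height = 1)
  bg <- tibble::tibble(id = sprintf("b%d", 1:500),
                       seq = random_dna(500, 60, seed = 65), height = 1)
  auc <- roc_curve(real, bg, pwm)$auc
  expect_gt(auc, 0.45)
  expect_lt(auc, 0.55)
  ## monotone curve, AUC within [0, 1]
  pts <- roc_curve(real, bg, pwm)$points
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
})

test_that("combination categories partition the toy fixture", {
  peaks <- tibble::tibble(id = sprintf("P%d", 1:5), seq = strrep("A", 50),
                          height = 1)
  h1 <- tibble::tibble(peak_id = c("P1", "P2", "P4"),
                       start = c(10L, 5L, 0L), strand = "+",
                       model_id = "m1", score = 0.9)
  h2 <- tibble::tibble(peak_id = c("P1", "P3", "P4"),
                       start = c(15L, 8L, 30L), strand = "+",
                       model_id = "m2", score = 0.9)
  cs <- combination_analysis(peaks, h1, h2, 8, 8)
  expect_equal(unname(cs$counts),
               c(1L, 1L, 1L, 1L, 1L))
  expect_equal(sum(cs$counts), nrow(peaks))
  ## empty second model: all detected peaks are category b
  cs_b <- combination_analysis(peaks, h1, h2[0, ], 8, 8)
  expect_equal(unname(cs_b$counts["b"]), 3L)
  expect_equal(unname(cs_b$counts["a"] + cs_b$counts["c"] +
                        cs_b$counts["d"]), 0L)
  expect_error(combination_analysis(peaks,
                                    dplyr::mutate(h1, peak_id = "ghost"),
                                    h2, 8, 8), "unknown")
})

test_that("combination categories match a brute-force recomputation", {
  withr::with_seed(66, {
    for (r in 1:30) {
      n <- 12
      peaks <- tibble::tibble(id = sprintf("p%d", 1:n), seq = strrep("A", 60),
                              height = 1)
      mk <- function(mid) {
        k <- rpois(1, 6)
        tibble::tibble(peak_id = sample(peaks$id, k, replace = TRUE),
                       start = sample(0:50, k, replace = TRUE),
                       strand = "+", model_id = mid, score = 0.9)
      }
      h1 <- mk("m1"); h2 <- mk("m2")
      cs <- combination_analysis(peaks, h1, h2, 9, 7)
      for (id in peaks$id) {
        s1 <- h1$start[h1$peak_id == id]
        s2 <- h2$start[h2$peak_id == id]
        expected <- if (!length(s1) && !length(s2)) "neither"
        else if (length(s1) && !length(s2)) "b"
        else if (!length(s1) && length(s2)) "c"
        else {
          ov <- FALSE
          for (a in s1) for (b in s2) {
            if (a < b + 7 && b < a + 9) ov <- TRUE
          }
          if (ov) "a" else "d"
        }
        expect_equal(cs$per_peak$category[cs$per_peak$peak_id == id],
                     expected)
      }
    }
  })
})

test_that("chi-squared on the 2x2 overlap table matches the hand formula", {
  tab <- rbind(c(30, 70), c(15, 85))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  hand <- 200 * (30 * 85 - 70 * 15)^2 / (100 * 100 * 45 * 155)
  expect_equal(unname(ct$statistic), hand, tolerance = 1e-9)
  expect_equal(hand, 6.451613, tolerance = 1e-6)
})

test_that("chance_overlap_test is null-calibrated on identical hit structure", {
  ## two disjoint-motif models on pure background: real and shuffled peaks
  ## have the same (random) hit structure, so chi2 should be small
  motif_a <- make_simple_motif("TRTTTRYH", core_mass = 0.95)
  motif_b <- make_simple_motif("CACGTGAC", core_mass = 0.95)
  m_a <- build_mono_pwm(generate_training_sites(motif_a, 40, seed = 67),
                        id = "a")
  m_b <- build_mono_pwm(generate_training_sites(motif_b, 40, seed = 68),
                        id = "b")
  peaks <- generate_background(uniform_chain(), 150, 80, seed = 69)
  res <- chance_overlap_test(peaks, m_a, m_b, thresholds = c(0.75, 0.75),
                             n_fold = 4, seed = 70)
  if (!is.na(res$p)) expect_gt(res$p, 0.01)
  ## glance/tidy surfaces
  g <- glance(res)
  expect_true(all(c("observed_frac", "expected_frac", "chi2", "p") %in%
                    names(g)))
})
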