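test_that("fit_markov estimates transitions with smoothing", {
  m0 <- fit_markov("AAAA", order = 0L)
  expect_gt(m0$p0[1], 0.6)
  m1 <- fit_markov(strrep("AC", 500), order = 1L)
  expect_gt(m1$transition["A", "C"], 0.98)
  expect_gt(m1$transition["C", "A"], 0.98)
  expect_error(fit_markov(character(0)), "empty")
  expect_error(fit_markov("ACGT", order = 2), "unsupported order")
})

test_that("generate_background is seed-deterministic and chain-faithful", {
  all_a <- fit_markov(strrep("A", 500), order = 0L)
  bg <- generate_background(all_a, 5, 50, seed = 1)
  expect_true(all(vapply(bg$seq, function(s) {
    mean(strsplit(s, "")[[1]] == "A") > 0.9
  }, logical(1))))

  b1 <- generate_background(uniform_chain(), 10, 80, seed = 9)
  b2 <- generate_background(uniform_chain(), 10, 80, seed = 9)
  expect_identical(b1, b2)
  expect_true(all(b1$height >= 15))

  ## order-1 chain: dinucleotide composition of a large generated set stays
  ## close to the source chain (L1 over the 16 frequencies)
  src <- fit_markov(random_dna(20, 200, seed = 2), order = 1L)
  big <- generate_background(src, 200, 200, seed = 3)
  refit <- fit_markov(big$seq, order = 1L)
  expect_lt(max(abs(refit$transition - src$transition)), 0.02)
  p_src <- as.vector(src$transition * src$p0)
  p_gen <- as.vector(refit$transition * refit$p0)
  expect_lt(sum(abs(p_src - p_gen)), 0.05)
})

test_that("implant truth records the exact planted strings", {
  motif <- test_motif()
  ps <- implanted_peak_set(60, 90, motif, sites_per_peak = 1, seed = 4)
  expect_equal(nrow(ps$truth), 60)
  for (i in seq_len(nrow(ps$truth))) {
    tr <- ps$truth[i, ]
    pk <- ps$peaks$seq[ps$peaks$id == tr$peak_id]
    observed <- substr(pk, tr$start + 1, tr$start + motif$L)
    expected <- if (tr$strand == "+") tr$site else reverse_complement(tr$site)
    expect_identical(observed, expected)
  }
})

test_that("implant count distribution matches the requested mixture", {
  motif <- test_motif()
  ps <- implanted_peak_set(1000, 60, motif,
                          sites_per_peak = c("1" = 0.4, "2" = 0.4, "3" = 0.2),
                          seed = 11)
  per_peak <- table(factor(ps$truth$peak_id, levels = ps$peaks$id))
  expect_lt(abs(mean(per_peak) - 1.8), 0.1)
  ## deterministic consensus motif gives verbatim consensus implants
  cons <- ground_truth_motif(diag(4)[c(4, 3, 4, 4, 4, 1, 2, 4), ] * 0.999999 +
                               (1 - 0.999999) / 4,
                             core_consensus = "TGTTTACT", core_offset = 0L)
  one <- implant_sites(generate_background(uniform_chain(), 5, 40, seed = 1),
                       cons, sites_per_peak = 1, seed = 2)
  expect_true(all(one$truth$site == "TGTTTACT"))
  ## impossible placements error out
  tiny <- generate_background(uniform_chain(), 2, 26, seed = 1)
  expect_error(implant_sites(tiny, motif, sites_per_peak = 3, seed = 1),
               "non-overlapping")
})

test_that("training sites carry the core pattern at the recorded offset", {
  motif <- test_motif(core_mass = 0.9999)
  sites <- generate_training_sites(motif, 53, flank_len = 6, seed = 5)
  expect_equal(attr(sites, "width"), motif$L + 12L)
  expect_equal(attr(sites, "core_offset"), 6L + motif$core_offset)
  core <- substring(sites$seq, attr(sites, "core_offset") + 1,
                    attr(sites, "core_offset") + 8)
  ok <- vapply(core, function(s) {
    tfbsbench:::matches_iupac(s, "TRTTTRYH")
  }, logical(1))
  expect_true(all(ok))
  expect_identical(generate_training_sites(motif, 10, 2, seed = 7),
                   generate_training_sites(motif, 10, 2, seed = 7))
  expect_equal(attr(generate_training_sites(motif, 5, 0, seed = 1), "width"),
               motif$L)
})

test_that("EMSA simulator honours the slope-ratio contract", {
  oligos <- tibble::tibble(id = c("control", "half", "zero"),
                           seq = NA, affinity = c(1, 0.5, 0))
  noiseless <- simulate_emsa_panel(oligos, noise_sd = 0, seed = 1)
  scored <- emsa_scores(noiseless)
  expect_equal(scored$emsa_score[scored$oligo_id == "control"], 1,
               tolerance = 1e-10)
  expect_equal(scored$emsa_score[scored$oligo_id == "half"], 0.5,
               tolerance = 1e-10)
  expect_equal(scored$emsa_score[scored$oligo_id == "zero"], 0,
               tolerance = 1e-10)
  ## Monte-Carlo: estimator stays close to truth under 5% noise
  ests <- vapply(1:100, function(i) {
    curves <- simulate_emsa_panel(oligos, noise_sd = 0.05, seed = 1000 + i)
    sc <- emsa_scores(curves)
    sc$emsa_score[sc$oligo_id == "half"]
  }, numeric(1))
  expect_gt(mean(ests), 0.45)
  expect_lt(mean(ests), 0.55)
  expect_error(simulate_emsa_panel(oligos, concentrations = c(-1, 5)),
               "positive")
  expect_error(simulate_emsa_panel(dplyr::mutate(oligos, affinity = c(2, 1, 0))),
               "control")
})

test_that("panel generators bracket the non-site bin edge", {
  motif <- test_motif()
  panel <- make_emsa_oligo_panel(motif, seed = 3)
  expect_equal(sum(panel$class == "control"), 1)
  expect_true(any(panel$affinity < 0.25) && any(panel$affinity > 0.75))
  expect_identical(panel, make_emsa_oligo_panel(motif, seed = 3))
})
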