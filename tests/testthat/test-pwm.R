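test_that("mono PWM frequencies and weights follow the pseudocount formula", {
  ## 4 sites, first column all A: f_A = (4 + 1*0.25)/(4 + 1) = 0.85
  sites <- c("AC", "AG", "AT", "AA")
  pwm <- build_mono_pwm(sites, q = rep(0.25, 4), pseudocount = 1)
  expect_equal(pwm$weights[1, 1], log(0.85 / 0.25), tolerance = 1e-12)
  expect_equal(exp(pwm$weights[1, 2]) * 0.25, 0.05 / 1, tolerance = 1e-12)
  ## duplication invariance of the count frequencies, checked in the
  ## vanishing-pseudocount limit on columns with no zero counts (a fixed
  ## pseudocount mass shrinks with N by construction, and empty cells keep
  ## an N-dependent floor)
  full <- c("AA", "AC", "AG", "AT", "CC", "GG", "TT", "AA")
  pwm_a <- build_mono_pwm(full, pseudocount = 1e-9)
  pwm_b <- build_mono_pwm(rep(full, 2), pseudocount = 1e-9)
  expect_equal(pwm_a$weights, pwm_b$weights, tolerance = 1e-6)
  ## a matrix at background composition is rejected as degenerate
  expect_error(build_mono_pwm(c("AC", "CA", "GT", "TG")), "degenerate")
  expect_error(build_mono_pwm("ACGT"), "two training sites")
})

test_that("di PWM counts adjacent dinucleotides", {
  dp <- build_di_pwm(c("AA", "AA"), pseudocount = 0.1)
  expect_equal(nrow(dp$weights), 1)
  f_aa <- (2 + 0.1 / 16) / (2 + 0.1)
  expect_equal(dp$weights[1, 1], log(f_aa / (1 / 16)), tolerance = 1e-12)
})

test_that("window scores match brute-force recomputation on random data", {
  sites <- random_dna(30, 14, seed = 21)
  pwm <- build_mono_pwm(sites)
  dp <- build_di_pwm(sites)
  wins <- random_dna(40, 14, seed = 22)
  for (w in wins) {
    expect_equal(score_window(pwm, w), brute_pwm_score(pwm, w),
                 tolerance = 1e-12)
    expect_equal(score_window(dp, w), brute_pwm_score(dp, w),
                 tolerance = 1e-12)
  }
  ## reverse strand equals forward scoring of the reverse complement
  for (w in wins[1:10]) {
    expect_equal(score_window(pwm, w, strand = "-"),
                 score_window(pwm, reverse_complement(w)), tolerance = 1e-12)
    expect_equal(score_window(dp, w, strand = "-"),
                 score_window(dp, reverse_complement(w)), tolerance = 1e-12)
  }
  expect_true(is.na(score_window(pwm, paste0(substr(wins[1], 1, 13), "N"))))
})

test_that("rescaling maps the attainable range onto [0, 1]", {
  sites <- random_dna(20, 10, seed = 31)
  pwm <- build_mono_pwm(sites)
  expect_equal(rescale_score(pwm, pwm$s_min), 0)
  expect_equal(rescale_score(pwm, pwm$s_max), 1)
  expect_equal(rescale_score(pwm, (pwm$s_min + pwm$s_max) / 2), 0.5)
  expect_error(rescale_score(pwm, pwm$s_max + 1), "outside")
  ## every scorable random window lands inside [0, 1]
  for (w in random_dna(50, 10, seed = 32)) {
    r <- rescale_score(pwm, score_window(pwm, w))
    expect_true(r >= 0 && r <= 1)
  }
})

test_that("consensus and anti-consensus windows reach the score extremes", {
  sites <- random_dna(25, 8, seed = 41)
  pwm <- build_mono_pwm(sites)
  best <- paste(c("A", "C", "G", "T")[apply(pwm$weights, 1, which.max)],
                collapse = "")
  worst <- paste(c("A", "C", "G", "T")[apply(pwm$weights, 1, which.min)],
                 collapse = "")
  expect_equal(score_window(pwm, best), pwm$s_max, tolerance = 1e-12)
  expect_equal(score_window(pwm, worst), pwm$s_min, tolerance = 1e-12)
})

test_that("mono and di PWMs agree when sites are column-independent", {
  motif <- test_motif(core_mass = 0.85)
  sites <- generate_training_sites(motif, 800, seed = 51)
  pwm <- build_mono_pwm(sites)
  dp <- build_di_pwm(sites)
  wins <- random_dna(300, motif$L, seed = 52)
  s1 <- vapply(wins, function(w) rescale_score(pwm, score_window(pwm, w)),
               numeric(1))
  s2 <- vapply(wins, function(w) rescale_score(dp, score_window(dp, w)),
               numeric(1))
  expect_gt(stats::cor(s1, s2), 0.95)
})

test_that("matrix length optimisation prefers informative columns", {
  ## 8-bp informative core, all other columns i.i.d. uniform background
  motif <- make_simple_motif("TRTTTRYH", core_mass = 0.95, flank = 0L)
  sites <- generate_training_sites(motif, 53, flank_len = 12, seed = 61)
  bg <- generate_background(uniform_chain(), 100, 150, seed = 62)
  ## single candidate is returned trivially
  single <- optimize_length(sites, bg, 12, type = "mono")
  expect_equal(single$best_length, 12)
  ## uninformative flank columns cannot reduce the false-positive rate
  opt <- optimize_length(sites, bg, c(8, 12, 16, 20, 24, 28, 32),
                         type = "mono")
  expect_lte(opt$best_length, 8 + 4)
  expect_equal(nrow(opt$table), 7)
  expect_error(optimize_length(sites, bg, 40, type = "mono"),
               "exceeds")
})

test_that("PWM text serialisation round-trips scores exactly", {
  sites <- random_dna(20, 12, seed = 71)
  for (mdl in list(build_mono_pwm(sites, id = "m1"),
                   build_di_pwm(sites, id = "d1"))) {
    p <- withr::local_tempfile(fileext = ".txt")
    write_pwm(mdl, p)
    back <- read_pwm(p)
    expect_equal(back$weights, mdl$weights, tolerance = 1e-15)
    expect_equal(back$s_min, mdl$s_min, tolerance = 1e-12)
    expect_equal(model_id(back), model_id(mdl))
    w <- random_dna(1, 12, seed = 72)
    expect_equal(score_window(back, w), score_window(mdl, w),
                 tolerance = 1e-12)
  }
})
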