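test_that("emsa_score is the OLS slope ratio against the control", {
  ctl <- tibble::tibble(conc_ng = c(2, 5, 20), intensity = c(100, 60, 0))
  rec <- tibble::tibble(conc_ng = c(2, 5, 20), intensity = c(100, 80, 50))
  ## hand OLS oracle: slope of intensity ~ ln(conc)
  hand_slope <- function(x, y) {
    lx <- log(x)
    sum((lx - mean(lx)) * (y - mean(y))) / sum((lx - mean(lx))^2)
  }
  expect_equal(emsa_score(rec, ctl),
               hand_slope(rec$conc_ng, rec$intensity) /
                 hand_slope(ctl$conc_ng, ctl$intensity),
               tolerance = 1e-12)
  ## self-competition scores exactly 1
  expect_equal(emsa_score(ctl, ctl), 1)
  ## flat intensities give slope 0, score 0
  flat <- tibble::tibble(conc_ng = c(2, 5, 20), intensity = c(50, 50, 50))
  expect_equal(emsa_score(flat, ctl), 0)
  ## contract violations
  expect_error(emsa_score(tibble::tibble(conc_ng = c(0, 5),
                                         intensity = c(1, 2)), ctl),
               "positive")
  expect_error(emsa_score(tibble::tibble(conc_ng = c(5, 5),
                                         intensity = c(1, 2)), ctl),
               "span")
  ## a positive slope (intensity rising) is clamped to 0 with a warning
  rising <- tibble::tibble(conc_ng = c(2, 5, 20), intensity = c(10, 50, 90))
  expect_warning(sc <- emsa_score(rising, ctl), "clamped")
  expect_equal(sc, 0)
})

test_that("affinity classes follow the strict non-site bin edge", {
  expect_equal(classify_affinity(0.24), "non-site")
  expect_equal(classify_affinity(0.25), "weak")
  expect_equal(classify_affinity(0.75), "weak")
  expect_equal(classify_affinity(0.80), "strong")
  expect_equal(classify_affinity(c(0, 0.5, 1)),
               c("non-site", "weak", "strong"))
})

test_that("derive_threshold takes the maximum non-site score strictly", {
  fake_model <- list(id = "m")
  tab <- tibble::tibble(oligo_id = c("a", "b", "c", "d"),
                        model_score = c(0.61, 0.70, 0.44, 0.95),
                        affinity_class = c("non-site", "non-site",
                                           "non-site", "strong"))
  ct <- derive_threshold(fake_model, tab)
  expect_equal(ct$threshold, 0.70)
  expect_setequal(attr(ct, "provenance"), c("a", "b", "c"))
  ## single non-site
  ct1 <- derive_threshold(fake_model, tab[tab$oligo_id == "a" |
                                            tab$oligo_id == "d", ])
  expect_equal(ct1$threshold, 0.61)
  ## threshold monotonicity: adding a non-site can only raise it
  tab2 <- dplyr::bind_rows(tab, tibble::tibble(oligo_id = "e",
                                               model_score = 0.8,
                                               affinity_class = "non-site"))
  expect_gte(derive_threshold(fake_model, tab2)$threshold, ct$threshold)
  expect_error(derive_threshold(fake_model,
                                tab[tab$affinity_class == "strong", ]),
               "non-site")
})

test_that("a simulated panel calibrates a generator-motif model correctly", {
  motif <- test_motif(core_mass = 0.95)
  panel <- make_emsa_oligo_panel(motif, n_strong = 5, n_weak = 5,
                                 n_nonsite = 6, seed = 31)
  curves <- simulate_emsa_panel(panel, noise_sd = 0.05, seed = 32)
  scored <- emsa_scores(curves)
  model <- motif_to_pwm(motif)
  ## independent per-site scoring oracle for the panel scores
  ms <- vapply(seq_len(nrow(panel)), function(i) {
    w <- substr(panel$seq[i], panel$core_start[i] + 1,
                panel$core_start[i] + motif$L)
    max(rescale_score(model, score_window(model, w)),
        rescale_score(model, score_window(model, w, strand = "-")))
  }, numeric(1))
  expect_equal(score_panel_oligos(panel, model)$model_score, ms,
               tolerance = 1e-12)
  tab <- dplyr::left_join(scored,
                          tibble::tibble(oligo_id = panel$id,
                                         model_score = ms),
                          by = "oligo_id")
  ct <- derive_threshold(model, tab)
  ns <- tab[tab$affinity_class == "non-site", ]
  expect_true(all(!(ns$model_score > ct$threshold)))
  strong <- tab[tab$affinity_class == "strong", ]
  expect_gte(mean(strong$model_score > ct$threshold), 0.8)
})

test_that("bin-edge sensitivity reports a CC per candidate edge", {
  motif <- test_motif()
  ps <- implanted_peak_set(40, 60, motif, seed = 41)
  model <- motif_to_pwm(motif)
  bg <- make_shuffled_background(ps$peaks, order = 1L, n_fold = 1L,
                                 seed = 42)
  oligo_scores <- tibble::tibble(oligo_id = sprintf("o%d", 1:10),
                                 emsa_score = seq(0.05, 0.95, length.out = 10),
                                 model_score = seq(0.45, 0.95,
                                                   length.out = 10))
  sens <- sensitivity_of_bin_edge(oligo_scores, ps$peaks, bg, model,
                                  edges = c(0.17, 0.25, 0.34))
  expect_equal(nrow(sens), 3)
  expect_true(all(sens$defined))
  ## an edge below every EMSA score leaves no non-sites: undefined
  sens0 <- sensitivity_of_bin_edge(oligo_scores, ps$peaks, bg, model,
                                   edges = 0.01)
  expect_false(sens0$defined)
})

test_that("EMSA curve files round-trip with the control flag", {
  oligos <- tibble::tibble(id = c("control", "x"), seq = NA,
                           affinity = c(1, 0.4))
  curves <- simulate_emsa_panel(oligos, noise_sd = 0.02, seed = 51)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_emsa_curves(curves, p)
  back <- read_emsa_curves(p)
  expect_equal(attr(back, "control_id"), "control")
  expect_equal(back$intensity, curves$intensity, tolerance = 1e-9)
  s1 <- emsa_scores(curves)
  s2 <- emsa_scores(back)
  expect_equal(s1$emsa_score, s2$emsa_score, tolerance = 1e-9)
})
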