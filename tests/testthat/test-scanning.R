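test_that("window scores equal an independent per-position recomputation", {
  sites <- random_dna(30, 10, seed = 81)
  pwm <- build_mono_pwm(sites)
  peaks <- tibble::tibble(id = sprintf("p%d", 1:10),
                          seq = random_dna(10, 50, seed = 82), height = 1)
  got <- score_windows(peaks, pwm)
  for (i in sample(nrow(got), 60)) {
    row <- got[i, ]
    pk <- peaks$seq[peaks$id == row$peak_id]
    w <- substr(pk, row$start + 1, row$start + 10)
    if (row$strand == "-") w <- reverse_complement(w)
    expect_equal(row$score, rescale_score(pwm, brute_pwm_score(pwm, w)),
                 tolerance = 1e-12)
  }
})

test_that("a single implanted consensus yields exactly one hit", {
  cons <- "TTTTGGGGCCCC"
  anti <- strrep("A", 80)
  sites <- c(cons, cons, cons, "TTTTGGGGCCCA")  # near-consensus training
  pwm <- build_mono_pwm(sites)
  seq <- paste0(substr(anti, 1, 30), cons, substr(anti, 1, 38))
  peaks <- tibble::tibble(id = "p", seq = seq, height = 1)
  hits <- scan_peaks(peaks, pwm, threshold = 0.95)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 30)
  expect_equal(hits$strand, "+")
  ## threshold above the attainable maximum yields no hits
  expect_equal(nrow(scan_peaks(peaks, pwm, threshold = 1, strict = TRUE)), 0)
})

test_that("hit counts are non-increasing in the threshold and never overlap", {
  sites <- random_dna(25, 8, seed = 91)
  pwm <- build_mono_pwm(sites)
  peaks <- tibble::tibble(id = sprintf("p%d", 1:5),
                          seq = random_dna(5, 120, seed = 92), height = 1)
  ths <- seq(0.3, 0.9, by = 0.1)
  counts <- vapply(ths, function(t) nrow(scan_peaks(peaks, pwm, t)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  hits <- scan_peaks(peaks, pwm, 0.5)
  for (id in unique(hits$peak_id)) {
    st <- sort(hits$start[hits$peak_id == id])
    if (length(st) > 1) expect_true(all(diff(st) >= 8))
  }
})

test_that("N bases remove exactly the windows covering them", {
  sites <- random_dna(20, 6, seed = 101)
  pwm <- build_mono_pwm(sites)
  clean <- random_dna(1, 40, seed = 102)
  dirty <- clean
  substr(dirty, 20, 20) <- "N"
  s_clean <- score_windows(tibble::tibble(id = "p", seq = clean, height = 1),
                           pwm)
  s_dirty <- score_windows(tibble::tibble(id = "p", seq = dirty, height = 1),
                           pwm)
  lost <- setdiff(paste(s_clean$start, s_clean$strand),
                  paste(s_dirty$start, s_dirty$strand))
  lost_starts <- as.integer(sub(" .*", "", lost))
  ## exactly the windows overlapping position 19 (0-based) are gone
  expect_setequal(unique(lost_starts), 14:19)
  kept <- dplyr::inner_join(s_clean, s_dirty, by = c("start", "strand"))
  expect_equal(kept$score.x, kept$score.y, tolerance = 1e-12)
})

test_that("recognized_fraction is monotone and hits the trivial cases", {
  motif <- test_motif()
  ps <- implanted_peak_set(40, 60, motif, seed = 111)
  pwm <- build_mono_pwm(generate_training_sites(motif, 50, seed = 112))
  expect_equal(recognized_fraction(ps$peaks, pwm, 0), 1)
  fr <- vapply(c(0.2, 0.5, 0.8, 0.95),
               function(t) recognized_fraction(ps$peaks, pwm, t), numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_error(recognized_fraction(ps$peaks[0, ], pwm, 0.5), "empty")
})

test_that("hit overlap uses half-open windows and is symmetric", {
  h1 <- tibble::tibble(peak_id = "p", start = 10)
  h2 <- tibble::tibble(peak_id = "p", start = 17)
  h3 <- tibble::tibble(peak_id = "p", start = 18)
  expect_true(hits_overlap(h1, h2, 8, 8))
  expect_false(hits_overlap(h1, h3, 8, 8))
  expect_equal(hits_overlap(h1, h2, 8, 8), hits_overlap(h2, h1, 8, 8))
  expect_error(hits_overlap(h1, tibble::tibble(peak_id = "q", start = 1),
                            8, 8), "different peaks")
})

test_that("scanning a reverse-complemented peak mirrors coordinates", {
  sites <- random_dna(20, 9, seed = 121)
  pwm <- build_mono_pwm(sites)
  seq <- random_dna(1, 45, seed = 122)
  fwd <- score_windows(tibble::tibble(id = "p", seq = seq, height = 1), pwm)
  rev <- score_windows(tibble::tibble(id = "p",
                                      seq = reverse_complement(seq),
                                      height = 1), pwm)
  n <- 45
  remapped <- rev
  remapped$start <- n - 9 - rev$start
  remapped$strand <- ifelse(rev$strand == "+", "-", "+")
  joined <- dplyr::inner_join(fwd, remapped, by = c("start", "strand"))
  expect_equal(nrow(joined), nrow(fwd))
  expect_equal(joined$score.x, joined$score.y, tolerance = 1e-12)
})

test_that("hits export as BED6 with scaled integer scores", {
  hits <- tibble::tibble(peak_id = "p1", start = 5L, strand = "+",
                         model_id = "m", score = 0.8766)
  p <- withr::local_tempfile(fileext = ".bed")
  write_hits_bed(hits, p, L = 10)
  bed <- read_bed(p)
  expect_equal(bed$start, 5)
  expect_equal(bed$end, 15)
  expect_equal(bed$score, 877)
})
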