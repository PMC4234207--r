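make_occurrences <- function(peaks, L, offsets = 0L, strand = "+") {
  tibble::tibble(peak_id = peaks$id,
                 offset = rep_len(offsets, nrow(peaks)),
                 strand = rep_len(strand, nrow(peaks)))
}

test_that("KDIC matches closed forms and the brute-force oracle", {
  peaks <- tibble::tibble(id = as.character(1:6),
                          seq = rep("TGTTTACTGGGG", 6), height = 20)
  occ <- make_occurrences(peaks, 8L)
  ## identical occurrences, uniform q, vanishing pseudocount: L * ln 4
  expect_equal(kdic(occ, peaks, 8, pseudocount = 1e-9), 8 * log(4),
               tolerance = 1e-4)
  ## columns at background composition: KDIC near 0
  flat <- tibble::tibble(id = as.character(1:4),
                         seq = c("ACGT", "CGTA", "GTAC", "TACG"), height = 1)
  expect_lt(kdic(make_occurrences(flat, 4L), flat, 4, pseudocount = 1e-9),
            0.01)
  ## random alignments: non-negative and equal to the oracle
  peaks2 <- tibble::tibble(id = as.character(1:10),
                           seq = random_dna(10, 30, seed = 2), height = 1)
  withr::with_seed(3, {
    for (r in 1:5) {
      occ2 <- tibble::tibble(peak_id = peaks2$id,
                             offset = sample(0:20, 10, replace = TRUE),
                             strand = sample(c("+", "-"), 10, replace = TRUE))
      wins <- vapply(seq_len(10), function(i) {
        w <- substr(peaks2$seq[i], occ2$offset[i] + 1, occ2$offset[i] + 10)
        if (occ2$strand[i] == "-") reverse_complement(w) else w
      }, character(1))
      got <- kdic(occ2, peaks2, 10, q = rep(0.25, 4), pseudocount = 1)
      expect_gte(got, 0)
      expect_equal(got, brute_kl_info(wins, rep(0.25, 4), 1, "mono"),
                   tolerance = 1e-10)
    }
  })
  expect_error(kdic(make_occurrences(peaks, 8L, offsets = 90L), peaks, 8),
               "bounds")
})

test_that("KDDIC matches closed forms and exceeds independence under dependence", {
  peaks <- tibble::tibble(id = as.character(1:5),
                          seq = rep("TGTTTACTGG", 5), height = 1)
  occ <- make_occurrences(peaks, 8L)
  expect_equal(kddic(occ, peaks, 8, pseudocount = 1e-9), 7 * log(16),
               tolerance = 1e-3)
  expect_gte(kddic(occ, peaks, 8), 0)
  ## oracle equality on random alignments
  peaks2 <- tibble::tibble(id = as.character(1:8),
                           seq = random_dna(8, 25, seed = 4), height = 1)
  occ2 <- make_occurrences(peaks2, 9L, offsets = c(0L, 3L, 5L, 7L),
                           strand = c("+", "-"))
  wins <- vapply(seq_len(8), function(i) {
    w <- substr(peaks2$seq[i], occ2$offset[i] + 1, occ2$offset[i] + 9)
    if (occ2$strand[i] == "-") reverse_complement(w) else w
  }, character(1))
  expect_equal(kddic(occ2, peaks2, 9, Q = rep(1/16, 16), pseudocount = 1),
               brute_kl_info(wins, rep(1/16, 16), 1, "di"), tolerance = 1e-10)
  ## first-order-dependent sites: KDDIC above the value implied by their
  ## mononucleotide columns under independence
  dep <- make_dependent_motif(stay = 0.7)
  sites <- generate_training_sites(dep, 120, seed = 5)
  pk <- tibble::tibble(id = as.character(1:120), seq = sites$seq, height = 1)
  occ3 <- make_occurrences(pk, 12L)
  counts <- vapply(1:12, function(j) {
    table(factor(substr(pk$seq, j, j), levels = c("A", "C", "G", "T")))
  }, numeric(4))
  f <- (counts + 0.25) / (120 + 1)
  indep_kddic <- 0
  for (j in 1:11) {
    for (a in 1:4) for (b in 1:4) {
      fa <- f[a, j] * f[b, j + 1]
      indep_kddic <- indep_kddic + fa * log(fa / (1/16))
    }
  }
  expect_gt(kddic(occ3, pk, 12), indep_kddic + 0.5)
})

test_that("single-peak discovery finds the exhaustively best window", {
  peak <- tibble::tibble(id = c("a", "b"),
                         seq = random_dna(2, 60, seed = 6), height = 1)
  res <- greedy_discover(peak, 8, mode = "mono", n_starts = 4, seed = 7)
  ## oracle: exhaustively evaluate all two-window alignments
  offs <- 0:52
  best <- -Inf
  for (o1 in offs) for (s1 in c("+", "-")) {
    for (o2 in offs) for (s2 in c("+", "-")) {
      occ <- tibble::tibble(peak_id = c("a", "b"), offset = c(o1, o2),
                            strand = c(s1, s2))
      v <- kdic(occ, peak, 8, q = res$q, pseudocount = 1)
      if (v > best) best <- v
    }
  }
  expect_equal(res$objective, best, tolerance = 1e-9)
})

test_that("discovery recovers a literal implanted motif", {
  bg <- generate_background(uniform_chain(), 50, 60, seed = 8)
  withr::with_seed(9, {
    seqs <- bg$seq
    for (i in 1:50) {
      st <- sample.int(60 - 8 + 1, 1)
      substr(seqs[i], st, st + 7) <- "TGTTTACT"
    }
    bg$seq <- seqs
  })
  res <- greedy_discover(bg, 8, mode = "mono", n_starts = 10, seed = 10)
  expect_true(res$consensus == "TGTTTACT" ||
                reverse_complement(res$consensus) == "TGTTTACT")
  expect_equal(nrow(res$occurrences), 50)
})

test_that("greedy objective traces never decrease within a start", {
  motif <- test_motif()
  ps <- implanted_peak_set(40, 80, motif, seed = 11)
  res <- greedy_discover(ps$peaks, 12, mode = "mono", n_starts = 3, seed = 12)
  for (tr in res$traces) {
    for (seg in tr) expect_true(all(diff(seg) >= -1e-6))
  }
  ## self-consistency: reported objective equals a recomputation
  expect_equal(res$objective,
               kdic(res$occurrences, ps$peaks, 12, q = res$q,
                    pseudocount = res$pseudocount),
               tolerance = 1e-9)
  di <- greedy_discover(ps$peaks, 12, mode = "di", n_starts = 2, seed = 13)
  expect_equal(di$objective,
               kddic(di$occurrences, ps$peaks, 12, Q = di$q,
                     pseudocount = di$pseudocount),
               tolerance = 1e-9)
})

test_that("discovery is strand-coherent on reverse-complemented input", {
  motif <- test_motif()
  ps <- implanted_peak_set(40, 70, motif, seed = 14)
  res_f <- greedy_discover(ps$peaks, 10, mode = "mono", n_starts = 5,
                           seed = 15)
  rc_peaks <- ps$peaks
  rc_peaks$seq <- reverse_complement(rc_peaks$seq)
  res_r <- greedy_discover(rc_peaks, 10, mode = "mono", n_starts = 5,
                           seed = 15)
  expect_equal(res_f$objective, res_r$objective, tolerance = 0.2)
})

test_that("shape weighting biases occurrences toward the coverage summit", {
  motif <- test_motif(core_mass = 0.9999)
  bg <- generate_background(uniform_chain(), 30, 60, seed = 16)
  ## two identical consensus copies per peak; profile peaks over the first
  withr::with_seed(17, {
    cons <- vapply(1:30, function(i) tfbsbench:::.draw_site(motif),
                   character(1))
    seqs <- bg$seq
    for (i in 1:30) {
      substr(seqs[i], 6, 17) <- cons[i]
      substr(seqs[i], 41, 52) <- cons[i]
    }
    bg$seq <- seqs
  })
  prof <- lapply(1:30, function(i) {
    p <- rep(1, 60); p[1:30] <- 30; p
  })
  bg$profile <- prof
  res <- greedy_discover(bg, 12, mode = "mono", n_starts = 5, seed = 18,
                         use_shape = TRUE)
  near_first <- mean(abs(res$occurrences$offset - 5) <= 2)
  expect_gt(near_first, 0.7)
})

test_that("discovered-length optimisation selects near the true length", {
  motif <- test_motif(core_mass = 0.95)
  ps <- implanted_peak_set(80, 70, motif, seed = 19)
  opt <- optimize_discovered_length(ps$peaks, c(8, 12, 16), mode = "mono",
                                    seed = 20, n_starts = 4)
  expect_true(opt$best_length %in% c(8, 12, 16))
  expect_equal(nrow(opt$table), 3)
  one <- optimize_discovered_length(ps$peaks, 12, mode = "mono", seed = 21,
                                    n_starts = 2)
  expect_equal(one$best_length, 12)
})
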