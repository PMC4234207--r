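## End-to-end orchestration of the study: simulate -> train -> calibrate ->
## scan -> benchmark, with a declarative config, derived per-stage seeds and
## plain-text artifacts throughout (diff-able, re-loadable).

#' Default pipeline configuration
#'
#' A nested list describing one full in-silico study: synthetic peak set
#' with implanted FoxA-like sites, curated-style training alignment, EMSA
#' panel, four models (length-optimised mono-PWM, SiteGA discriminant,
#' greedy KDIC mono matrix, greedy KDDIC dinucleotide matrix), EMSA
#' threshold calibration and the benchmark suite. Every random stage derives
#' its own seed from `seed`.
#'
#' @param outdir Output directory for all artifacts.
#' @param seed Master integer seed.
#' @return A `run_config` list.
#' @export
default_config <- function(outdir = tempfile("tfbs_run_"), seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    outdir = outdir,
    simulate = list(
      n_peaks = 300L, peak_len = 120L, order = 1L,
      min_height = 15, height_size = 2, height_mu = 25,
      sites_per_peak = c("1" = 0.4, "2" = 0.4, "3" = 0.2),
      core_mass = 0.85,
      n_training = 53L, training_flank = 10L,
      emsa = list(n_nonsite = 20L, n_binder = 44L,
                  flank_len = 6L, noise_sd = 0.05,
                  concentrations = c(2, 5, 20))),
    train = list(
      opwm_lengths = c(8L, 12L, 16L, 20L, 24L, 28L, 32L),
      tp_anchor = 0.9,
      discovery_L = 12L, n_starts = 10L, bootstrap_frac = 0.5,
      sitega = list(K = 12L, pop_size = 30L, generations = 30L,
                    crossover = 0.7, mutation = 0.1, elitism = 2L)),
    benchmark = list(
      n_fold = 10L, order = 1L,
      pair = c("sitega", "kdic_pwm"))),
    class = "run_config")
}

.config_hash <- function(config) {
  rlang::hash(config[setdiff(names(config), "outdir")])
}

.stage_log <- function(config, stage, seeds) {
  path <- file.path(config$outdir, "run_log.tsv")
  line <- sprintf("%s\t%s\t%s", stage, .config_hash(config),
                  paste(sprintf("%s=%d", names(seeds), seeds), collapse = ","))
  if (!file.exists(path)) {
    writeLines(c("stage\tconfig_hash\tseeds", line), path)
  } else {
    ## idempotent per stage: replace an existing line for the same stage
    lines <- readLines(path)
    lines <- lines[!grepl(paste0("^", stage, "\t"), lines)]
    writeLines(c(lines, line), path)
  }
  invisible(path)
}

#' Simulate a full synthetic dataset to disk
#'
#' Writes FASTA + BED6+1 peaks with implanted sites, the ground-truth TSV
#' and the aligned training-site set, plus a run log recording the config
#' hash and stage seeds. (The EMSA verification panel is built later, at
#' the calibration stage, from the trained models' own predictions.)
#'
#' @param config A [default_config()]-style list.
#' @return Invisibly, a list with the in-memory `peak_set` and `sites`.
#' @export
pipeline_simulate <- function(config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(config$outdir, 2) != 0) {
    stop(sprintf("output directory not writable: %s", config$outdir),
         call. = FALSE)
  }
  sc <- config$simulate
  seeds <- c(background = derive_seed(config$seed, "background"),
             implant = derive_seed(config$seed, "implant"),
             training = derive_seed(config$seed, "training"))
  motif <- default_foxa_motif(core_mass = sc$core_mass)
  chain <- structure(list(order = 1L, p0 = rep(0.25, 4),
                          transition = matrix(0.25, 4, 4)),
                     class = "markov_model")
  bg <- generate_background(chain, sc$n_peaks, sc$peak_len,
                            seed = seeds[["background"]],
                            min_height = sc$min_height,
                            height_size = sc$height_size,
                            height_mu = sc$height_mu)
  peak_set <- implant_sites(bg, motif, sites_per_peak = sc$sites_per_peak,
                            seed = seeds[["implant"]])
  sites <- generate_training_sites(motif, sc$n_training,
                                   flank_len = sc$training_flank,
                                   seed = seeds[["training"]])
  write_fasta(peak_set$peaks, file.path(config$outdir, "peaks.fa"))
  write_peak_table(peak_set$peaks, file.path(config$outdir, "peaks.tsv"))
  write_truth(peak_set, file.path(config$outdir, "truth.tsv"))
  write_aligned_sites(sites, file.path(config$outdir, "training_sites.txt"))
  .stage_log(config, "simulate", seeds)
  invisible(list(peak_set = peak_set, sites = sites))
}

.model_paths <- function(config) {
  dir <- file.path(config$outdir, "models")
  list(dir = dir,
       opwm = file.path(dir, "opwm.txt"),
       sitega = file.path(dir, "sitega.txt"),
       kdic = file.path(dir, "kdic_pwm.txt"),
       kddic = file.path(dir, "kddic_dipwm.txt"))
}

.load_models <- function(config) {
  mp <- .model_paths(config)
  list(opwm = read_pwm(mp$opwm), sitega = read_sitega(mp$sitega),
       kdic_pwm = read_pwm(mp$kdic), kddic_dipwm = read_pwm(mp$kddic))
}

.read_peaks <- function(config) {
  read_peak_table(file.path(config$outdir, "peaks.tsv"),
                  file.path(config$outdir, "peaks.fa"))
}

#' Train all four model kinds from the simulated dataset
#'
#' Pattern matching: length-optimised mono-PWM (oPWM) and SiteGA, trained on
#' the curated-style alignment. Pattern discovery: greedy KDIC mono matrix
#' and greedy KDDIC dinucleotide matrix, trained on the peaks themselves.
#' Models are serialised as plain text under `models/`.
#'
#' @param config A [default_config()]-style list.
#' @return Invisibly, the named list of trained models.
#' @export
pipeline_train <- function(config) {
  tc <- config$train
  for (f in c("peaks.tsv", "peaks.fa", "training_sites.txt")) {
    if (!file.exists(file.path(config$outdir, f))) {
      stop(sprintf("missing training input %s; run pipeline_simulate first", f),
           call. = FALSE)
    }
  }
  peaks <- .read_peaks(config)
  sites <- read_aligned_sites(file.path(config$outdir, "training_sites.txt"))
  seeds <- c(opwm_bg = derive_seed(config$seed, "opwm_bg"),
             sitega = derive_seed(config$seed, "sitega"),
             kdic = derive_seed(config$seed, "kdic"),
             kddic = derive_seed(config$seed, "kddic"))
  bg1 <- make_shuffled_background(peaks, order = 1L, n_fold = 1L,
                                  seed = seeds[["opwm_bg"]])
  opt <- optimize_length(sites, bg1,
                         candidate_lengths = tc$opwm_lengths,
                         tp_anchor = tc$tp_anchor, type = "mono")
  opwm <- opt$model
  opwm$id <- "opwm"
  sg_sites <- trim_aligned_sites(sites, opt$best_length)
  sitega <- evolve_feature_set(sg_sites, K = tc$sitega$K,
                               ga_params = tc$sitega,
                               seed = seeds[["sitega"]], id = "sitega")
  kdic_res <- greedy_discover(peaks, tc$discovery_L, mode = "mono",
                              n_starts = tc$n_starts,
                              bootstrap_frac = tc$bootstrap_frac,
                              seed = seeds[["kdic"]], id = "kdic_pwm")
  kddic_res <- greedy_discover(peaks, tc$discovery_L, mode = "di",
                               n_starts = tc$n_starts,
                               bootstrap_frac = tc$bootstrap_frac,
                               seed = seeds[["kddic"]], id = "kddic_dipwm")
  mp <- .model_paths(config)
  dir.create(mp$dir, recursive = TRUE, showWarnings = FALSE)
  write_pwm(opwm, mp$opwm)
  write_sitega(sitega, mp$sitega)
  write_pwm(kdic_res$model, mp$kdic)
  write_pwm(kddic_res$model, mp$kddic)
  write_occurrences(kdic_res, file.path(mp$dir, "kdic_occurrences.tsv"))
  write_occurrences(kddic_res, file.path(mp$dir, "kddic_occurrences.tsv"))
  readr::write_tsv(opt$table, file.path(mp$dir, "opwm_length_table.tsv"),
                   progress = FALSE)
  .stage_log(config, "train", seeds)
  invisible(list(opwm = opwm, sitega = sitega, kdic_pwm = kdic_res$model,
                 kddic_dipwm = kddic_res$model))
}

#' Calibrate per-model thresholds by simulated EMSA verification
#'
#' Emulates the experimental verification round: the trained models\'
#' top-scoring predictions in the peaks are pooled into an oligo panel,
#' classified as binder/non-binder against the implant ground truth,
#' EMSA competition curves are simulated at the assigned affinities, and
#' each model\'s threshold is set at the highest model score among the
#' oligos whose EMSA score falls in the non-site bin.
#'
#' @param config A [default_config()]-style list.
#' @return Invisibly, the thresholds tibble.
#' @export
pipeline_calibrate <- function(config) {
  sc <- config$simulate
  models <- .load_models(config)
  peaks <- .read_peaks(config)
  truth <- readr::read_tsv(file.path(config$outdir, "truth.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  seeds <- c(panel = derive_seed(config$seed, "panel"),
             curves = derive_seed(config$seed, "curves"))
  oligos <- select_verification_oligos(
    list(peaks = peaks, truth = truth), models,
    n_nonsite = sc$emsa$n_nonsite, n_binder = sc$emsa$n_binder,
    flank_len = sc$emsa$flank_len, seed = seeds[["panel"]])
  curves <- simulate_emsa_panel(oligos,
                                concentrations = sc$emsa$concentrations,
                                noise_sd = sc$emsa$noise_sd,
                                seed = seeds[["curves"]])
  readr::write_tsv(oligos, file.path(config$outdir, "emsa_oligos.tsv"),
                   progress = FALSE)
  write_emsa_curves(curves, file.path(config$outdir, "emsa_curves.tsv"))
  scored <- emsa_scores(curves)
  thresholds <- purrr::map(models, function(m) {
    ms <- .best_scores(tibble::tibble(id = oligos$id, seq = oligos$seq), m)
    tab <- dplyr::left_join(scored,
                            tibble::tibble(oligo_id = oligos$id,
                                           model_score = ms),
                            by = "oligo_id")
    derive_threshold(m, tab)
  })
  out <- dplyr::bind_rows(thresholds)
  readr::write_tsv(out, file.path(config$outdir, "thresholds.tsv"),
                   progress = FALSE)
  readr::write_tsv(scored, file.path(config$outdir, "emsa_scores.tsv"),
                   progress = FALSE)
  .stage_log(config, "calibrate", seeds)
  invisible(out)
}

.read_thresholds <- function(config) {
  tab <- readr::read_tsv(file.path(config$outdir, "thresholds.tsv"),
                         show_col_types = FALSE, progress = FALSE)
  stats::setNames(tab$threshold, tab$model_id)
}

#' Scan the peaks with every calibrated model
#'
#' Hits pass their model's EMSA-derived threshold strictly and are written
#' as TSV and BED6; per-model recognized-peak fractions go to
#' `recognized.tsv`.
#'
#' @param config A [default_config()]-style list.
#' @return Invisibly, a named list of hit tibbles.
#' @export
pipeline_scan <- function(config) {
  peaks <- .read_peaks(config)
  models <- .load_models(config)
  thr <- .read_thresholds(config)
  hits <- purrr::map(models, function(m) {
    scan_peaks(peaks, m, unname(thr[model_id(m)]), strict = TRUE)
  })
  for (nm in names(hits)) {
    write_hits_tsv(hits[[nm]], file.path(config$outdir,
                                         sprintf("hits_%s.tsv", nm)))
    write_hits_bed(hits[[nm]], file.path(config$outdir,
                                         sprintf("hits_%s.bed", nm)),
                   L = model_width(models[[nm]]), peaks = peaks)
  }
  rec <- tibble::tibble(
    model_id = names(models),
    threshold = unname(thr[names(models)]),
    n_sites = vapply(hits, nrow, integer(1)),
    recognized_fraction = vapply(names(models), function(nm) {
      recognized_fraction(peaks, models[[nm]], unname(thr[nm]), strict = TRUE)
    }, numeric(1)))
  readr::write_tsv(rec, file.path(config$outdir, "recognized.tsv"),
                   progress = FALSE)
  .stage_log(config, "scan", c(scan = config$seed))
  invisible(hits)
}

#' Benchmark all models and the configured model pair
#'
#' Builds a Markov-shuffled background, computes per-model ROC/AUC and the
#' Matthews CC at the calibrated thresholds, runs the pairwise combination
#' analysis (with union recognition and homotypic-cluster fraction) for the
#' configured pair, and the tenfold chance-overlap chi-squared test.
#'
#' @param config A [default_config()]-style list.
#' @return Invisibly, the report list (also written as `report.json`).
#' @export
pipeline_benchmark <- function(config) {
  bc <- config$benchmark
  peaks <- .read_peaks(config)
  models <- .load_models(config)
  thr <- .read_thresholds(config)
  seeds <- c(roc_bg = derive_seed(config$seed, "roc_bg"),
             chance = derive_seed(config$seed, "chance"))
  bg <- make_shuffled_background(peaks, order = bc$order, n_fold = 1L,
                                 seed = seeds[["roc_bg"]])
  per_model <- purrr::map(names(models), function(nm) {
    m <- models[[nm]]
    roc <- roc_curve(peaks, bg, m)
    readr::write_tsv(roc$points,
                     file.path(config$outdir, sprintf("roc_%s.tsv", nm)),
                     progress = FALSE)
    t0 <- unname(thr[nm])
    best_real <- .best_scores(peaks, m)
    best_bg <- .best_scores(bg, m)
    counts <- confusion_counts(
      tp = sum(best_real > t0, na.rm = TRUE),
      fn = nrow(peaks) - sum(best_real > t0, na.rm = TRUE),
      fp = sum(best_bg > t0, na.rm = TRUE),
      tn = nrow(bg) - sum(best_bg > t0, na.rm = TRUE))
    tibble::tibble(model_id = nm, threshold = t0, auc = roc$auc,
                   tp_rate = counts$tp / nrow(peaks),
                   fp_rate = counts$fp / nrow(bg),
                   cc = correlation_coefficient(counts))
  })
  per_model <- dplyr::bind_rows(per_model)
  readr::write_tsv(per_model, file.path(config$outdir, "benchmark.tsv"),
                   progress = FALSE)

  report <- list(config_hash = .config_hash(config),
                 seed = config$seed,
                 per_model = per_model)
  if (length(bc$pair) == 2L && all(bc$pair %in% names(models))) {
    m1 <- models[[bc$pair[1]]]; m2 <- models[[bc$pair[2]]]
    h1 <- scan_peaks(peaks, m1, unname(thr[bc$pair[1]]), strict = TRUE)
    h2 <- scan_peaks(peaks, m2, unname(thr[bc$pair[2]]), strict = TRUE)
    comb <- combination_analysis(peaks, h1, h2, model_width(m1),
                                 model_width(m2))
    readr::write_tsv(tidy(comb),
                     file.path(config$outdir,
                               sprintf("combination_%s_%s.tsv",
                                       bc$pair[1], bc$pair[2])),
                     progress = FALSE)
    chance <- chance_overlap_test(peaks, m1, m2,
                                  thresholds = unname(thr[bc$pair]),
                                  n_fold = bc$n_fold,
                                  seed = seeds[["chance"]],
                                  order = bc$order)
    union_frac <- mean(comb$per_peak$category != "neither")
    pair_report <- list(pair = bc$pair,
                        union_recognized_fraction = union_frac,
                        cluster_fraction = comb$cluster_fraction,
                        categories = as.list(comb$counts),
                        chance_overlap = glance(chance))
    report$pair <- pair_report
  } else if (length(bc$pair) < 2L) {
    message("benchmark pair not configured; skipping combination analysis")
  }
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .stage_log(config, "benchmark", seeds)
  invisible(report)
}

#' Run the full pipeline
#'
#' `simulate -> train -> calibrate -> scan -> benchmark` under one config;
#' identical config and seed give byte-identical artifacts.
#'
#' @param config A [default_config()]-style list.
#' @return Invisibly, the benchmark report list.
#' @export
pipeline_all <- function(config) {
  pipeline_simulate(config)
  pipeline_train(config)
  pipeline_calibrate(config)
  pipeline_scan(config)
  report <- pipeline_benchmark(config)
  invisible(report)
}
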