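## SiteGA-style model: a linear discriminant over locally positioned
## dinucleotide (LPD) frequencies, with the feature set selected by a
## genetic algorithm to separate training sites from background.

#' Locally positioned dinucleotide features
#'
#' A feature is the frequency of one dinucleotide within a sub-window
#' ``[start, end)`` of the scored site: the count of the dinucleotide over
#' positions `start .. end-2` divided by `end - start - 1`.
#'
#' @param start,end 0-based half-open window bounds, `end - start >= 2`.
#' @param dinuc Dinucleotide string (e.g. `"TT"`).
#' @return A one-row tibble (`start`, `end`, `dinuc`).
#' @export
lpd_feature <- function(start, end, dinuc) {
  stopifnot(end - start >= 2L, start >= 0L, dinuc %in% .DINUCS)
  tibble::tibble(start = as.integer(start), end = as.integer(end),
                 dinuc = dinuc)
}

#' Extract one LPD feature value from a sequence
#'
#' @param seq ACGT string (the full site window).
#' @param feature A one-row feature tibble from [lpd_feature()].
#' @return Frequency in \[0, 1\].
#' @export
extract_feature <- function(seq, feature) {
  v <- seq_to_int(toupper(seq))
  if (feature$end > length(v)) stop("feature window outside sequence", call. = FALSE)
  d <- dinuc_codes(v)
  code <- match(feature$dinuc, .DINUCS)
  idx <- (feature$start + 1L):(feature$end - 1L)
  mean(d[idx] == code)
}

## n x K feature matrix for integer-encoded sequences of equal width.
.feature_matrix <- function(int_mat, features) {
  n <- nrow(int_mat)
  K <- nrow(features)
  d <- t(apply(int_mat, 1, dinuc_codes))
  if (ncol(int_mat) == 2L) d <- matrix(d, ncol = 1L)
  X <- matrix(0, n, K)
  codes <- match(features$dinuc, .DINUCS)
  for (k in seq_len(K)) {
    idx <- (features$start[k] + 1L):(features$end[k] - 1L)
    X[, k] <- rowMeans(d[, idx, drop = FALSE] == codes[k])
  }
  X
}

#' Fit a Fisher linear discriminant on LPD features
#'
#' `w` is proportional to `(Sigma_pooled + lambda I)^{-1} (mu_site - mu_bg)`
#' with the intercept at the midpoint of the projected class means and the
#' orientation fixed so that sites project higher. A singular pooled
#' covariance triggers an automatic increase of the ridge `lambda`.
#'
#' @param features Feature tibble (`start`, `end`, `dinuc`).
#' @param site_seqs,background_seqs Character vectors of equal-width ACGT
#'   sequences, at least two per class.
#' @param lambda Initial ridge regularisation.
#' @return A list with `weights`, `intercept`, `lambda` and the feature
#'   tibble.
#' @export
fit_discriminant <- function(features, site_seqs, background_seqs,
                             lambda = 1e-6) {
  site_seqs <- .site_strings(site_seqs)
  background_seqs <- .site_strings(background_seqs)
  stopifnot(length(site_seqs) >= 2L, length(background_seqs) >= 2L)
  X1 <- .feature_matrix(.site_matrix(site_seqs), features)
  X0 <- .feature_matrix(.site_matrix(background_seqs), features)
  mu1 <- colMeans(X1); mu0 <- colMeans(X0)
  n1 <- nrow(X1); n0 <- nrow(X0)
  S <- (crossprod(sweep(X1, 2, mu1)) + crossprod(sweep(X0, 2, mu0))) /
    (n1 + n0 - 2)
  K <- nrow(features)
  scale0 <- mean(diag(S)) + 1e-12
  w <- NULL
  lam <- lambda
  repeat {
    w <- tryCatch(solve(S + diag(lam * scale0, K), mu1 - mu0),
                  error = function(e) NULL)
    if (!is.null(w) && all(is.finite(w))) break
    lam <- max(lam * 10, 1e-6)
    if (lam > 1e6) stop("could not regularise pooled covariance", call. = FALSE)
    message(sprintf("singular pooled covariance; raising ridge to %g", lam))
  }
  if (sum(w * (mu1 - mu0)) < 0) w <- -w
  intercept <- -sum(w * (mu1 + mu0) / 2)
  list(weights = as.numeric(w), intercept = intercept, lambda = lam,
       features = features)
}

## Leave-one-out Matthews CC of a linear read-out of the feature matrix.
## Uses the equivalence of the two-class discriminant direction with least
## squares on a 0/1 class label, whose LOO predictions have the closed form
## y - e/(1 - h).
.loo_cc <- function(X, y, lambda = 1e-8) {
  Xc <- cbind(1, X)
  A <- crossprod(Xc) + diag(lambda * (1 + mean(diag(crossprod(Xc)))),
                            ncol(Xc))
  Ai <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ai)) return(-1)
  H <- Xc %*% Ai
  h <- rowSums(H * Xc)
  fit <- as.numeric(Xc %*% (Ai %*% crossprod(Xc, y)))
  e <- y - fit
  h <- pmin(h, 1 - 1e-8)
  pred <- y - e / (1 - h)
  cls <- as.integer(pred > 0.5)
  tp <- as.numeric(sum(cls == 1 & y == 1)); fn <- as.numeric(sum(cls == 0 & y == 1))
  fp <- as.numeric(sum(cls == 1 & y == 0)); tn <- as.numeric(sum(cls == 0 & y == 0))
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

.random_feature <- function(width, win_range) {
  len <- sample(seq(win_range[1], min(win_range[2], width)), 1L)
  start <- sample.int(width - len + 1L, 1L) - 1L
  tibble::tibble(start = start, end = start + len,
                 dinuc = .DINUCS[sample.int(16L, 1L)])
}

.feature_key <- function(f) paste(f$start, f$end, f$dinuc)

.random_individual <- function(K, width, win_range) {
  feats <- .random_feature(width, win_range)
  while (nrow(feats) < K) {
    cand <- .random_feature(width, win_range)
    if (!.feature_key(cand) %in% .feature_key(feats)) {
      feats <- dplyr::bind_rows(feats, cand)
    }
  }
  feats
}

.mutate_individual <- function(feats, width, win_range, rate) {
  K <- nrow(feats)
  for (k in seq_len(K)) {
    if (stats::runif(1) >= rate) next
    move <- sample.int(3L, 1L)
    if (move == 1L) {        # jitter window bounds by up to 2
      st <- feats$start[k] + sample(-2:2, 1L)
      en <- feats$end[k] + sample(-2:2, 1L)
      st <- max(0L, min(st, width - 2L))
      en <- max(st + 2L, min(en, width))
      if (en - st > win_range[2]) en <- st + win_range[2]
      feats$start[k] <- as.integer(st); feats$end[k] <- as.integer(en)
    } else if (move == 2L) { # redraw dinucleotide
      feats$dinuc[k] <- .DINUCS[sample.int(16L, 1L)]
    } else {                 # full redraw
      feats[k, ] <- .random_feature(width, win_range)
    }
  }
  ## repair duplicates by redraw
  while (anyDuplicated(.feature_key(feats))) {
    dup <- which(duplicated(.feature_key(feats)))[1]
    feats[dup, ] <- .random_feature(width, win_range)
  }
  feats
}

#' Evolve an LPD feature set with a genetic algorithm
#'
#' Individuals are K-sets of LPD features; fitness is the leave-one-out
#' Matthews correlation coefficient of the linear discriminant separating
#' sites from background on those features. Uniform feature-exchange
#' crossover, bound/dinucleotide mutation, tournament selection and elitism;
#' the best individual ever seen is returned as a fitted `sitega_model`.
#'
#' @param site_seqs Training sites (character vector or [aligned_sites()]).
#' @param background_seqs Background sequences of the same width; when
#'   `NULL`, order-1 Markov sequences matched to the site composition are
#'   generated.
#' @param K Number of features per individual.
#' @param ga_params List with `pop_size`, `generations`, `crossover`,
#'   `mutation`, `elitism`.
#' @param seed Integer seed; runs are deterministic under a fixed seed.
#' @param win_range Allowed feature window lengths (bp).
#' @param n_background Number of background sequences generated when
#'   `background_seqs` is `NULL`.
#' @param id Model identifier.
#' @return An object of class `sitega_model` with the selected features,
#'   discriminant weights, rescaling range, best LOO-CC fitness and the
#'   per-generation best-fitness trace.
#' @export
evolve_feature_set <- function(site_seqs, background_seqs = NULL, K = 20,
                               ga_params = list(), seed = 1L,
                               win_range = c(2L, 8L), n_background = NULL,
                               id = "sitega") {
  gp <- utils::modifyList(list(pop_size = 50L, generations = 100L,
                               crossover = 0.7, mutation = 0.1,
                               elitism = 2L), ga_params)
  site_seqs <- .site_strings(site_seqs)
  width <- nchar(site_seqs[1])
  n_possible <- sum((width - seq(win_range[1], min(win_range[2], width)) + 1L) * 16L)
  if (K > n_possible) stop("K exceeds the number of possible features", call. = FALSE)
  withr::with_seed(seed, {
    if (is.null(background_seqs)) {
      chain <- fit_markov(site_seqs, order = 1L)
      nb <- if (is.null(n_background)) max(2L * length(site_seqs), 100L) else n_background
      background_seqs <- apply(.draw_markov_int(chain, nb, width), 1, int_to_seq)
    } else {
      background_seqs <- .site_strings(background_seqs)
    }
    M1 <- .site_matrix(site_seqs)
    M0 <- .site_matrix(background_seqs)
    Mall <- rbind(M1, M0)
    y <- c(rep(1L, nrow(M1)), rep(0L, nrow(M0)))
    fitness_of <- function(feats) .loo_cc(.feature_matrix(Mall, feats), y)

    pop <- replicate(gp$pop_size, .random_individual(K, width, win_range),
                     simplify = FALSE)
    fits <- vapply(pop, fitness_of, numeric(1))
    best_feats <- pop[[which.max(fits)]]
    best_fit <- max(fits)
    trace <- best_fit
    if (gp$generations > 0L) {
      for (g in seq_len(gp$generations)) {
        ord <- order(fits, decreasing = TRUE)
        newpop <- pop[ord[seq_len(gp$elitism)]]
        while (length(newpop) < gp$pop_size) {
          pick <- function() {
            c2 <- sample.int(gp$pop_size, 2L)
            pop[[c2[which.max(fits[c2])]]]
          }
          p1 <- pick(); p2 <- pick()
          if (stats::runif(1) < gp$crossover) {
            mask <- stats::runif(K) < 0.5
            child <- dplyr::bind_rows(p1[mask, , drop = FALSE],
                                      p2[!mask, , drop = FALSE])
            while (anyDuplicated(.feature_key(child))) {
              dup <- which(duplicated(.feature_key(child)))[1]
              child[dup, ] <- .random_feature(width, win_range)
            }
          } else {
            child <- p1
          }
          child <- .mutate_individual(child, width, win_range, gp$mutation)
          newpop <- c(newpop, list(child))
        }
        pop <- newpop
        fits <- vapply(pop, fitness_of, numeric(1))
        if (max(fits) > best_fit) {
          best_fit <- max(fits)
          best_feats <- pop[[which.max(fits)]]
        }
        trace <- c(trace, best_fit)
      }
    }
    disc <- fit_discriminant(best_feats, site_seqs, background_seqs)
    Xtr <- .feature_matrix(Mall, best_feats)
    s <- as.numeric(Xtr %*% disc$weights) + disc$intercept
    rng <- max(s) - min(s)
    s_min <- min(s) - 0.05 * rng
    s_max <- max(s) + 0.05 * rng
  })
  structure(list(width = as.integer(width), features = best_feats,
                 weights = disc$weights, intercept = disc$intercept,
                 s_min = s_min, s_max = s_max,
                 fitness = best_fit, fitness_trace = trace, id = id),
            class = c("sitega_model", "tfbs_model"))
}

#' @export
model_width.sitega_model <- function(model) model$width

#' Score a window with a SiteGA model
#'
#' The linear discriminant score is min-max rescaled over the training-time
#' score range (extended by a 5% margin) and clamped to \[0, 1\]. Strand `-`
#' scores the reverse complement; windows containing N are unscorable (`NA`).
#'
#' @param model A `sitega_model`.
#' @param window ACGT string of length `model$width`.
#' @param strand `"+"` or `"-"`.
#' @return Rescaled score in \[0, 1\], or `NA`.
#' @export
score_sitega <- function(model, window, strand = "+") {
  if (nchar(window) != model$width) {
    stop("window length must equal model width", call. = FALSE)
  }
  v <- seq_to_int(toupper(window))
  if (strand == "-") v <- rc_int(v)
  if (anyNA(v)) return(NA_real_)
  X <- .feature_matrix(matrix(v, nrow = 1L), model$features)
  s <- sum(X * model$weights) + model$intercept
  min(1, max(0, (s - model$s_min) / (model$s_max - model$s_min)))
}

#' @export
score_window.sitega_model <- function(model, window, strand = "+") {
  score_sitega(model, window, strand)
}

#' @export
.window_scores_int.sitega_model <- function(model, v) {
  W <- model$width
  noff <- length(v) - W + 1L
  if (noff < 1L) return(numeric(0))
  d <- dinuc_codes(v)
  nas <- cumsum(c(0L, is.na(d)))
  s <- rep(model$intercept, noff)
  codes <- match(model$features$dinuc, .DINUCS)
  i0 <- seq_len(noff) - 1L  # 0-based offsets
  for (k in seq_len(nrow(model$features))) {
    st <- model$features$start[k]; en <- model$features$end[k]
    ind <- cumsum(c(0, ifelse(is.na(d), 0, d == codes[k])))
    cnt <- ind[i0 + en] - ind[i0 + st + 1L]
    s <- s + model$weights[k] * cnt / (en - st - 1L)
  }
  ## windows whose dinucleotide track touches an N are unscorable
  bad <- (nas[i0 + W] - nas[i0 + 1L]) > 0L
  s[bad] <- NA_real_
  pmin(1, pmax(0, (s - model$s_min) / (model$s_max - model$s_min)))
}

#' Write / read a SiteGA model as plain text
#'
#' Lines: `#sitega <width> <K> <id>`, one `start end dinuc weight` line per
#' feature, then `intercept`, `s_min`, `s_max`.
#'
#' @param model A `sitega_model`.
#' @param path File path.
#' @return The reader returns the model; the writer `path`, invisibly.
#' @export
write_sitega <- function(model, path) {
  lines <- c(sprintf("#sitega %d %d %s", model$width, nrow(model$features),
                     model$id),
             sprintf("%d %d %s %s", model$features$start, model$features$end,
                     model$features$dinuc,
                     format(model$weights, digits = 17)),
             format(c(model$intercept, model$s_min, model$s_max), digits = 17))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sitega
#' @export
read_sitega <- function(path) {
  lines <- readLines(path)
  h <- strsplit(lines[1], "\\s+")[[1]]
  width <- as.integer(h[2]); K <- as.integer(h[3]); id <- h[4]
  feat_lines <- lines[2:(K + 1)]
  parts <- strsplit(trimws(feat_lines), "\\s+")
  features <- tibble::tibble(
    start = vapply(parts, function(p) as.integer(p[1]), integer(1)),
    end = vapply(parts, function(p) as.integer(p[2]), integer(1)),
    dinuc = vapply(parts, function(p) p[3], character(1)))
  weights <- vapply(parts, function(p) as.numeric(p[4]), numeric(1))
  tail3 <- as.numeric(lines[(K + 2):(K + 4)])
  structure(list(width = width, features = features, weights = weights,
                 intercept = tail3[1], s_min = tail3[2], s_max = tail3[3],
                 fitness = NA_real_, fitness_trace = numeric(0), id = id),
            class = c("sitega_model", "tfbs_model"))
}

#' @export
print.sitega_model <- function(x, ...) {
  cat(sprintf("<sitega_model> '%s', width %d, %d LPD features, LOO-CC %.3f\n",
              x$id, x$width, nrow(x$features), x$fitness))
  invisible(x)
}
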