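## Shared fixtures built in code.

uniform_chain <- function() {
  structure(list(order = 0L, p0 = rep(0.25, 4)), class = "markov_model")
}

random_dna <- function(n, len, seed = 1) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = "")
    }, character(1))
  })
}

## Brute-force per-position PWM window score, independent of the package's
## vectorised path.
brute_pwm_score <- function(model, window) {
  letters_ <- strsplit(window, "")[[1]]
  if (model$type == "mono") {
    idx <- match(letters_, c("A", "C", "G", "T"))
    sum(vapply(seq_along(idx), function(j) model$weights[j, idx[j]],
               numeric(1)))
  } else {
    di <- paste0(letters_[-length(letters_)], letters_[-1])
    cols <- match(di, as.vector(t(outer(c("A","C","G","T"),
                                        c("A","C","G","T"), paste0))))
    sum(vapply(seq_along(cols), function(j) model$weights[j, cols[j]],
               numeric(1)))
  }
}

## Brute-force SiteGA window score via per-feature substring counting.
brute_sitega_score <- function(model, window) {
  vals <- vapply(seq_len(nrow(model$features)), function(k) {
    f <- model$features[k, ]
    sub <- substr(window, f$start + 1, f$end)
    pairs <- vapply(seq_len(nchar(sub) - 1),
                    function(i) substr(sub, i, i + 1), character(1))
    mean(pairs == f$dinuc)
  }, numeric(1))
  s <- sum(vals * model$weights) + model$intercept
  min(1, max(0, (s - model$s_min) / (model$s_max - model$s_min)))
}

## Brute-force KDIC/KDDIC from an explicit window list.
brute_kl_info <- function(windows, q, pseudocount, alphabet = c("mono", "di")) {
  alphabet <- match.arg(alphabet)
  bases <- c("A", "C", "G", "T")
  if (alphabet == "mono") {
    letters_list <- lapply(windows, function(w) strsplit(w, "")[[1]])
    syms <- bases
  } else {
    letters_list <- lapply(windows, function(w) {
      l <- strsplit(w, "")[[1]]
      paste0(l[-length(l)], l[-1])
    })
    syms <- as.vector(t(outer(bases, bases, paste0)))
  }
  ncol_ <- length(letters_list[[1]])
  total <- 0
  for (j in seq_len(ncol_)) {
    col <- vapply(letters_list, `[[`, character(1), j)
    for (a in seq_along(syms)) {
      f <- (sum(col == syms[a]) + pseudocount * q[a]) /
        (length(col) + pseudocount)
      total <- total + f * log(f / q[a])
    }
  }
  total
}

## A small sharp test motif and matching training data.
test_motif <- function(core_mass = 0.95) default_foxa_motif(core_mass)

implanted_peak_set <- function(n_peaks, peak_len, motif, sites_per_peak = 1,
                               seed = 1) {
  bg <- generate_background(uniform_chain(), n_peaks, peak_len,
                            seed = derive_seed_pub(seed, "bg"))
  implant_sites(bg, motif, sites_per_peak = sites_per_peak,
                seed = derive_seed_pub(seed, "implant"))
}

## deterministic child seeds for fixtures, independent of package internals
derive_seed_pub <- function(seed, salt) {
  as.integer((seed * 7919 + sum(utf8ToInt(salt))) %% 2147483587) + 1L
}
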