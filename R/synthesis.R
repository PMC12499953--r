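#' Synthesize one fricative-like token
#'
#' Source-filter emulation of sibilant frication: seeded Gaussian white noise
#' is shaped by a two-pole resonator representing the front-cavity resonance
#' (centre `resonance_hz`, 3 dB bandwidth `bandwidth_hz`), optionally mixed
#' with a second resonator, given a first-order spectral tilt in dB/octave
#' (relative to 1 kHz), and optionally contaminated with band-limited
#' low-frequency rumble (flat below 200 Hz, raised-cosine edge to 300 Hz,
#' emulating ambient noise and voicing remnants) at a level in dB relative
#' to the frication RMS. Output is normalized to unit RMS.
#'
#' @param resonance_hz Front-cavity resonance in Hz (must be below Nyquist;
#'   the measurable band is 3-9 kHz).
#' @param duration_s Token duration in seconds.
#' @param bandwidth_hz Resonance 3 dB bandwidth in Hz.
#' @param tilt_db_per_oct Spectral tilt in dB per octave (0 = flat source).
#' @param secondary_resonance_hz Optional second resonance in Hz (`NA` for
#'   none).
#' @param secondary_gain_db Level of the secondary resonator relative to the
#'   primary, in dB.
#' @param lf_contam_db Level of the low-frequency contaminant relative to the
#'   frication, in dB (`-Inf` for none).
#' @param rate_hz Sampling rate in Hz.
#' @param seed Seed; the waveform is a pure function of the arguments.
#' @return A [waveform()] of `round(duration_s * rate_hz)` samples, unit RMS.
#' @export
synth_fricative <- function(resonance_hz, duration_s = 0.15,
                            bandwidth_hz = 300, tilt_db_per_oct = 0,
                            secondary_resonance_hz = NA_real_,
                            secondary_gain_db = 0,
                            lf_contam_db = -Inf,
                            rate_hz = 44100, seed = 1L) {
  if (resonance_hz >= rate_hz / 2) {
    stop("synth_fricative: resonance must be below Nyquist", call. = FALSE)
  }
  if (duration_s <= 0.015) {
    stop("synth_fricative: duration must exceed 15 ms", call. = FALSE)
  }
  n <- round(duration_s * rate_hz)
  pad <- 2000L  # discard the resonator's startup transient

  resonate <- function(x, fc, bw) {
    r <- exp(-pi * bw / rate_hz)
    signal::filter(1, c(1, -2 * r * cos(2 * pi * fc / rate_hz), r^2), x)
  }

  with_local_seed(seed, {
    src <- stats::rnorm(n + pad)
    y <- as.numeric(resonate(src, resonance_hz, bandwidth_hz))
    if (is.finite(secondary_resonance_hz)) {
      y2 <- as.numeric(resonate(src, secondary_resonance_hz, bandwidth_hz))
      y <- y / stats::sd(y) +
        10^(secondary_gain_db / 20) * y2 / stats::sd(y2)
    }
    y <- y[-seq_len(pad)]

    if (tilt_db_per_oct != 0) {
      ## first-order spectral slope applied in the frequency domain,
      ## anchored at 1 kHz
      nf <- length(y)
      f <- (0:(nf - 1)) / nf * rate_hz
      f <- pmin(f, rate_hz - f)
      gain <- 10^(tilt_db_per_oct * log2(pmax(f, 20) / 1000) / 20)
      y <- Re(stats::fft(stats::fft(y) * gain, inverse = TRUE)) / nf
    }
    y <- y / sqrt(mean(y^2))

    if (is.finite(lf_contam_db)) {
      lf <- stats::rnorm(n)
      f <- (0:(n - 1)) / n * rate_hz
      f <- pmin(f, rate_hz - f)
      gain <- ifelse(f <= 200, 1,
              ifelse(f >= 300, 0,
                     0.5 + 0.5 * cos(pi * (f - 200) / 100)))
      lf <- Re(stats::fft(stats::fft(lf) * gain, inverse = TRUE)) / n
      lf <- lf / sqrt(mean(lf^2))
      y <- y + 10^(lf_contam_db / 20) * lf
    }
    waveform(y / sqrt(mean(y^2)), rate_hz)
  })
}

#' Configuration of the synthetic corpus generator
#'
#' Defaults emulate the study conditions the pipeline targets: /s/-coded
#' tokens draw their front-cavity resonance from a higher band than
#' /sh/-coded ones, with overlap representing intermediate productions;
#' per-token spectral tilt jitter degrades the centroid (which integrates the
#' whole spectrum) more than the band peak (a local argmax); a moderate
#' low-frequency contaminant exercises the 300 Hz filter.
#'
#' @param s_range,sh_range Uniform resonance ranges (Hz) for target /s/ and
#'   /sh/. The defaults overlap substantially (4800-6800 Hz), emulating the
#'   wide within-category spread and frequent intermediate productions of
#'   young children's sibilants.
#' @param dur_range Uniform token duration range (s).
#' @param bandwidth_hz Resonance bandwidth (Hz).
#' @param tilt_mean,tilt_sd Mean and SD (dB/octave) of the per-token spectral
#'   tilt.
#' @param lf_contam_db Low-frequency contaminant level (dB re frication RMS).
#' @param prop_s Proportion of /s/ targets.
#' @param rate_hz Sampling rate.
#' @return List of class `corpus_config`.
#' @export
corpus_config <- function(s_range = c(4800, 8600), sh_range = c(3400, 6800),
                          dur_range = c(0.08, 0.20), bandwidth_hz = 300,
                          tilt_mean = 0, tilt_sd = 3, lf_contam_db = -10,
                          prop_s = 0.5, rate_hz = 44100) {
  structure(list(s_range = s_range, sh_range = sh_range,
                 dur_range = dur_range, bandwidth_hz = bandwidth_hz,
                 tilt_mean = tilt_mean, tilt_sd = tilt_sd,
                 lf_contam_db = lf_contam_db, prop_s = prop_s,
                 rate_hz = rate_hz),
            class = "corpus_config")
}

## Narrow-transcription emulation: category follows the resonance relative
## to the /s/-/sh/ overlap region, mimicking the direction (not the counts)
## of perceptual categories in child sibilant data.
assign_transcription <- function(resonance_hz) {
  cut_levels <- c(-Inf, 4800, 5800, 6800, Inf)
  TRANSCRIPTION_LEVELS[c(2, 4, 3, 1)][findInterval(resonance_hz,
                                                   cut_levels)]
}

#' Generate a synthetic fricative corpus with known ground truth
#'
#' @param n_tokens Number of tokens.
#' @param config A [corpus_config()].
#' @param seed Root seed; the corpus is a pure function of `(n_tokens,
#'   config, seed)`.
#' @return List of class `synthetic_corpus`: `tokens` (list of
#'   `fricative_token`), `truth` (data frame of every generative parameter
#'   per token) and `config`.
#' @export
synth_corpus <- function(n_tokens, config = corpus_config(), seed = 1L) {
  if (n_tokens < 1) stop("synth_corpus: n_tokens must be >= 1", call. = FALSE)
  truth <- with_local_seed(derive_seed(seed, "corpus-design"), {
    target <- stats::rbinom(n_tokens, 1, config$prop_s)
    res <- ifelse(target == 1,
                  stats::runif(n_tokens, config$s_range[1], config$s_range[2]),
                  stats::runif(n_tokens, config$sh_range[1], config$sh_range[2]))
    data.frame(
      token_id = sprintf("tok%04d", seq_len(n_tokens)),
      child_id = sprintf("child%02d", 1 + (seq_len(n_tokens) - 1) %% 10),
      word = ifelse(target == 1, "sun", "sheep"),
      target = target,
      resonance_hz = res,
      bandwidth_hz = config$bandwidth_hz,
      tilt_db_per_oct = stats::rnorm(n_tokens, config$tilt_mean,
                                     config$tilt_sd),
      lf_contam_db = config$lf_contam_db,
      duration_s = stats::runif(n_tokens, config$dur_range[1],
                                config$dur_range[2]),
      seed = vapply(seq_len(n_tokens),
                    function(i) derive_seed(seed, paste0("tok", i)),
                    integer(1)),
      stringsAsFactors = FALSE
    )
  })
  truth$transcription <- assign_transcription(truth$resonance_hz)

  tokens <- lapply(seq_len(n_tokens), function(i) {
    w <- synth_fricative(truth$resonance_hz[i],
                         duration_s = truth$duration_s[i],
                         bandwidth_hz = truth$bandwidth_hz[i],
                         tilt_db_per_oct = truth$tilt_db_per_oct[i],
                         lf_contam_db = truth$lf_contam_db[i],
                         rate_hz = config$rate_hz,
                         seed = truth$seed[i])
    structure(list(token_id = truth$token_id[i],
                   child_id = truth$child_id[i],
                   word = truth$word[i],
                   target = truth$target[i],
                   transcription = truth$transcription[i],
                   onset_s = 0, offset_s = duration(w),
                   audio = w),
              class = "fricative_token")
  })
  structure(list(tokens = tokens, truth = truth, config = config,
                 seed = seed),
            class = "synthetic_corpus")
}

#' Write a synthetic corpus to disk in the reader's layout
#'
#' Produces `wav/<token_id>.wav` (token embedded between 50 ms silences),
#' `textgrid/<token_id>.TextGrid` (tier `"fricative"`, interval labeled with
#' the token id), `tokens.csv` and `truth.csv`, so [read_corpus()]
#' round-trips the corpus.
#'
#' @param corpus A [synth_corpus()] result.
#' @param dir Output directory (created if needed).
#' @param bits WAV sample format (see [write_wav()]).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir, bits = 32L) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  dir.create(file.path(dir, "wav"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "textgrid"), recursive = TRUE,
             showWarnings = FALSE)
  pad_s <- 0.05
  meta <- corpus$truth[, c("token_id", "child_id", "word", "target")]
  meta$transcription <- corpus$truth$transcription
  meta$onset_s <- pad_s
  meta$offset_s <- NA_real_
  for (i in seq_along(corpus$tokens)) {
    tok <- corpus$tokens[[i]]
    rate <- tok$audio$rate
    npad <- round(pad_s * rate)
    x <- c(numeric(npad), 0.1 * tok$audio$samples, numeric(npad))
    w <- waveform(x, rate)
    write_wav(w, file.path(dir, "wav", paste0(tok$token_id, ".wav")),
              bits = bits)
    off <- (npad + length(tok$audio$samples)) / rate
    meta$offset_s[i] <- off
    write_textgrid(
      data.frame(start = c(0, pad_s, off),
                 end = c(pad_s, off, duration(w)),
                 label = c("", tok$token_id, ""),
                 stringsAsFactors = FALSE),
      file.path(dir, "textgrid", paste0(tok$token_id, ".TextGrid")),
      tier = "fricative", xmax = duration(w))
  }
  utils::write.csv(meta, file.path(dir, "tokens.csv"), row.names = FALSE)
  utils::write.csv(corpus$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Truth parameters of the rating simulator
#'
#' Logit-scale coefficients of the generative beta mixed-effects model, the
#' beta precision, the listener random-effect SDs (intercept, target slope,
#' measure slope) with their correlation matrix, and the stimulus intercept
#' SD. The default direction follows the rating-scale convention (0 = /s/,
#' 1 = /sh/): a higher (more /s/-like) acoustic measure lowers the expected
#' rating, so `beta_measure` is negative.
#'
#' @param beta0,beta_target,beta_measure,beta_interaction Fixed effects.
#' @param phi Beta precision.
#' @param listener_sds Length-3 SD vector (intercept, target, measure).
#' @param listener_corr 3 x 3 correlation matrix.
#' @param stimulus_sd Stimulus intercept SD.
#' @param n_listeners Number of simulated listeners.
#' @return List of class `rating_truth`.
#' @export
rating_truth <- function(beta0 = 1.0, beta_target = -0.8,
                         beta_measure = -1.5, beta_interaction = 0,
                         phi = 10, listener_sds = c(0.3, 0.3, 0.3),
                         listener_corr = diag(3), stimulus_sd = 0.4,
                         n_listeners = 40L) {
  stopifnot(phi > 0, all(listener_sds >= 0), stimulus_sd >= 0)
  ev <- eigen(listener_corr, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8)) {
    stop("rating_truth: listener_corr is not positive semi-definite",
         call. = FALSE)
  }
  structure(list(beta0 = beta0, beta_target = beta_target,
                 beta_measure = beta_measure,
                 beta_interaction = beta_interaction, phi = phi,
                 listener_sds = listener_sds, listener_corr = listener_corr,
                 stimulus_sd = stimulus_sd,
                 n_listeners = as.integer(n_listeners)),
            class = "rating_truth")
}

#' Simulate listener VAS ratings from a driving acoustic variable
#'
#' Every listener rates every token. Listener effect vectors (intercept,
#' target slope, measure slope) are drawn from the configured multivariate
#' normal, stimulus intercepts from `N(0, stimulus_sd^2)`; the rating mean is
#' the inverse logit of the linear predictor and ratings are beta draws with
#' precision `phi`.
#'
#' @param tokens Data frame with `token_id`, `target`, and the driving
#'   variable column.
#' @param truth A [rating_truth()].
#' @param driving Name of the driving variable column (already scaled to
#'   \[0, 1\]).
#' @param seed Seed; the table is a pure function of its inputs.
#' @return Data frame `listener_id`, `token_id`, `value` with one row per
#'   listener x token.
#' @export
simulate_ratings <- function(tokens, truth, driving = "resonance_scaled",
                             seed = 1L) {
  if (!driving %in% names(tokens)) {
    stop(sprintf("simulate_ratings: no column '%s' in tokens", driving),
         call. = FALSE)
  }
  x <- tokens[[driving]]
  if (any(x < -1e-9 | x > 1 + 1e-9)) {
    stop("simulate_ratings: driving variable must be scaled to [0, 1]",
         call. = FALSE)
  }
  J <- truth$n_listeners
  K <- nrow(tokens)
  Sigma <- diag(truth$listener_sds) %*% truth$listener_corr %*%
    diag(truth$listener_sds)
  with_local_seed(derive_seed(seed, "ratings"), {
    L <- t(chol(Sigma + diag(1e-12, 3)))
    u <- t(L %*% matrix(stats::rnorm(3 * J), 3, J))   # J x 3
    b <- stats::rnorm(K, 0, truth$stimulus_sd)
    jj <- rep(seq_len(J), each = K)
    kk <- rep(seq_len(K), times = J)
    eta <- (truth$beta0 + u[jj, 1]) +
      (truth$beta_target + u[jj, 2]) * tokens$target[kk] +
      (truth$beta_measure + u[jj, 3]) * x[kk] +
      truth$beta_interaction * tokens$target[kk] * x[kk] +
      b[kk]
    mu <- stats::plogis(eta)
    eps <- 1e-9
    if (any(mu < eps | mu > 1 - eps)) {
      warning("simulate_ratings: extreme means clamped away from 0/1",
              call. = FALSE)
      mu <- pmin(1 - eps, pmax(eps, mu))
    }
    y <- stats::rbeta(length(mu), mu * truth$phi, (1 - mu) * truth$phi)
    y <- pmin(1 - 1e-12, pmax(1e-12, y))
    data.frame(listener_id = sprintf("L%03d", jj),
               token_id = tokens$token_id[kk],
               value = y,
               stringsAsFactors = FALSE)
  })
}
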