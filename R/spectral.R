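#' Default spectral analysis configuration
#'
#' Collects every tunable of the measurement procedure with its default:
#' six 15 ms windows over the central 80% of the token, Hamming taper,
#' 4096-point transform (about 10.8 Hz bins at 44.1 kHz), high-band filter at
#' 300 Hz with a 100 Hz raised-cosine edge, M1 weighted by power
#' (amplitude squared), and the three mid-frequency peak bands. No
#' pre-emphasis is applied anywhere in the procedure.
#'
#' @param n_windows Number of analysis windows.
#' @param win_ms Window length in milliseconds.
#' @param central_frac Fraction of the token, centred on its midpoint, that
#'   the windows cover.
#' @param n_fft Transform length (zero-padded).
#' @param taper Window taper: `"hamming"`, `"hann"`, `"blackman"` or
#'   `"boxcar"`.
#' @param filter_cutoff_hz High-band filter cutoff in Hz (`NA` disables the
#'   filter).
#' @param filter_smoothing_hz Width of the raised-cosine filter edge in Hz.
#' @param m1_lo_hz,m1_hi_hz Integration band for the centroid (`NA` upper
#'   bound means Nyquist).
#' @param m1_power_exponent Exponent applied to linear amplitude when
#'   weighting the centroid: 2 (power, default) or 1 (amplitude).
#' @param fm_bands Named list of `c(lo, hi)` bands (Hz) for the mid-frequency
#'   peak.
#' @return A list of class `spectral_config`.
#' @export
spectral_config <- function(n_windows = 6L,
                            win_ms = 15,
                            central_frac = 0.8,
                            n_fft = 4096L,
                            taper = "hamming",
                            filter_cutoff_hz = 300,
                            filter_smoothing_hz = 100,
                            m1_lo_hz = 300,
                            m1_hi_hz = NA_real_,
                            m1_power_exponent = 2,
                            fm_bands = list(fm_3_7 = c(3000, 7000),
                                            fm_3_8 = c(3000, 8000),
                                            fm_3_9 = c(3000, 9000))) {
  structure(list(n_windows = as.integer(n_windows), win_ms = win_ms,
                 central_frac = central_frac, n_fft = as.integer(n_fft),
                 taper = taper, filter_cutoff_hz = filter_cutoff_hz,
                 filter_smoothing_hz = filter_smoothing_hz,
                 m1_lo_hz = m1_lo_hz, m1_hi_hz = m1_hi_hz,
                 m1_power_exponent = m1_power_exponent,
                 fm_bands = fm_bands),
            class = "spectral_config")
}

taper_fn <- function(name, n) {
  x <- 2 * pi * (0:(n - 1)) / (n - 1)
  switch(name,
    hamming  = 0.54 - 0.46 * cos(x),
    hann     = 0.5 - 0.5 * cos(x),
    blackman = 0.42 - 0.5 * cos(x) + 0.08 * cos(2 * x),
    boxcar   = rep(1, n),
    stop(sprintf("unknown taper '%s'", name), call. = FALSE)
  )
}

#' Zero-phase high-band filter
#'
#' Removes voicing and low-frequency ambient noise below `cutoff_hz` before
#' spectral measurement. Implemented in the frequency domain as a pass band
#' from the cutoff to Nyquist with a raised-cosine (Hann) edge of width
#' `smoothing_hz` centred on the cutoff; the filter is zero-phase and
#' length-preserving.
#'
#' @param w A [waveform()].
#' @param cutoff_hz Cutoff in Hz (must be below Nyquist).
#' @param smoothing_hz Transition-band width in Hz.
#' @return A filtered [waveform()] of the same length.
#' @export
highband_filter <- function(w, cutoff_hz = 300, smoothing_hz = 100) {
  stopifnot(inherits(w, "waveform"))
  nyq <- w$rate / 2
  if (cutoff_hz >= nyq) {
    stop("highband_filter: cutoff must be below Nyquist", call. = FALSE)
  }
  n <- length(w$samples)
  if (n < 2 * w$rate / max(smoothing_hz, 1)) {
    warning("highband_filter: token shorter than twice the smoothing period; edge resolution is limited",
            call. = FALSE)
  }
  f <- (0:(n - 1)) / n * w$rate
  f <- pmin(f, w$rate - f)              # folded (two-sided) frequency axis
  lo <- cutoff_hz - smoothing_hz / 2
  hi <- cutoff_hz + smoothing_hz / 2
  gain <- ifelse(f <= lo, 0,
          ifelse(f >= hi, 1,
                 0.5 - 0.5 * cos(pi * (f - lo) / (hi - lo))))
  y <- Re(stats::fft(stats::fft(w$samples) * gain, inverse = TRUE)) / n
  waveform(y, w$rate)
}

#' Plan the analysis windows for one token
#'
#' The analysis region is the central `central_frac` of the token (centred on
#' its temporal midpoint). The first window starts at the region onset and the
#' last window ends at the region offset, with equal spacing between
#' successive onsets; the overlap fraction is `max(0, (win - step) / win)`.
#' Tokens whose overlap exceeds 50% are *flagged* downstream, not removed.
#'
#' @param duration_s Token duration in seconds.
#' @param n_windows Number of windows.
#' @param win_ms Window length in ms.
#' @param central_frac Analysed fraction of the token.
#' @return A list of class `window_plan`: `n_windows`, `win_s`,
#'   `region_start_s`, `region_end_s`, `onsets_s`, `centers_s`, `step_s`,
#'   `overlap_frac`.
#' @examples
#' plan_windows(0.090)$overlap_frac   # 0.24
#' plan_windows(0.060)$overlap_frac   # 0.56 -> flagged downstream
#' @export
plan_windows <- function(duration_s, n_windows = 6L, win_ms = 15,
                         central_frac = 0.8) {
  win_s <- win_ms / 1000
  region_len <- central_frac * duration_s
  if (!is.finite(duration_s) || region_len < win_s) {
    stop(sprintf("plan_windows: analysis region (%.1f ms) shorter than one %g ms window; token unmeasurable",
                 1000 * region_len, win_ms), call. = FALSE)
  }
  region_start <- (duration_s - region_len) / 2
  region_end <- region_start + region_len
  if (n_windows > 1L) {
    step <- (region_len - win_s) / (n_windows - 1)
    onsets <- region_start + (0:(n_windows - 1)) * step
  } else {
    step <- region_len
    onsets <- region_start + (region_len - win_s) / 2
  }
  overlap <- max(0, (win_s - step) / win_s)
  structure(list(n_windows = as.integer(n_windows), win_s = win_s,
                 region_start_s = region_start, region_end_s = region_end,
                 onsets_s = onsets, centers_s = onsets + win_s / 2,
                 step_s = step, overlap_frac = overlap),
            class = "window_plan")
}

#' @export
print.window_plan <- function(x, ...) {
  cat(sprintf("<window_plan: %d x %.0f ms over [%.1f, %.1f] ms, step %.1f ms, overlap %.0f%%>\n",
              x$n_windows, 1000 * x$win_s, 1000 * x$region_start_s,
              1000 * x$region_end_s, 1000 * x$step_s, 100 * x$overlap_frac))
  invisible(x)
}

#' Time-averaged power spectrum of a token
#'
#' Each planned window is tapered, zero-padded to `n_fft` and transformed;
#' the estimate is the arithmetic mean of the windows' squared-magnitude
#' spectra on the linear power scale. Averaging several windows reduces the
#' variance of the noise-spectrum estimate. No pre-emphasis is applied.
#'
#' @param w A [waveform()].
#' @param plan A [plan_windows()] result for this token.
#' @param n_fft Transform length (zero-padded; must be at least the window
#'   length in samples).
#' @param taper Taper name (see [spectral_config()]).
#' @return A list of class `spectrum_estimate`: `freqs_hz` (0 to Nyquist),
#'   `power` (mean linear power per bin), `n_fft`, `window_fn`.
#' @export
time_averaged_spectrum <- function(w, plan, n_fft = 4096L, taper = "hamming") {
  stopifnot(inherits(w, "waveform"), inherits(plan, "window_plan"))
  wl <- round(plan$win_s * w$rate)
  if (wl > n_fft) {
    stop("time_averaged_spectrum: window longer than n_fft", call. = FALSE)
  }
  tp <- taper_fn(taper, wl)
  n <- length(w$samples)
  half <- n_fft %/% 2L + 1L
  acc <- numeric(half)
  for (j in seq_len(plan$n_windows)) {
    i0 <- round(plan$onsets_s[j] * w$rate) + 1L
    i1 <- i0 + wl - 1L
    if (i0 < 1L || i1 > n) {
      stop(sprintf("time_averaged_spectrum: window %d [%d, %d] extends past the audio (%d samples)",
                   j, i0, i1, n), call. = FALSE)
    }
    seg <- w$samples[i0:i1] * tp
    spec <- stats::fft(c(seg, numeric(n_fft - wl)))[seq_len(half)]
    acc <- acc + Re(spec)^2 + Im(spec)^2
  }
  structure(list(freqs_hz = (0:(half - 1L)) * w$rate / n_fft,
                 power = acc / plan$n_windows,
                 n_fft = as.integer(n_fft),
                 window_fn = taper),
            class = "spectrum_estimate")
}

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat(sprintf("<spectrum_estimate: %d bins, 0-%.0f Hz, %s taper, n_fft %d>\n",
              length(x$freqs_hz), max(x$freqs_hz), x$window_fn, x$n_fft))
  invisible(x)
}

#' Spectral centroid (first spectral moment, M1)
#'
#' The weighted mean frequency of the spectrum over `[lo_hz, hi_hz]`:
#' \deqn{M1 = \sum_k f_k p_k / \sum_k p_k}
#' with weights \eqn{p_k = a_k^{e}} where \eqn{a_k} is linear amplitude and
#' `e = power_exponent` (2 for power weighting, the default; 1 for amplitude
#' weighting).
#'
#' @param spec A `spectrum_estimate`.
#' @param lo_hz,hi_hz Integration band (inclusive); `hi_hz = NA` means
#'   Nyquist.
#' @param power_exponent Amplitude exponent (2 = power, 1 = amplitude).
#' @return Centroid frequency in Hz.
#' @export
spectral_moment_m1 <- function(spec, lo_hz = 300, hi_hz = NA_real_,
                               power_exponent = 2) {
  stopifnot(inherits(spec, "spectrum_estimate"))
  if (is.na(hi_hz)) hi_hz <- max(spec$freqs_hz)
  sel <- spec$freqs_hz >= lo_hz & spec$freqs_hz <= hi_hz
  p <- spec$power[sel]^(power_exponent / 2)   # stored power = amplitude^2
  if (!any(p > 0)) {
    stop("spectral_moment_m1: no positive power in the integration band",
         call. = FALSE)
  }
  sum(spec$freqs_hz[sel] * p) / sum(p)
}

#' Band-limited spectral peak (FM)
#'
#' The frequency of the maximum-power bin within `[lo_hz, hi_hz]` (inclusive
#' bounds). Interpreted as the front-cavity resonance of the fricative: a
#' shorter cavity (fronter constriction, /s/-like) gives a higher peak.
#' Ties are broken toward the lowest frequency, so the result is
#' deterministic.
#'
#' @param spec A `spectrum_estimate`.
#' @param lo_hz,hi_hz Search band in Hz.
#' @return Peak frequency in Hz.
#' @export
band_peak_fm <- function(spec, lo_hz = 3000, hi_hz) {
  stopifnot(inherits(spec, "spectrum_estimate"))
  if (!(lo_hz < hi_hz) || hi_hz > max(spec$freqs_hz) + 1e-9) {
    stop("band_peak_fm: need lo < hi <= Nyquist", call. = FALSE)
  }
  sel <- which(spec$freqs_hz >= lo_hz & spec$freqs_hz <= hi_hz)
  if (length(sel) < 2L) {
    stop("band_peak_fm: band contains fewer than 2 bins", call. = FALSE)
  }
  spec$freqs_hz[sel[which.max(spec$power[sel])]]
}

#' Measure one fricative token
#'
#' Runs the full measurement chain: high-band filter, window planning,
#' time-averaged spectrum, centroid and the three mid-frequency peaks. The
#' jump flag marks tokens whose peak sits below 7 kHz in the 3-8 kHz band but
#' above 8 kHz in the 3-9 kHz band -- a substantial jump suggesting the wider
#' band caught a resonance above the front-cavity one.
#'
#' @param tok A `fricative_token` (or a bare [waveform()], in which case ids
#'   are filled with `NA`).
#' @param config A [spectral_config()].
#' @return One-row data frame: `token_id`, `duration_s`, `overlap_frac`,
#'   `m1_hz`, `fm_3_7_hz`, `fm_3_8_hz`, `fm_3_9_hz`, `fm_jump_flag`.
#' @export
measure_token <- function(tok, config = spectral_config()) {
  if (inherits(tok, "waveform")) {
    tok <- list(token_id = NA_character_, audio = tok, target = NA_real_,
                transcription = NA_character_)
  }
  w <- tok$audio
  dur <- duration(w)
  if (!is.na(config$filter_cutoff_hz)) {
    w <- highband_filter(w, config$filter_cutoff_hz, config$filter_smoothing_hz)
  }
  plan <- plan_windows(dur, config$n_windows, config$win_ms,
                       config$central_frac)
  spec <- time_averaged_spectrum(w, plan, config$n_fft, config$taper)
  fm <- vapply(config$fm_bands,
               function(b) band_peak_fm(spec, b[1], b[2]), numeric(1))
  out <- data.frame(
    token_id = tok$token_id,
    duration_s = dur,
    overlap_frac = plan$overlap_frac,
    m1_hz = spectral_moment_m1(spec, config$m1_lo_hz, config$m1_hi_hz,
                               config$m1_power_exponent),
    stringsAsFactors = FALSE
  )
  for (nm in names(fm)) out[[paste0(nm, "_hz")]] <- fm[[nm]]
  out$fm_jump_flag <- out$fm_3_8_hz < 7000 & out$fm_3_9_hz > 8000
  out
}

#' Measure a list of tokens
#'
#' @param tokens List of `fricative_token` objects (e.g. from
#'   [read_corpus()]).
#' @param config A [spectral_config()].
#' @param keep_meta Carry `target` and `transcription` columns through.
#' @return Data frame with one row per token (see [measure_token()]).
#' @export
measure_tokens <- function(tokens, config = spectral_config(),
                           keep_meta = TRUE) {
  rows <- lapply(tokens, measure_token, config = config)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_meta && length(tokens) &&
      !is.null(tokens[[1]]$target)) {
    out$target <- vapply(tokens, function(t) t$target, numeric(1))
    out$transcription <- vapply(tokens, function(t) t$transcription,
                                character(1))
  }
  out
}
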