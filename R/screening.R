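MEASURE_COLS <- c("m1_hz", "fm_3_7_hz", "fm_3_8_hz", "fm_3_9_hz")

#' Exclude tokens shorter than a minimum duration
#'
#' Tokens at the boundary are retained (`duration_s >= min_s` keeps).
#'
#' @param measures Data frame with a `duration_s` column.
#' @param min_s Minimum duration in seconds (default 60 ms).
#' @return List with data frames `kept` and `excluded`.
#' @export
exclude_short <- function(measures, min_s = 0.060) {
  keep <- measures$duration_s >= min_s
  list(kept = measures[keep, , drop = FALSE],
       excluded = measures[!keep, , drop = FALSE])
}

#' Exclude per-target outliers on any acoustic measure
#'
#' For each acoustic measure and each target group separately, the mean and
#' SD are computed once on the input set (single pass, no re-estimation after
#' removals). A token is excluded if *any* of its measures falls strictly
#' outside mean +/- `k_sd` * SD for its own target group, so one common
#' analysis set serves all downstream models. A degenerate group (SD = 0)
#' excludes nothing and logs a warning.
#'
#' @param measures Data frame with the four measure columns and `target`.
#' @param k_sd SD multiplier (default 2).
#' @param measure_cols Columns screened (default the four acoustic measures).
#' @return List with `kept`, `excluded`, and `stats` (the frozen per-group
#'   means/SDs, usable to re-apply the same rule).
#' @export
exclude_outliers <- function(measures, k_sd = 2, measure_cols = MEASURE_COLS) {
  measure_cols <- intersect(measure_cols, names(measures))
  if (!length(measure_cols)) {
    stop("exclude_outliers: no measure columns present", call. = FALSE)
  }
  if (!"target" %in% names(measures)) {
    stop("exclude_outliers: 'target' column required", call. = FALSE)
  }
  stats_list <- list()
  out <- rep(FALSE, nrow(measures))
  for (g in unique(measures$target)) {
    sel <- measures$target == g
    if (sum(sel) < 2L) {
      warning(sprintf("exclude_outliers: target group %s has < 2 tokens; skipped", g),
              call. = FALSE)
      next
    }
    for (mc in measure_cols) {
      x <- measures[[mc]][sel]
      mu <- mean(x); sdev <- stats::sd(x)
      stats_list[[length(stats_list) + 1L]] <-
        data.frame(target = g, measure = mc, mean = mu, sd = sdev,
                   stringsAsFactors = FALSE)
      if (!is.finite(sdev) || sdev == 0) {
        warning(sprintf("exclude_outliers: SD = 0 for %s in target group %s; no exclusions there",
                        mc, g), call. = FALSE)
        next
      }
      out[sel] <- out[sel] | abs(x - mu) > k_sd * sdev
    }
  }
  list(kept = measures[!out, , drop = FALSE],
       excluded = measures[out, , drop = FALSE],
       stats = do.call(rbind, stats_list))
}

## Re-apply a frozen outlier rule (used by the idempotence property).
apply_outlier_stats <- function(measures, stats, k_sd = 2) {
  out <- rep(FALSE, nrow(measures))
  for (r in seq_len(nrow(stats))) {
    if (!is.finite(stats$sd[r]) || stats$sd[r] == 0) next
    sel <- measures$target == stats$target[r]
    x <- measures[[stats$measure[r]]][sel]
    out[sel] <- out[sel] | abs(x - stats$mean[r]) > k_sd * stats$sd[r]
  }
  out
}

#' Flag tokens whose analysis windows overlap too much
#'
#' Flagged tokens are retained but reported: heavy window overlap means the
#' six analysis windows are not independent samples of the frication noise.
#' The boundary is strict (`overlap_frac > max_frac` flags).
#'
#' @param measures Data frame with an `overlap_frac` column.
#' @param max_frac Maximum admissible overlap (default 0.5).
#' @return Logical vector, one flag per row.
#' @export
flag_overlap <- function(measures, max_frac = 0.5) {
  measures$overlap_frac > max_frac
}

#' Screen a measured token set
#'
#' Applies the exclusion rules in order: minimum duration first, then
#' single-pass per-target outlier removal on the duration-passing set, then
#' overlap flagging of the retained tokens. Dispositions are mutually
#' exclusive and exhaustive, and the counts reconcile exactly.
#'
#' @param measures Data frame from [measure_tokens()] (requires `target`).
#' @param min_s Minimum duration (s).
#' @param k_sd Outlier SD multiplier.
#' @param max_overlap Overlap flag threshold.
#' @return List of class `screening_report`: `kept` (with `overlap_flag`
#'   column), `disposition` (token_id -> one of `"retained"`,
#'   `"short_excluded"`, `"outlier_excluded"`), counts `n_input`,
#'   `n_short_excluded`, `n_outlier_excluded`, `n_overlap_flagged`,
#'   `n_retained`, and the frozen `outlier_stats`.
#' @export
screen_tokens <- function(measures, min_s = 0.060, k_sd = 2,
                          max_overlap = 0.5) {
  sh <- exclude_short(measures, min_s)
  ol <- exclude_outliers(sh$kept, k_sd)
  kept <- ol$kept
  kept$overlap_flag <- flag_overlap(kept, max_overlap)
  disposition <- data.frame(
    token_id = c(sh$excluded$token_id, ol$excluded$token_id, kept$token_id),
    disposition = c(rep("short_excluded", nrow(sh$excluded)),
                    rep("outlier_excluded", nrow(ol$excluded)),
                    rep("retained", nrow(kept))),
    stringsAsFactors = FALSE
  )
  structure(list(
    kept = kept,
    disposition = disposition,
    n_input = nrow(measures),
    n_short_excluded = nrow(sh$excluded),
    n_outlier_excluded = nrow(ol$excluded),
    n_overlap_flagged = sum(kept$overlap_flag),
    n_retained = nrow(kept),
    outlier_stats = ol$stats,
    min_s = min_s, k_sd = k_sd, max_overlap = max_overlap
  ), class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf(paste0(
    "Token screening: %d in\n",
    "  short (< %g ms):      %d excluded\n",
    "  outlier (+/- %g SD):  %d excluded\n",
    "  overlap (> %g%%):     %d flagged (retained)\n",
    "  retained:             %d\n"),
    x$n_input, 1000 * x$min_s, x$n_short_excluded, x$k_sd,
    x$n_outlier_excluded, 100 * x$max_overlap, x$n_overlap_flagged,
    x$n_retained))
  invisible(x)
}

#' Min-max scale a measure onto \[0, 1\]
#'
#' Affine map of the retained token set onto \[0, 1\] (min to 0, max to 1).
#' The range used is stored so new data can be projected consistently and so
#' scaling can be inverted exactly.
#'
#' @param x Numeric vector (at least two distinct values).
#' @return Object of class `measure_scaling`: list with `scaled`, `min`,
#'   `max`.
#' @export
minmax_scale <- function(x) {
  rng <- range(x)
  if (!all(is.finite(rng)) || diff(rng) == 0) {
    stop("minmax_scale: need at least two distinct finite values",
         call. = FALSE)
  }
  structure(list(scaled = (x - rng[1]) / diff(rng),
                 min = rng[1], max = rng[2]),
            class = "measure_scaling")
}

#' Project new values with a stored scaling
#' @param scaling A `measure_scaling`.
#' @param x New raw values.
#' @return Scaled values (not clamped).
#' @export
project_scaling <- function(scaling, x) {
  (x - scaling$min) / (scaling$max - scaling$min)
}

#' Invert a stored scaling
#' @param scaling A `measure_scaling`.
#' @param s Scaled values.
#' @return Raw values.
#' @export
invert_scaling <- function(scaling, s) {
  s * (scaling$max - scaling$min) + scaling$min
}

#' Scale all acoustic measures of a screened set onto \[0, 1\]
#'
#' @param kept Data frame of retained tokens.
#' @param measure_cols Measure columns to scale.
#' @return List: `data` (with added `<measure>_scaled` columns, named
#'   `m1`, `fm_3_7`, ... i.e. the `_hz` suffix dropped) and `scalings` (named
#'   list of `measure_scaling` objects).
#' @export
scale_measures <- function(kept, measure_cols = MEASURE_COLS) {
  scalings <- list()
  for (mc in intersect(measure_cols, names(kept))) {
    sc <- minmax_scale(kept[[mc]])
    nm <- sub("_hz$", "", mc)
    kept[[nm]] <- sc$scaled
    scalings[[nm]] <- sc
  }
  list(data = kept, scalings = scalings)
}
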