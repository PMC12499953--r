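MEASURE_ORDER <- c("m1", "fm_3_7", "fm_3_8", "fm_3_9")

#' Compare acoustic measures as predictors of listener ratings
#'
#' The headline analysis: fit the baseline model (ratings predicted by
#' target), then for each acoustic measure a main-effects model and an
#' interaction model; the interaction is kept only when its likelihood-ratio
#' test against the main-effects model is significant at `alpha`. Models are
#' ranked by the AIC of the kept fit; ties break by the fixed measure order
#' m1, fm_3_7, fm_3_8, fm_3_9.
#'
#' @param data Analysis table: one row per rating with `value_open`,
#'   `target`, `listener_id`, `token_id` and the scaled measure columns.
#' @param measures Measures to compare (subset of `MEASURE_ORDER`).
#' @param alpha Significance level for the interaction decision.
#' @param control,seed Passed to [beta_glmm()].
#' @return Object of class `comparison_report`: `models` data frame
#'   (measure, kept spec, loglik, n_params, aic, interaction LRT, LRT vs
#'   baseline, delta AIC vs winner, converged), `winner`, `baseline` fit and
#'   all `fits`.
#' @export
run_comparison <- function(data, measures = MEASURE_ORDER, alpha = 0.05,
                           control = glmm_control(), seed = 1L) {
  measures <- intersect(MEASURE_ORDER, measures)
  missing <- setdiff(measures, names(data))
  if (length(missing)) {
    stop(sprintf("run_comparison: scaled measure column(s) missing: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  baseline <- beta_glmm(model_spec("none"), data, control = control,
                        seed = seed)
  fits <- list(baseline = baseline)
  rows <- list()
  for (ms in measures) {
    main <- beta_glmm(model_spec(ms), data, control = control, seed = seed)
    intr <- beta_glmm(model_spec(ms, interaction = TRUE), data,
                      control = control, seed = seed)
    lrt_int <- lr_test(intr, main)
    keep_interaction <- is.finite(lrt_int$p_value) &&
      lrt_int$p_value < alpha && intr$converged
    kept <- if (keep_interaction) intr else main
    lrt_base <- lr_test(kept, baseline)
    fits[[ms]] <- list(main = main, interaction = intr, kept = kept)
    rows[[ms]] <- data.frame(
      measure = ms,
      kept_spec = if (keep_interaction) "interaction" else "main",
      loglik = kept$loglik,
      n_params = kept$n_params,
      aic = kept$aic,
      lrt_interaction_chisq = lrt_int$chisq,
      lrt_interaction_df = lrt_int$df,
      lrt_interaction_p = lrt_int$p_value,
      lrt_baseline_chisq = lrt_base$chisq,
      lrt_baseline_df = lrt_base$df,
      lrt_baseline_p = lrt_base$p_value,
      converged = kept$converged,
      stringsAsFactors = FALSE
    )
  }
  models <- do.call(rbind, rows)
  rownames(models) <- NULL
  usable <- models[models$converged, , drop = FALSE]
  if (nrow(usable) < nrow(models)) {
    warning(sprintf("run_comparison: %d non-converged model(s) excluded from the ranking: %s",
                    nrow(models) - nrow(usable),
                    paste(models$measure[!models$converged], collapse = ", ")),
            call. = FALSE)
  }
  ord <- order(usable$aic, match(usable$measure, MEASURE_ORDER))
  ranking <- usable$measure[ord]
  winner <- if (length(ranking)) ranking[1] else NA_character_
  models$delta_aic <- models$aic -
    if (length(ranking)) usable$aic[ord][1] else NA_real_
  models <- models[order(match(models$measure, ranking),
                         match(models$measure, MEASURE_ORDER)), ]
  rownames(models) <- NULL
  structure(list(models = models, ranking = ranking, winner = winner,
                 baseline_aic = baseline$aic,
                 baseline_loglik = baseline$loglik,
                 alpha = alpha, fits = fits),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Model comparison (beta mixed-effects, AIC ascending)\n")
  cat(sprintf("  baseline (target only): AIC %.1f\n", x$baseline_aic))
  for (r in seq_len(nrow(x$models))) {
    m <- x$models[r, ]
    cat(sprintf("  %-8s %-12s AIC %10.1f  dAIC %8.1f  vs baseline chisq[%d] = %.1f (p = %.3g)%s\n",
                m$measure, paste0("(", m$kept_spec, ")"), m$aic, m$delta_aic,
                m$lrt_baseline_df, m$lrt_baseline_chisq, m$lrt_baseline_p,
                if (m$converged) "" else "  [not converged]"))
  }
  cat(sprintf("  winner: %s\n", x$winner))
  invisible(x)
}

#' Scatter of token-mean ratings against each scaled measure
#'
#' Convenience figure: per-token mean rating (logit axis) against the scaled
#' measure, one panel per measure, separate points and least-squares lines
#' per target.
#'
#' @param data Analysis table (as passed to [run_comparison()]).
#' @param measures Measures to plot.
#' @return Invisibly, the per-token summary data frame.
#' @export
plot_measure_ratings <- function(data, measures = MEASURE_ORDER) {
  measures <- intersect(measures, names(data))
  agg <- stats::aggregate(value_open ~ token_id + target, data, mean)
  agg <- merge(agg, unique(data[, c("token_id", measures)]), by = "token_id")
  old <- graphics::par(mfrow = c(2, ceiling(length(measures) / 2)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (ms in measures) {
    graphics::plot(agg[[ms]], stats::qlogis(agg$value_open),
                   col = ifelse(agg$target == 1, "steelblue", "tomato"),
                   pch = 19, cex = 0.7, xlab = paste(ms, "(scaled)"),
                   ylab = "mean rating (logit)", main = ms)
    for (tg in unique(agg$target)) {
      sel <- agg$target == tg
      graphics::abline(stats::lm(stats::qlogis(agg$value_open[sel]) ~
                                   agg[[ms]][sel]),
                       col = ifelse(tg == 1, "steelblue", "tomato"))
    }
  }
  invisible(agg)
}

#' Summarize substantial-jump flags across tokens
#'
#' Counts tokens whose mid-frequency peak jumps from below 7 kHz (3-8 kHz
#' band) to above 8 kHz (3-9 kHz band), overall and by transcription
#' category. Such jumps suggest the widest band caught a resonance above the
#' front-cavity one.
#'
#' @param measures Data frame with `fm_jump_flag` (and optionally
#'   `transcription`).
#' @return List of class `jump_report`: `n`, `n_flagged`, `fraction`,
#'   `by_transcription` (table, possibly empty).
#' @export
jump_report <- function(measures) {
  if (!"fm_jump_flag" %in% names(measures)) {
    stop("jump_report: 'fm_jump_flag' column required", call. = FALSE)
  }
  n <- nrow(measures)
  flagged <- measures$fm_jump_flag
  by_tr <- if ("transcription" %in% names(measures) && any(flagged)) {
    table(measures$transcription[flagged])
  } else {
    table(character(0))
  }
  structure(list(n = n, n_flagged = sum(flagged),
                 fraction = if (n > 0) sum(flagged) / n else NA_real_,
                 by_transcription = by_tr),
            class = "jump_report")
}

#' @export
print.jump_report <- function(x, ...) {
  cat(sprintf("Substantial FM jumps: %d / %d tokens (%.1f%%)\n",
              x$n_flagged, x$n, 100 * x$fraction))
  if (length(x$by_transcription)) {
    for (nm in names(x$by_transcription)) {
      cat(sprintf("  %-10s %d\n", nm, x$by_transcription[[nm]]))
    }
  }
  invisible(x)
}
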