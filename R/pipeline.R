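## Orchestration layer: directory-level commands tying the modules together.
## These functions are what the thin command-line wrapper in
## inst/scripts/sibspect-pipeline.R dispatches to.

#' Default pipeline run configuration
#'
#' Every default equals the corresponding module-level default; the resolved
#' configuration is serialized next to the outputs of each command so a run
#' can be reproduced bit-for-bit from its snapshot.
#'
#' @param seed Root seed.
#' @param n_tokens Tokens to simulate.
#' @param n_listeners Listeners to simulate.
#' @param min_s,k_sd,max_overlap Screening parameters.
#' @param alpha Interaction-decision significance level.
#' @param spectral A [spectral_config()].
#' @param corpus A [corpus_config()].
#' @param truth A [rating_truth()].
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_tokens = 200L, n_listeners = 20L,
                       min_s = 0.060, k_sd = 2, max_overlap = 0.5,
                       alpha = 0.05,
                       spectral = spectral_config(),
                       corpus = corpus_config(),
                       truth = rating_truth(n_listeners = n_listeners)) {
  structure(list(seed = as.integer(seed), n_tokens = as.integer(n_tokens),
                 n_listeners = as.integer(n_listeners), min_s = min_s,
                 k_sd = k_sd, max_overlap = max_overlap, alpha = alpha,
                 spectral = spectral, corpus = corpus, truth = truth),
            class = "run_config")
}

#' Load a run configuration from a YAML snapshot
#'
#' Re-reads a `config.yaml` written next to a previous run's outputs, so a
#' run can be reproduced from its snapshot.
#'
#' @param path Path to the YAML snapshot.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config(seed = raw$seed, n_tokens = raw$n_tokens,
                    n_listeners = raw$n_listeners, min_s = raw$min_s,
                    k_sd = raw$k_sd, max_overlap = raw$max_overlap,
                    alpha = raw$alpha)
  for (nm in names(raw$spectral)) {
    if (nm == "fm_bands") {
      cfg$spectral$fm_bands <- lapply(raw$spectral$fm_bands, unlist)
    } else {
      cfg$spectral[[nm]] <- raw$spectral[[nm]]
    }
  }
  for (nm in setdiff(names(raw$corpus), "")) {
    cfg$corpus[[nm]] <- unlist(raw$corpus[[nm]])
  }
  for (nm in names(raw$truth)) {
    v <- raw$truth[[nm]]
    cfg$truth[[nm]] <- if (nm == "listener_corr") {
      do.call(rbind, lapply(v, unlist))
    } else {
      unlist(v)
    }
  }
  cfg
}

write_config_snapshot <- function(config, path) {
  plain <- rapply(unclass(config), function(x) {
    if (is.matrix(x)) apply(x, 1, as.numeric, simplify = FALSE) else x
  }, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Simulate a corpus plus ratings to disk
#'
#' Writes the full corpus layout (`wav/`, `textgrid/`, `tokens.csv`,
#' `truth.csv`), simulated `ratings.csv` driven by the true resonance
#' (scaled to \[0, 1\] over the corpus), and a `config.yaml` snapshot.
#'
#' @param out_dir Output directory.
#' @param config A [run_config()].
#' @param force Overwrite a non-empty directory.
#' @return `out_dir`, invisibly.
#' @export
run_simulate <- function(out_dir, config = run_config(), force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force) {
    stop(sprintf("run_simulate: '%s' is not empty (use force = TRUE)",
                 out_dir), call. = FALSE)
  }
  corpus <- synth_corpus(config$n_tokens, config$corpus, seed = config$seed)
  write_corpus(corpus, out_dir)
  tok <- corpus$truth
  tok$resonance_scaled <- minmax_scale(tok$resonance_hz)$scaled
  ratings <- simulate_ratings(tok, config$truth,
                              driving = "resonance_scaled",
                              seed = config$seed)
  utils::write.csv(ratings, file.path(out_dir, "ratings.csv"),
                   row.names = FALSE)
  write_config_snapshot(config, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Measure every token of a corpus directory
#'
#' @param corpus_dir Corpus directory (layout of [write_corpus()]).
#' @param config A [run_config()]; its `spectral` element drives the
#'   measurement.
#' @param out_csv Optional path for the measures CSV.
#' @return Measures data frame (one row per token). Per-token failures are
#'   reported as warnings and skipped; if more than 10% of tokens fail the
#'   command errors.
#' @export
run_measure <- function(corpus_dir, config = run_config(), out_csv = NULL) {
  meta <- read_token_metadata(file.path(corpus_dir, "tokens.csv"))
  files <- if ("file" %in% names(meta)) meta$file else meta$token_id
  rows <- list()
  failures <- character(0)
  for (r in seq_len(nrow(meta))) {
    row <- tryCatch({
      audio <- read_wav(file.path(corpus_dir, "wav",
                                  paste0(files[r], ".wav")))
      ann <- read_textgrid(file.path(corpus_dir, "textgrid",
                                     paste0(files[r], ".TextGrid")),
                           tier = "fricative")
      tok <- extract_tokens(audio, ann, meta[r, , drop = FALSE])[[1]]
      cbind(measure_token(tok, config$spectral), target = tok$target,
            transcription = tok$transcription, stringsAsFactors = FALSE)
    }, error = function(e) {
      warning(sprintf("run_measure: token '%s' skipped: %s",
                      meta$token_id[r], conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(row)) failures <- c(failures, meta$token_id[r]) else
      rows[[length(rows) + 1L]] <- row
  }
  if (length(failures) > 0.1 * nrow(meta)) {
    stop(sprintf("run_measure: %d of %d tokens failed",
                 length(failures), nrow(meta)), call. = FALSE)
  }
  measures <- if (length(rows)) do.call(rbind, rows) else
    measure_token(waveform(numeric(1) + 1, 44100))[0, ]
  rownames(measures) <- NULL
  if (!is.null(out_csv)) {
    utils::write.csv(measures, out_csv, row.names = FALSE)
    write_config_snapshot(config, sub("\\.csv$", "_config.yaml", out_csv))
  }
  measures
}

#' Screen, scale and model a measured corpus against its ratings
#'
#' Runs the full analysis: token screening, token-wise removal of ratings of
#' excluded stimuli, min-max scaling of the retained measures, boundary
#' compression of the ratings, the AIC model comparison and the jump
#' summary.
#'
#' @param measures Measures data frame (from [run_measure()]).
#' @param ratings Ratings data frame with `listener_id`, `token_id`, `value`
#'   in \[0, 1\] (or `value_open`).
#' @param config A [run_config()].
#' @param out_dir Optional directory for JSON reports.
#' @return List: `screening` (a `screening_report`), `comparison` (a
#'   `comparison_report`), `jumps` (a `jump_report`), `analysis` (the
#'   modeling table), `scalings`.
#' @export
run_analyze <- function(measures, ratings, config = run_config(),
                        out_dir = NULL) {
  unknown <- setdiff(unique(ratings$token_id), measures$token_id)
  if (length(unknown)) {
    stop(sprintf("run_analyze: ratings reference unknown token_id(s): %s",
                 paste(utils::head(unknown, 5), collapse = ", ")),
         call. = FALSE)
  }
  screening <- screen_tokens(measures, config$min_s, config$k_sd,
                             config$max_overlap)
  sc <- scale_measures(screening$kept)
  kept <- sc$data
  ratings <- ratings[ratings$token_id %in% kept$token_id, , drop = FALSE]
  if (!"value_open" %in% names(ratings)) {
    ratings$value_open <- squeeze_boundaries(ratings$value)
  }
  analysis <- merge(ratings,
                    kept[, c("token_id", "target",
                             intersect(MEASURE_ORDER, names(kept)))],
                    by = "token_id", sort = FALSE)
  comparison <- run_comparison(analysis, alpha = config$alpha,
                               seed = config$seed)
  jumps <- jump_report(screening$kept)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(n_input = screening$n_input,
           n_short_excluded = screening$n_short_excluded,
           n_outlier_excluded = screening$n_outlier_excluded,
           n_overlap_flagged = screening$n_overlap_flagged,
           n_retained = screening$n_retained,
           n_ratings = nrow(analysis)),
      file.path(out_dir, "screening.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(models = comparison$models, ranking = comparison$ranking,
           winner = comparison$winner,
           baseline_aic = comparison$baseline_aic,
           jump_fraction = jumps$fraction),
      file.path(out_dir, "comparison.json"), auto_unbox = TRUE, digits = NA)
    write_config_snapshot(config, file.path(out_dir, "config.yaml"))
  }
  list(screening = screening, comparison = comparison, jumps = jumps,
       analysis = analysis, scalings = sc$scalings)
}
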