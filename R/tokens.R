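#' Transcription categories recognised by the pipeline
#'
#' Narrow transcription of each fricative token: a clear \[s\], a clear
#' \[sh\], or an intermediate sound closer to one end or the other.
#' @export
TRANSCRIPTION_LEVELS <- c("[s]", "[sh]", "[s]:[sh]", "[sh]:[s]")

#' Read a token metadata table
#'
#' @param path CSV with required columns `token_id`, `child_id`, `word`,
#'   `target` (1 = /s/, 0 = /sh/), `transcription` (one of
#'   [TRANSCRIPTION_LEVELS]), `onset_s`, `offset_s`.
#' @return A validated data frame.
#' @export
read_token_metadata <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("token_id", "child_id", "word", "target", "transcription",
                "onset_s", "offset_s")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    stop(sprintf("read_token_metadata: missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(meta$token_id)) {
    stop("read_token_metadata: duplicated token_id values", call. = FALSE)
  }
  if (!all(meta$target %in% c(0, 1))) {
    stop("read_token_metadata: 'target' must be coded /s/ = 1, /sh/ = 0",
         call. = FALSE)
  }
  bad <- setdiff(unique(meta$transcription), TRANSCRIPTION_LEVELS)
  if (length(bad)) {
    stop(sprintf("read_token_metadata: unknown transcription(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  meta
}

#' Extract annotated fricative tokens from a recording
#'
#' Joins a metadata table to the labeled intervals of an annotation tier (the
#' interval label must equal `token_id`; no fuzzy matching) and slices the
#' audio for each matched row. Slices are half-open `[onset, offset)` with
#' sample index `round(t * rate)`, so a shared boundary sample is never
#' double-counted.
#'
#' @param audio A [waveform()] covering the whole recording.
#' @param ann An `interval_annotation` from [read_textgrid()].
#' @param meta Metadata data frame (see [read_token_metadata()]).
#' @return A list of `fricative_token` objects, in metadata row order. Each is
#'   a list with `token_id`, `child_id`, `word`, `target`, `transcription`,
#'   `onset_s`, `offset_s` and `audio` (a [waveform()] slice).
#' @export
extract_tokens <- function(audio, ann, meta) {
  stopifnot(inherits(audio, "waveform"), inherits(ann, "interval_annotation"))
  iv <- ann$intervals
  unmatched <- setdiff(meta$token_id, iv$label)
  if (length(unmatched)) {
    stop(sprintf("extract_tokens: metadata row(s) with no matching interval: %s",
                 paste(unmatched, collapse = ", ")), call. = FALSE)
  }
  n_total <- length(audio$samples)
  out <- vector("list", nrow(meta))
  for (r in seq_len(nrow(meta))) {
    id <- meta$token_id[r]
    k <- which(iv$label == id)
    if (length(k) != 1L) {
      stop(sprintf("extract_tokens: token_id '%s' matches %d intervals",
                   id, length(k)), call. = FALSE)
    }
    onset <- iv$start[k]
    offset <- iv$end[k]
    if (is.finite(meta$onset_s[r]) &&
        abs(meta$onset_s[r] - onset) > 1e-3) {
      warning(sprintf("extract_tokens: onset mismatch for '%s' (metadata %.4f vs tier %.4f); using the tier",
                      id, meta$onset_s[r], onset), call. = FALSE)
    }
    i0 <- round(onset * audio$rate) + 1L
    i1 <- round(offset * audio$rate)
    if (i0 < 1L || i1 > n_total) {
      stop(sprintf("extract_tokens: interval for '%s' [%g, %g] s lies outside the audio (%g s)",
                   id, onset, offset, n_total / audio$rate), call. = FALSE)
    }
    out[[r]] <- structure(list(
      token_id = id,
      child_id = meta$child_id[r],
      word = meta$word[r],
      target = meta$target[r],
      transcription = meta$transcription[r],
      onset_s = onset,
      offset_s = offset,
      audio = waveform(audio$samples[i0:i1], audio$rate)
    ), class = "fricative_token")
  }
  out
}

#' @export
print.fricative_token <- function(x, ...) {
  cat(sprintf("<fricative_token '%s': target %s, %s, %.3f-%.3f s>\n",
              x$token_id, if (x$target == 1) "/s/" else "/sh/",
              x$transcription, x$onset_s, x$offset_s))
  invisible(x)
}

#' Read a corpus directory into a token list
#'
#' Expects the layout written by [write_corpus()]: `wav/<token_id>.wav`,
#' `textgrid/<token_id>.TextGrid` (tier `"fricative"`, one interval labeled
#' with the token id) and `tokens.csv` (metadata). One WAV per token and
#' continuous multi-token recordings are both supported: every metadata row is
#' looked up in the annotation of its own file (`file` column, optional;
#' default `<token_id>`).
#'
#' @param dir Corpus directory.
#' @param tier Annotation tier name (default `"fricative"`).
#' @return List of `fricative_token` objects.
#' @export
read_corpus <- function(dir, tier = "fricative") {
  meta <- read_token_metadata(file.path(dir, "tokens.csv"))
  files <- if ("file" %in% names(meta)) meta$file else meta$token_id
  out <- vector("list", nrow(meta))
  for (f in unique(files)) {
    rows <- which(files == f)
    audio <- read_wav(file.path(dir, "wav", paste0(f, ".wav")))
    ann <- read_textgrid(file.path(dir, "textgrid", paste0(f, ".TextGrid")),
                         tier = tier)
    out[rows] <- extract_tokens(audio, ann, meta[rows, , drop = FALSE])
  }
  out
}
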