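## Praat TextGrid text files come in two dialects: the verbose "long" form
## (key = value lines nested by item/intervals) and the "short" form (bare
## values, one per line, in the same order). Both are normalised here into a
## single value stream and interpreted identically, so the two dialects of the
## same annotation parse to the same result. UTF-8 and UTF-16 (BOM-detected)
## encodings are supported.

tg_read_lines <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("read_textgrid: file not found: '%s'", path), call. = FALSE)
  }
  bom <- readBin(path, "raw", 2L)
  enc <- if (length(bom) == 2L &&
             ((bom[1] == as.raw(0xFF) && bom[2] == as.raw(0xFE)) ||
              (bom[1] == as.raw(0xFE) && bom[2] == as.raw(0xFF)))) {
    "UTF-16"
  } else {
    "UTF-8"
  }
  con <- file(path, "r", encoding = enc)
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

## Turn a TextGrid body (after the two header lines) into a stream of values:
## numbers, quoted strings and bare flags, dropping structural decoration.
tg_value_stream <- function(lines) {
  vals <- list()
  lineno <- integer(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "") next
    ## structural lines of the long format carry no value
    if (grepl("^(item|intervals|points)\\s*\\[\\d*\\]\\s*:?\\s*$", ln)) next
    if (grepl("^item\\s*\\[\\]\\s*:?\\s*$", ln)) next
    ## "intervals: size = 3" / "points: size = 2" -> the count
    m <- regmatches(ln, regexec("^(intervals|points):\\s*size\\s*=\\s*(\\S+)$", ln))[[1]]
    if (length(m) == 3L) {
      vals[[length(vals) + 1L]] <- m[[3]]
      lineno[length(vals)] <- i
      next
    }
    ## "key = value" (long) or a bare value (short)
    v <- if (grepl("=", ln)) trimws(sub("^[^=]*=", "", ln)) else ln
    vals[[length(vals) + 1L]] <- v
    lineno[length(vals)] <- i
    next
  }
  list(values = unlist(vals), lines = lineno)
}

tg_unquote <- function(s) {
  s <- sub('^"', "", s)
  s <- sub('"$', "", s)
  gsub('""', '"', s)
}

tg_num <- function(stream, pos, path) {
  v <- suppressWarnings(as.numeric(stream$values[[pos]]))
  if (is.na(v)) {
    stop(sprintf(
      "read_textgrid: expected a number at line %d of '%s' (got '%s')",
      stream$lines[[pos]], path, stream$values[[pos]]), call. = FALSE)
  }
  v
}

#' Read one interval tier from a Praat TextGrid
#'
#' Parses both the long and the short text dialect, in UTF-8 or UTF-16.
#' Empty-label intervals are retained; filtering is the caller's concern.
#'
#' @param path Path to a `.TextGrid` file.
#' @param tier Name of the interval tier to extract.
#' @return An object of class `interval_annotation`: list with `tier_name` and
#'   a data frame `intervals` with columns `start`, `end`, `label` (seconds),
#'   sorted by `start`.
#' @export
read_textgrid <- function(path, tier) {
  lines <- tg_read_lines(path)
  if (length(lines) < 2L ||
      !grepl("ooTextFile", lines[[1]]) ||
      !grepl("TextGrid", lines[[2]])) {
    stop(sprintf("read_textgrid: '%s' does not look like a Praat TextGrid (bad header)",
                 path), call. = FALSE)
  }
  stream <- tg_value_stream(lines[-(1:2)])
  vals <- stream$values
  p <- 1L
  take_num <- function() {
    v <- tg_num(stream, p, path)
    p <<- p + 1L
    v
  }
  take_str <- function() {
    v <- tg_unquote(vals[[p]])
    p <<- p + 1L
    v
  }

  invisible(take_num())                 # global xmin
  invisible(take_num())                 # global xmax
  invisible({ p <- p + 1L })            # tiers? <exists> flag
  n_tiers <- as.integer(take_num())

  tiers_seen <- character(0)
  result <- NULL
  for (t in seq_len(n_tiers)) {
    klass <- take_str()
    name <- take_str()
    invisible(take_num())               # tier xmin
    invisible(take_num())               # tier xmax
    n_items <- as.integer(take_num())
    if (identical(klass, "IntervalTier")) {
      starts <- numeric(n_items); ends <- numeric(n_items)
      labels <- character(n_items)
      for (k in seq_len(n_items)) {
        starts[k] <- take_num()
        ends[k] <- take_num()
        labels[k] <- take_str()
      }
      tiers_seen <- c(tiers_seen, name)
      if (identical(name, tier) && is.null(result)) {
        o <- order(starts)
        iv <- data.frame(start = starts[o], end = ends[o],
                         label = labels[o], stringsAsFactors = FALSE)
        if (any(iv$end <= iv$start)) {
          stop(sprintf("read_textgrid: tier '%s' in '%s' has an interval with end <= start",
                       tier, path), call. = FALSE)
        }
        if (nrow(iv) > 1L && any(iv$start[-1L] < iv$end[-nrow(iv)] - 1e-9)) {
          stop(sprintf("read_textgrid: tier '%s' in '%s' has overlapping intervals",
                       tier, path), call. = FALSE)
        }
        result <- structure(list(tier_name = name, intervals = iv),
                            class = "interval_annotation")
      }
    } else {
      ## point tier (TextTier): skip number/mark pairs
      tiers_seen <- c(tiers_seen, name)
      for (k in seq_len(n_items)) {
        invisible(take_num())
        invisible(take_str())
      }
    }
  }
  if (is.null(result)) {
    stop(sprintf("read_textgrid: no interval tier named '%s' in '%s' (tiers present: %s)",
                 tier, path, paste(tiers_seen, collapse = ", ")), call. = FALSE)
  }
  result
}

#' @export
print.interval_annotation <- function(x, ...) {
  cat(sprintf("<interval_annotation: tier '%s', %d intervals>\n",
              x$tier_name, nrow(x$intervals)))
  invisible(x)
}

#' Write a single-tier TextGrid (long text format)
#'
#' Companion writer used by the synthetic-corpus generator so that generated
#' annotations round-trip through [read_textgrid()].
#'
#' @param intervals Data frame with columns `start`, `end`, `label`.
#' @param path Output path.
#' @param tier Tier name.
#' @param xmax Total file duration in seconds; defaults to the last interval
#'   end.
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(intervals, path, tier = "fricative",
                           xmax = max(intervals$end)) {
  q <- function(s) paste0('"', gsub('"', '""', s), '"')
  lines <- c(
    'File type = "ooTextFile"',
    'Object class = "TextGrid"',
    "",
    "xmin = 0",
    sprintf("xmax = %.17g", xmax),
    "tiers? <exists>",
    "size = 1",
    "item []:",
    "    item [1]:",
    '        class = "IntervalTier"',
    sprintf("        name = %s", q(tier)),
    "        xmin = 0",
    sprintf("        xmax = %.17g", xmax),
    sprintf("        intervals: size = %d", nrow(intervals))
  )
  for (k in seq_len(nrow(intervals))) {
    lines <- c(lines,
      sprintf("        intervals [%d]:", k),
      sprintf("            xmin = %.17g", intervals$start[k]),
      sprintf("            xmax = %.17g", intervals$end[k]),
      sprintf("            text = %s", q(intervals$label[k])))
  }
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}
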