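test_that("WAV files round-trip within one LSB of the sample format", {
  w <- with_seed(1, waveform(stats::runif(5000, -0.9, 0.9), 44100))
  for (bits in c(16L, 24L, 32L)) {
    path <- tempfile(fileext = ".wav")
    write_wav(w, path, bits = bits)
    w2 <- read_wav(path)
    expect_equal(w2$rate, 44100)
    expect_equal(length(w2$samples), length(w$samples))
    lsb <- switch(as.character(bits), "16" = 1 / 32767, "24" = 1 / 8388607,
                  "32" = 1e-7)
    expect_lt(max(abs(w2$samples - w$samples)), lsb + 1e-12)
    unlink(path)
  }
})

test_that("16-bit full-scale positive PCM reads as 1.0 and zeros stay zero", {
  path <- tempfile(fileext = ".wav")
  write_wav(waveform(rep(1, 100), 8000), path, bits = 16L)
  expect_true(all(abs(read_wav(path)$samples - 1) <= 1 / 32767))
  write_wav(waveform(rep(0, 44100), 44100), path, bits = 16L)
  w <- read_wav(path)
  expect_equal(length(w$samples), 44100)
  expect_true(all(w$samples == 0))
  unlink(path)
})

test_that("stereo WAV returns channel 1 with one sample per frame", {
  # hand-rolled 2-channel 16-bit file: ch1 ramps, ch2 is constant
  path <- tempfile(fileext = ".wav")
  n <- 50
  ch1 <- as.integer(seq(-1000, 1000, length.out = n))
  ch2 <- rep(32000L, n)
  inter <- as.vector(rbind(ch1, ch2))
  con <- file(path, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 4 * n), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")          # channels
  writeBin(8000L, con, size = 4, endian = "little")
  writeBin(32000L, con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(4 * n), con, size = 4, endian = "little")
  writeBin(inter, con, size = 2, endian = "little")
  close(con)
  expect_warning(w <- read_wav(path), "channel 1")
  expect_equal(length(w$samples), n)
  expect_equal(w$samples, ch1 / 32767, tolerance = 1e-12)
  unlink(path)
})

test_that("unreadable or empty audio raises format errors", {
  expect_error(read_wav(tempfile()), "not found")
  bad <- tempfile()
  writeLines("this is not audio at all, not even close", bad)
  expect_error(read_wav(bad), "RIFF")
  unlink(bad)
  expect_error(waveform(numeric(0), 44100), "non-empty")
  expect_error(waveform(c(1, NA), 44100), "finite")
})

short_textgrid <- function(path, tiers) {
  # `tiers`: named list of interval data frames -> short-format file
  xmax <- max(vapply(tiers, function(t) max(t$end), numeric(1)))
  lines <- c('File type = "ooTextFile"', 'Object class = "TextGrid"', "",
             "0", format(xmax), "<exists>", as.character(length(tiers)))
  for (nm in names(tiers)) {
    t <- tiers[[nm]]
    lines <- c(lines, '"IntervalTier"', paste0('"', nm, '"'),
               "0", format(xmax), as.character(nrow(t)))
    for (k in seq_len(nrow(t))) {
      lines <- c(lines, format(t$start[k]), format(t$end[k]),
                 paste0('"', t$label[k], '"'))
    }
  }
  writeLines(lines, path)
  path
}

test_that("long and short TextGrid dialects parse identically", {
  iv <- data.frame(start = c(0, 0.5, 1.2), end = c(0.5, 1.2, 2.0),
                   label = c("", "tok1", ""), stringsAsFactors = FALSE)
  p_long <- tempfile(fileext = ".TextGrid")
  p_short <- tempfile(fileext = ".TextGrid")
  write_textgrid(iv, p_long, tier = "phone", xmax = 2.0)
  short_textgrid(p_short, list(phone = iv))
  a <- read_textgrid(p_long, "phone")
  b <- read_textgrid(p_short, "phone")
  expect_equal(a$intervals, b$intervals, tolerance = 1e-12)
  expect_equal(nrow(a$intervals), 3L)          # empty labels retained
  expect_equal(a$intervals$label[2], "tok1")
  unlink(c(p_long, p_short))
})

test_that("missing tiers and malformed TextGrids produce clear errors", {
  iv <- data.frame(start = 0, end = 1, label = "x")
  p <- tempfile(fileext = ".TextGrid")
  write_textgrid(iv, p, tier = "phone")
  err <- expect_error(read_textgrid(p, "words2"), "words2")
  expect_match(conditionMessage(err), "phone")   # names available tiers
  writeLines(c("File type = \"ooTextFile\"", "Object class = \"TextGrid\"",
               "", "0", "1", "<exists>", "1", '"IntervalTier"', '"t"',
               "0", "1", "2", "0", "oops"), p)
  expect_error(read_textgrid(p, "t"), "line")
  writeLines("not a textgrid", p)
  expect_error(read_textgrid(p, "t"), "header")
  unlink(p)
})

test_that("token extraction slices half-open intervals at sample precision", {
  rate <- 44100
  audio <- waveform(seq_len(rate) / rate, rate)   # 1 s ramp
  iv <- data.frame(start = c(0.100, 0.400), end = c(0.250, 0.500),
                   label = c("tokA", "tokB"), stringsAsFactors = FALSE)
  ann <- structure(list(tier_name = "fricative", intervals = iv),
                   class = "interval_annotation")
  meta <- data.frame(token_id = c("tokA", "tokB"), child_id = "c1",
                     word = c("sun", "sheep"), target = c(1, 0),
                     transcription = c("[s]", "[sh]"),
                     onset_s = c(0.100, 0.400), offset_s = c(0.250, 0.500),
                     stringsAsFactors = FALSE)
  toks <- extract_tokens(audio, ann, meta)
  expect_length(toks, 2L)
  expect_equal(length(toks[[1]]$audio$samples), 6615L)   # round(0.15 * 44100)
  expect_equal(toks[[1]]$token_id, "tokA")
  # slices are disjoint: first sample of tokB is after last of tokA
  expect_equal(toks[[1]]$audio$samples[1], audio$samples[4411])
  expect_equal(toks[[2]]$audio$samples[1], audio$samples[round(0.4 * rate) + 1])

  meta_bad <- meta; meta_bad$token_id[2] <- "ghost"
  expect_error(extract_tokens(audio, ann, meta_bad), "ghost")

  iv2 <- iv; iv2$end[2] <- 1.5
  ann2 <- structure(list(tier_name = "fricative", intervals = iv2),
                    class = "interval_annotation")
  expect_error(extract_tokens(audio, ann2, meta), "outside the audio")
})

test_that("metadata validation enforces coding and category conventions", {
  p <- tempfile(fileext = ".csv")
  base <- data.frame(token_id = c("a", "b"), child_id = "c", word = "w",
                     target = c(1, 0), transcription = c("[s]", "[sh]:[s]"),
                     onset_s = 0, offset_s = 0.1)
  utils::write.csv(base, p, row.names = FALSE)
  expect_silent(meta <- read_token_metadata(p))
  bad <- base; bad$target <- c(1, 2)
  utils::write.csv(bad, p, row.names = FALSE)
  expect_error(read_token_metadata(p), "coded")
  bad <- base; bad$transcription[1] <- "[z]"
  utils::write.csv(bad, p, row.names = FALSE)
  expect_error(read_token_metadata(p), "transcription")
  bad <- base; bad$token_id <- c("a", "a")
  utils::write.csv(bad, p, row.names = FALSE)
  expect_error(read_token_metadata(p), "duplicated")
  unlink(p)
})
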