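#' Construct a waveform object
#'
#' A waveform is a mono sequence of dimensionless amplitudes with a sampling
#' rate in Hz. All audio handled by the package (recorded or synthesized) is
#' carried in this container.
#'
#' @param samples Numeric vector of finite amplitudes (nominally in
#'   \eqn{[-1, 1]}).
#' @param rate Sampling frequency in Hz (positive scalar).
#' @return An object of class `waveform`: a list with elements `samples` and
#'   `rate`.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * seq(0, 0.01, by = 1 / 8000)), 8000)
#' duration(w)
#' @export
waveform <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop("waveform: 'samples' must be non-empty", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("waveform: amplitudes must all be finite", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop("waveform: 'rate' must be a positive scalar (Hz)", call. = FALSE)
  }
  structure(list(samples = samples, rate = as.numeric(rate)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz (%.4f s)>\n",
              length(x$samples), x$rate, duration(x)))
  invisible(x)
}

#' Duration of a waveform in seconds
#'
#' @param w A [waveform()].
#' @return Duration in seconds (`length(samples) / rate`).
#' @export
duration <- function(w) {
  stopifnot(inherits(w, "waveform"))
  length(w$samples) / w$rate
}

## ---- RIFF/WAVE reading -----------------------------------------------------
## Minimal chunk walker for canonical WAV files: PCM 16/24-bit integer and
## 32-bit IEEE float, mono or multichannel (channel 1 kept). Integer data are
## scaled so that positive full scale maps to +1 (e.g. 32767 -> 1.0).

#' Read a WAV file
#'
#' Reads a RIFF/WAVE file containing 16- or 24-bit integer PCM or 32-bit IEEE
#' float samples. Multichannel files are reduced to channel 1 with a warning.
#'
#' @param path Path to a `.wav` file.
#' @return A [waveform()] with amplitudes scaled to \eqn{[-1, 1]} (integer
#'   formats are divided by their positive full-scale value).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("read_wav: file not found: '%s'", path), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    stop(sprintf("read_wav: '%s' is not a RIFF file", path), call. = FALSE)
  }
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    stop(sprintf("read_wav: '%s' is not a WAVE file", path), call. = FALSE)
  }

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(sz) == 0L) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz + (sz %% 2L))
      fmt <- list(
        format    = readBin(body[1:2], "integer", 1, size = 2,
                            endian = "little", signed = FALSE),
        channels  = readBin(body[3:4], "integer", 1, size = 2,
                            endian = "little", signed = FALSE),
        rate      = readBin(body[5:8], "integer", 1, size = 4,
                            endian = "little"),
        bits      = readBin(body[15:16], "integer", 1, size = 2,
                            endian = "little", signed = FALSE)
      )
      ## WAVE_FORMAT_EXTENSIBLE: actual format is in the GUID's first 2 bytes
      if (fmt$format == 0xFFFE && sz >= 26) {
        fmt$format <- readBin(body[25:26], "integer", 1, size = 2,
                              endian = "little", signed = FALSE)
      }
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", sz + (sz %% 2L)))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }

  if (is.null(fmt)) {
    stop(sprintf("read_wav: no 'fmt ' chunk in '%s'", path), call. = FALSE)
  }
  if (is.null(data_raw) || length(data_raw) == 0L) {
    stop(sprintf("read_wav: no audio data in '%s'", path), call. = FALSE)
  }

  x <- switch(as.character(fmt$format),
    "1" = {  # integer PCM
      if (fmt$bits == 16L) {
        readBin(data_raw, "integer", n = length(data_raw) %/% 2L,
                size = 2, endian = "little", signed = TRUE) / 32767
      } else if (fmt$bits == 24L) {
        n <- length(data_raw) %/% 3L
        b <- matrix(as.integer(data_raw[seq_len(3L * n)]), nrow = 3L)
        v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388607
      } else {
        stop(sprintf("read_wav: unsupported PCM bit depth %d", fmt$bits),
             call. = FALSE)
      }
    },
    "3" = {  # IEEE float
      if (fmt$bits != 32L) {
        stop(sprintf("read_wav: unsupported float bit depth %d", fmt$bits),
             call. = FALSE)
      }
      readBin(data_raw, "double", n = length(data_raw) %/% 4L,
              size = 4, endian = "little")
    },
    stop(sprintf("read_wav: unsupported WAV format code %d", fmt$format),
         call. = FALSE)
  )

  if (fmt$channels > 1L) {
    warning(sprintf("read_wav: %d channels in '%s'; keeping channel 1",
                    fmt$channels, path), call. = FALSE)
    x <- x[seq(1L, length(x), by = fmt$channels)]
  }
  if (length(x) == 0L) {
    stop(sprintf("read_wav: zero-length audio in '%s'", path), call. = FALSE)
  }
  waveform(x, fmt$rate)
}

#' Write a waveform to a WAV file
#'
#' @param w A [waveform()].
#' @param path Output path.
#' @param bits Sample format: 16 (integer PCM, default), 24 (integer PCM) or
#'   32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, bits = 16L) {
  stopifnot(inherits(w, "waveform"))
  bits <- as.integer(bits)
  if (!bits %in% c(16L, 24L, 32L)) {
    stop("write_wav: 'bits' must be 16, 24 or 32", call. = FALSE)
  }
  x <- pmin(1, pmax(-1, w$samples))
  n <- length(x)
  bytes_per <- bits %/% 8L
  fmt_code <- if (bits == 32L) 3L else 1L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n * bytes_per), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                # channels
  writeBin(as.integer(round(w$rate)), con, size = 4, endian = "little")
  writeBin(as.integer(round(w$rate)) * bytes_per, con, size = 4,
           endian = "little")                                    # byte rate
  writeBin(bytes_per, con, size = 2, endian = "little")          # block align
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n * bytes_per), con, size = 4, endian = "little")
  if (bits == 16L) {
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else if (bits == 24L) {
    v <- as.integer(round(x * 8388607))
    v <- ifelse(v < 0, v + 16777216L, v)
    b <- rbind(v %% 256L, (v %/% 256L) %% 256L, (v %/% 65536L) %% 256L)
    writeBin(as.raw(b), con)
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}
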