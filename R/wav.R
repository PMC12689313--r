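# Minimal RIFF/WAVE reader and writer (PCM 16-bit and IEEE float32, mono or
# stereo). The installed stack has no WAV package, and the formats used here
# are the two fixed subtypes the toolkit itself writes.

#' Read a WAV file
#'
#' Supports PCM 16-bit and IEEE float32, mono or multi-channel. Samples are
#' returned as doubles in \[-1, 1\] (PCM scaled by 1/32768).
#'
#' @param path Path to a `.wav` file.
#' @return List with `samples` (numeric matrix, channels in columns) and
#'   `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        format    = readBin(fmt_raw[1:2], "integer", 1, size = 2, endian = "little", signed = FALSE),
        channels  = readBin(fmt_raw[3:4], "integer", 1, size = 2, endian = "little", signed = FALSE),
        rate      = readBin(fmt_raw[5:8], "integer", 1, size = 4, endian = "little"),
        bits      = readBin(fmt_raw[15:16], "integer", 1, size = 2, endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + (sz %% 2)))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV (missing fmt/data): ", path)
  if (length(data_raw) == 0) stop("empty WAV data chunk: ", path)
  if (fmt$format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) / 2, size = 2,
                 endian = "little", signed = TRUE) / 32768
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "double", length(data_raw) / 4, size = 4,
                 endian = "little")
  } else {
    stop("unsupported WAV encoding (need PCM16 or float32): ", path)
  }
  list(samples = matrix(x, ncol = fmt$channels, byrow = TRUE),
       sample_rate = fmt$rate)
}

#' Write a WAV file
#'
#' @param samples Numeric vector (mono) or matrix with channels in columns,
#'   amplitudes nominally in \[-1, 1\].
#' @param sample_rate Sample rate in Hz.
#' @param path Output path.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @param normalize If `TRUE`, rescale by the peak when it exceeds 1 so the
#'   file never clips.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path, bits = 16, normalize = TRUE) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  stopifnot(bits %in% c(16, 32), sample_rate > 0)
  if (any(!is.finite(samples))) stop("non-finite samples")
  peak <- max(abs(samples))
  if (normalize && peak > 1) samples <- samples / peak
  nch <- ncol(samples)
  interleaved <- as.numeric(t(samples))
  bytes_per <- bits / 8
  data_sz <- length(interleaved) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_sz), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(as.integer(if (bits == 16) 1 else 3), con, size = 2, endian = "little")
  writeBin(as.integer(nch), con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * nch * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(nch * bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, size = 4, endian = "little")
  if (bits == 16) {
    q <- as.integer(pmax(pmin(round(interleaved * 32767), 32767), -32768))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(interleaved, con, size = 4, endian = "little")
  }
  invisible(path)
}
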