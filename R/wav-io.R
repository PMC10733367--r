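# Minimal RIFF/WAVE PCM I/O. Only what the pipeline needs: 16-bit PCM,
# mono (a multi-channel file is averaged to mono on read).

#' Write a mono waveform to a 16-bit PCM WAV file
#'
#' Samples are expected in `[-1, 1]`; values outside are clipped with a
#' warning.
#'
#' @param samples numeric vector of audio samples in `[-1, 1]`.
#' @param sample_rate_hz sampling rate in Hz.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate_hz, path) {
  if (any(abs(samples) > 1)) {
    phon_warn("samples outside [-1, 1] clipped on WAV write")
    samples <- pmin(1, pmax(-1, samples))
  }
  pcm <- as.integer(round(samples * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(sample_rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate_hz * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a PCM WAV file
#'
#' Supports 16-bit integer PCM; multi-channel audio is mixed down to mono.
#'
#' @param path WAV file path.
#' @return list with `samples` (numeric, in `[-1, 1]`) and `sample_rate_hz`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) phon_stop("invalidInput", "not a RIFF file: %s", path)
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) phon_stop("invalidInput", "not a WAVE file: %s", path)
  sample_rate <- NULL; n_channels <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      n_channels <- fmt[2]
      if (fmt[1] != 1L || bits != 16L) {
        phon_stop("invalidInput", "only 16-bit PCM WAV supported (got format %d, %d bits)",
                  fmt[1], bits)
      }
      extra <- size - 16L
      if (extra > 0) readBin(con, raw(), n = extra)
    } else if (identical(id, "data")) {
      if (is.null(sample_rate)) phon_stop("invalidInput", "data chunk before fmt chunk")
      samples <- readBin(con, integer(), n = size %/% 2L, size = 2,
                         signed = TRUE, endian = "little")
      break
    } else {
      readBin(con, raw(), n = size + (size %% 2L))
    }
  }
  if (is.null(samples)) phon_stop("invalidInput", "no data chunk in %s", path)
  x <- samples / 32767  # mirror of the writer's scaling
  if (n_channels > 1L) {
    x <- colMeans(matrix(x, nrow = n_channels))
  }
  list(samples = as.numeric(x), sample_rate_hz = sample_rate)
}
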