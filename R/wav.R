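#' Read and write mono 16-bit PCM WAV files
#'
#' Minimal RIFF/WAVE support for stimulus audio: 16-bit PCM, one channel.
#' `write_wav()` clips samples to \[-1, 1\] and scales to 16-bit integers;
#' `read_wav()` returns samples rescaled to \[-1, 1\].
#'
#' @param samples Numeric vector of audio samples in \[-1, 1\].
#' @param fs_hz Sampling rate in Hz.
#' @param path File path.
#' @return `read_wav()` returns a list with elements `samples` and `fs_hz`;
#'   `write_wav()` returns `path` invisibly.
#' @export
write_wav <- function(samples, fs_hz, path) {
  stopifnot(is.numeric(samples), fs_hz > 0)
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(fs_hz), con, size = 4, endian = "little")
  writeBin(as.integer(fs_hz * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) abort("not a RIFF/WAVE file")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) abort("not a RIFF/WAVE file")
  fs_hz <- NULL
  repeat {
    chunk <- readChar(con, 4)
    if (length(chunk) == 0 || nchar(chunk) < 4) abort("no data chunk found")
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(chunk, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      fs_hz <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, "raw", n = size - 8))
      if (fmt[1] != 1L || fmt[2] != 1L) abort("only mono 16-bit PCM supported")
    } else if (identical(chunk, "data")) {
      pcm <- readBin(con, integer(), n = size / 2, size = 2, endian = "little")
      return(list(samples = pcm / 32767, fs_hz = fs_hz))
    } else {
      invisible(readBin(con, "raw", n = size))
    }
  }
}
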