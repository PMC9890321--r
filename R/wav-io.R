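#' Read a mono 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE reader covering the format used for field recordings in
#' this package: linear PCM, 16-bit, single channel. Chunks other than `fmt `
#' and `data` (e.g. `LIST`) are skipped.
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (numeric vector scaled to \[-1, 1\]),
#'   `sample_rate` (Hz) and `bit_depth`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  sample_rate <- NULL; bit_depth <- NULL; n_channels <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only linear PCM WAV is supported")
      n_channels <- fmt[2]
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little") # byte rate
      readBin(con, "integer", 1, size = 2, endian = "little") # block align
      bit_depth <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (identical(id, "data")) {
      if (is.null(bit_depth)) stop("malformed WAV: data chunk before fmt")
      if (bit_depth != 16L) stop("only 16-bit WAV is supported")
      samples <- readBin(con, "integer", size / 2, size = 2, signed = TRUE,
                         endian = "little")
      if (size %% 2 == 1) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", size + size %% 2) # skip unknown chunk (word-aligned)
    }
    if (!is.null(samples) && !is.null(sample_rate)) break
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  if (!is.null(n_channels) && n_channels != 1L)
    stop("only mono WAV is supported")
  list(samples = samples / 32768, sample_rate = sample_rate,
       bit_depth = bit_depth)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples Numeric vector in \[-1, 1\]; values outside are clipped.
#' @param sample_rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  stopifnot(is.numeric(samples), length(samples) > 0, sample_rate > 0)
  x <- pmin(pmax(samples, -1), 32767 / 32768)
  pcm <- as.integer(round(x * 32768))
  data_size <- length(pcm) * 2L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                 # PCM
  writeBin(1L, con, size = 2, endian = "little")                 # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")                 # block align
  writeBin(16L, con, size = 2, endian = "little")                # bit depth
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
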