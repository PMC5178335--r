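## Minimal RIFF/WAVE reader and writer.
##
## The package generates and consumes standard PCM WAV so that external
## recordings drop straight into the pipeline. Only the two encodings the
## generator emits are supported: 16-bit integer PCM (format tag 1) and
## 32-bit IEEE float (format tag 3), mono or multi-channel, interleaved.

#' Write a waveform to a WAV file
#'
#' @param samples numeric vector (mono) or matrix with one column per
#'   channel, values in \[-1, 1\].
#' @param path output file path.
#' @param sampleRate sampling rate in Hz.
#' @param bitDepth 16 (integer PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".wav")
#' writeWav(sin(2 * pi * 440 * seq(0, 0.01, by = 1/44100)), f, 44100)
#' w <- readWav(f)
#' w$sampleRate
#' @export
writeWav <- function(samples, path, sampleRate, bitDepth = 16L) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("'samples' must be a numeric vector or matrix")
  if (!bitDepth %in% c(16L, 32L)) stop("bitDepth must be 16 or 32")
  nCh <- ncol(samples)
  nFrames <- nrow(samples)
  bytesPerSample <- bitDepth / 8L
  blockAlign <- nCh * bytesPerSample
  dataBytes <- nFrames * blockAlign
  fmtTag <- if (bitDepth == 16L) 1L else 3L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataBytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmtTag, con, size = 2, endian = "little")
  writeBin(nCh, con, size = 2, endian = "little")
  writeBin(as.integer(sampleRate), con, size = 4, endian = "little")
  writeBin(as.integer(sampleRate * blockAlign), con, size = 4, endian = "little")
  writeBin(as.integer(blockAlign), con, size = 2, endian = "little")
  writeBin(as.integer(bitDepth), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataBytes), con, size = 4, endian = "little")
  interleaved <- as.numeric(t(samples))
  if (bitDepth == 16L) {
    x <- pmax(pmin(interleaved, 1), -1)
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(interleaved, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file
#'
#' @param path WAV file path.
#' @return list with `samples` (numeric matrix, frames x channels, in
#'   \[-1, 1\]), `sampleRate`, and `bitDepth`.
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4L) != "RIFF") stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", size = 4, endian = "little"))
  if (readChar(con, 4L) != "WAVE") stop("not a WAVE file: ", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4L)
    if (length(id) == 0L || nchar(id) < 4L) stop("no data chunk in ", path)
    sz <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        tag = readBin(con, "integer", size = 2, endian = "little"),
        nCh = readBin(con, "integer", size = 2, endian = "little"),
        rate = readBin(con, "integer", size = 4, endian = "little"),
        byteRate = readBin(con, "integer", size = 4, endian = "little"),
        blockAlign = readBin(con, "integer", size = 2, endian = "little"),
        bits = readBin(con, "integer", size = 2, endian = "little"))
      if (sz > 16L) invisible(readBin(con, "raw", n = sz - 16L))
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk precedes fmt chunk in ", path)
      n <- sz / (fmt$bits / 8L)
      x <- if (fmt$tag == 1L && fmt$bits == 16L) {
        readBin(con, "integer", n = n, size = 2, signed = TRUE,
                endian = "little") / 32767
      } else if (fmt$tag == 3L && fmt$bits == 32L) {
        readBin(con, "double", n = n, size = 4, endian = "little")
      } else {
        stop("unsupported WAV encoding (tag ", fmt$tag, ", ", fmt$bits, " bit)")
      }
      samples <- matrix(x, ncol = fmt$nCh, byrow = TRUE)
      return(list(samples = samples, sampleRate = fmt$rate, bitDepth = fmt$bits))
    } else {
      invisible(readBin(con, "raw", n = sz + (sz %% 2L)))
    }
  }
}
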