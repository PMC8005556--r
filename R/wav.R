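#' Read a PCM WAV file into a trace
#'
#' Reads a RIFF/WAVE file containing 16-bit integer PCM samples. Multichannel
#' files are reduced to their first channel. Samples are scaled to
#' \[-1, 1\] (division by 32768) and the rate is taken from the format chunk.
#'
#' @param path Path to a `.wav` file.
#' @param label Channel label for the returned trace.
#' @return A [sampled_trace] with unit `"dimensionless"`.
#' @seealso [write_wav()]
#' @export
read_wav <- function(path, label = "speech") {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    stop("not a RIFF file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, 2, signed = FALSE,
                               endian = "little"),
        n_channels = readBin(body[3:4], "integer", 1, 2, signed = FALSE,
                             endian = "little"),
        rate = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(body[15:16], "integer", 1, 2, signed = FALSE,
                       endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("missing fmt or data chunk in ", path, call. = FALSE)
  if (fmt$audio_format != 1L || fmt$bits != 16L)
    stop("only 16-bit integer PCM WAV is supported", call. = FALSE)

  x <- readBin(data_raw, "integer", n = length(data_raw) %/% 2L,
               size = 2, signed = TRUE, endian = "little")
  if (fmt$n_channels > 1L)
    x <- x[seq(1L, length(x), by = fmt$n_channels)]
  sampled_trace(x / 32768, fmt$rate, units = "dimensionless", label = label)
}

#' Write a trace as a 16-bit PCM WAV file
#'
#' Samples are clipped to \[-1, 1\] and quantized to 16-bit integers.
#'
#' @param trace A [sampled_trace].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(trace, path) {
  stopifnot(is_trace(trace))
  x <- pmin(pmax(trace$samples, -1), 1)
  pcm <- as.integer(pmin(pmax(round(x * 32768), -32768), 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(round(trace$rate)), con, size = 4, endian = "little")
  writeBin(as.integer(round(trace$rate)) * 2L, con, size = 4,
           endian = "little")                               # byte rate
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
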