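# Minimal RIFF/WAVE reader and writer for the stimulus pipeline.
# Supports PCM 16-bit integer and IEEE float 32-bit, mono and stereo,
# which covers the emotional-speech source material and everything the
# package itself writes.

#' Read a WAV file
#'
#' Reads PCM 16-bit or IEEE float 32-bit WAV, mono or stereo. Integer
#' samples are rescaled to `[-1, 1)` (division by 32768).
#'
#' @param path path to a `.wav` file.
#' @return An [audio_clip()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  u32 <- function() readBin(con, "integer", 1L, size = 4, endian = "little")
  u16 <- function() readBin(con, "integer", 1L, size = 2, endian = "little", signed = FALSE)
  tag <- function() rawToChar(readBin(con, "raw", 4L))
  if (tag() != "RIFF") stop_("%s is not a RIFF file", path)
  u32()
  if (tag() != "WAVE") stop_("%s is not a WAVE file", path)
  fmt <- NULL
  repeat {
    id <- tag()
    if (length(id) == 0L || nchar(id) < 4L) stop_("no data chunk found in %s", path)
    size <- u32()
    if (id == "fmt ") {
      fmt <- list(format = u16(), channels = u16(), rate = u32())
      u32(); u16()                      # byte rate, block align
      fmt$bits <- u16()
      if (size > 16) readBin(con, "raw", size - 16L)
    } else if (id == "data") {
      if (is.null(fmt)) stop_("data chunk before fmt chunk in %s", path)
      if (fmt$format == 1L && fmt$bits == 16L) {
        n <- size %/% 2L
        x <- readBin(con, "integer", n, size = 2, endian = "little") / 32768
      } else if (fmt$format == 3L && fmt$bits == 32L) {
        n <- size %/% 4L
        x <- readBin(con, "double", n, size = 4, endian = "little")
      } else {
        stop_("unsupported WAV encoding (format %d, %d bits) in %s",
              fmt$format, fmt$bits, path)
      }
      if (fmt$channels == 2L) {
        x <- cbind(x[seq(1, length(x), by = 2)], x[seq(2, length(x), by = 2)])
      } else if (fmt$channels != 1L) {
        stop_("unsupported channel count %d in %s", fmt$channels, path)
      }
      return(audio_clip(x, fmt$rate))
    } else {
      readBin(con, "raw", size + size %% 2L)  # skip chunk (word aligned)
    }
  }
}

#' Write a WAV file
#'
#' Writes PCM 16-bit (`bit_depth = 16`, samples clipped to `[-1, 1]` and
#' scaled by 32767) or IEEE float 32-bit (`bit_depth = "float32"`).
#'
#' @param clip an [audio_clip()].
#' @param path output path.
#' @param bit_depth `16` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path, bit_depth = "float32") {
  stopifnot(inherits(clip, "audio_clip"))
  channels <- if (is.matrix(clip$samples)) 2L else 1L
  x <- if (channels == 2L) as.vector(t(clip$samples)) else clip$samples
  float <- identical(bit_depth, "float32")
  if (!float && !identical(bit_depth, 16) && !identical(bit_depth, 16L)) {
    stop_("bit_depth must be 16 or \"float32\"")
  }
  bytes_per <- if (float) 4L else 2L
  data_size <- length(x) * bytes_per
  rate <- as.integer(round(clip$sample_rate))
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36L + data_size)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16L)
  w16(if (float) 3L else 1L); w16(channels); w32(rate)
  w32(rate * channels * bytes_per); w16(channels * bytes_per)
  w16(8L * bytes_per)
  writeChar("data", con, eos = NULL); w32(data_size)
  if (float) {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(pmax(-1, pmin(1, x)) * 32767)), con,
             size = 2, endian = "little")
  }
  invisible(path)
}
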