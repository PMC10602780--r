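#' Construct an audio signal
#'
#' A minimal container for mono audio: a numeric sample vector in
#' \eqn{[-1, 1]} plus a sampling rate.
#'
#' @param samples numeric vector of samples.
#' @param rate sampling rate in Hz.
#' @return an object of class `audio_signal`.
#' @export
audio_signal <- function(samples, rate) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop_prosopath("sampling rate must be a single positive number",
                   "prosopath_audio_error")
  if (length(samples) < 1L)
    stop_prosopath("audio must contain at least one sample",
                   "prosopath_audio_error")
  structure(list(samples = as.numeric(samples), rate = as.numeric(rate)),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

#' Duration of an audio signal in seconds
#' @param audio an `audio_signal`.
#' @return duration in seconds.
#' @export
audio_duration <- function(audio) length(audio$samples) / audio$rate

#' Extract a time slice of an audio signal
#' @param audio an `audio_signal`.
#' @param start_s,end_s slice bounds in seconds (clamped to the signal).
#' @return an `audio_signal` holding the slice.
#' @export
audio_slice <- function(audio, start_s, end_s) {
  i0 <- max(1L, floor(start_s * audio$rate) + 1L)
  i1 <- min(length(audio$samples), ceiling(end_s * audio$rate))
  if (i1 < i0)
    stop_prosopath("empty audio slice", "prosopath_audio_error")
  audio_signal(audio$samples[i0:i1], audio$rate)
}

#' Read a mono PCM WAV file
#'
#' Minimal RIFF/WAVE reader for uncompressed 16-bit mono PCM, the only
#' format the pipeline emits and consumes.
#'
#' @param path path to a WAV file.
#' @return an `audio_signal`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    stop_prosopath("not a RIFF/WAVE file", "prosopath_audio_error")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stop_prosopath("not a RIFF/WAVE file", "prosopath_audio_error")
  rate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, 2, endian = "little", signed = FALSE)
      channels <- fmt[2]
      rate <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little"))
      invisible(readBin(con, "integer", 1, 2, endian = "little"))
      bits <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (identical(id, "data")) {
      if (is.null(bits)) stop_prosopath("WAV data before fmt chunk",
                                        "prosopath_audio_error")
      n <- size %/% (bits %/% 8L)
      samples <- readBin(con, "integer", n, bits %/% 8L, endian = "little",
                         signed = TRUE)
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(samples))
    stop_prosopath("no data chunk in WAV file", "prosopath_audio_error")
  if (!identical(channels, 1L))
    stop_prosopath("only mono WAV is supported", "prosopath_audio_error")
  audio_signal(samples / 2^(bits - 1), rate)
}

#' Write a mono PCM16 WAV file
#'
#' @param audio an `audio_signal`; samples are clipped to \eqn{[-1, 1]}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path) {
  s <- pmin(1, pmax(-1, audio$samples))
  pcm <- as.integer(round(s * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")              # PCM
  writeBin(1L, con, 2, endian = "little")              # mono
  writeBin(as.integer(audio$rate), con, 4, endian = "little")
  writeBin(as.integer(audio$rate) * 2L, con, 4, endian = "little")
  writeBin(2L, con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}

# Frame decomposition: start times of frames of length frame_s at hop hop_s.
# A frame covers [start, start + frame_s); only complete frames are used.
frame_starts <- function(duration_s, frame_s, hop_s) {
  if (duration_s < frame_s) return(numeric(0))
  seq(0, duration_s - frame_s, by = hop_s)
}

# Per-frame RMS of an audio signal; returns data.frame(time, rms) where
# time is the frame START (interval convention: frame = [time, time+frame]).
frame_rms <- function(audio, frame_ms = 25, hop_ms = 10) {
  n <- length(audio$samples)
  flen <- max(1L, round(frame_ms / 1000 * audio$rate))
  hop <- max(1L, round(hop_ms / 1000 * audio$rate))
  starts <- seq(1L, n - flen + 1L, by = hop)
  if (n < flen) starts <- 1L
  cs <- c(0, cumsum(audio$samples^2))
  ends <- pmin(starts + flen - 1L, n)
  rms <- sqrt((cs[ends + 1L] - cs[starts]) / (ends - starts + 1L))
  data.frame(time = (starts - 1L) / audio$rate, rms = rms)
}

#' Intensity contour of an audio signal
#'
#' Frame RMS expressed in dB re 20 micro-units (the digital analogue of
#' the SPL reference), so that speech-like amplitudes land in the familiar
#' 50-90 dB range and the contour mean is strictly positive.
#'
#' @param audio an `audio_signal`.
#' @param frame_ms frame length in ms.
#' @param hop_ms hop in ms.
#' @return data.frame with columns `time` (s, frame start) and `db`.
#' @export
intensity_track <- function(audio, frame_ms = 32, hop_ms = 10) {
  fr <- frame_rms(audio, frame_ms, hop_ms)
  db <- 20 * log10(pmax(fr$rms, .Machine$double.xmin) / 2e-5)
  structure(data.frame(time = fr$time, db = db),
            class = c("intensity_track", "data.frame"))
}
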