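#' Synthesize a schematic trial waveform
#'
#' Produces one harmonic vowel-like burst per digit of the response, with the
#' acoustic correlates of load built in: the fundamental rises by a factor
#' `1 + k_f * load` over the speaker's base F0, the amplitude by
#' `1 + k_a * load`, and the inter-digit pause shortens with load. The bursts
#' are deliberately schematic (harmonic stacks, not phonetically realistic
#' digits); the feature-extraction path only needs load-monotone acoustics.
#'
#' @param digits Integer digit vector spoken (only its length matters
#'   acoustically).
#' @param load Relative cognitive load in (0, 1].
#' @param base_f0 Speaker's baseline fundamental, Hz.
#' @param k_f,k_a Fractional F0 / amplitude increase per unit load.
#' @param amplitude Baseline peak amplitude of a burst (0 gives silence).
#' @param burst_duration,pause_duration Seconds per digit burst and baseline
#'   inter-digit pause.
#' @param pause_load_shortening Fractional pause shortening at load 1.
#' @param n_harmonics Harmonics in each burst (amplitude 1/h).
#' @param sample_rate Sampling rate, Hz.
#' @return List with `samples` (peak amplitude <= 1) and `sample_rate`.
#' @export
#' @examples
#' w <- synthesize_trial_audio(c(9, 3, 7, 2), load = 0.5)
#' length(w$samples) / w$sample_rate
synthesize_trial_audio <- function(digits, load, base_f0 = 160, k_f = 0.15,
                                   k_a = 0.3, amplitude = 0.3,
                                   burst_duration = 0.3, pause_duration = 0.3,
                                   pause_load_shortening = 0.4,
                                   n_harmonics = 5L, sample_rate = 16000) {
  if (load <= 0 || load > 1) verr("invalid_parameter", "load must be in (0, 1]")
  if (length(digits) < 1L) verr("invalid_parameter", "need at least one digit")
  f0 <- base_f0 * (1 + k_f * load)
  amp <- amplitude * (1 + k_a * load)
  pause <- max(0.02, pause_duration * (1 - pause_load_shortening * load))
  tb <- seq(0, burst_duration, by = 1 / sample_rate)
  env <- 0.5 - 0.5 * cos(2 * pi * seq_along(tb) / length(tb))
  burst <- rowSums(vapply(seq_len(n_harmonics),
                          function(h) sin(2 * pi * h * f0 * tb) / h,
                          numeric(length(tb)))) * env
  if (max(abs(burst)) > 0) burst <- amp * burst / max(abs(burst))
  gap <- numeric(round(pause * sample_rate))
  samples <- c(numeric(length(gap)),
               unlist(lapply(seq_along(digits),
                             function(i) c(burst, gap)), use.names = FALSE))
  samples <- samples / max(1, max(abs(samples)))
  list(samples = samples, sample_rate = sample_rate)
}

#' Write a waveform to a 16-bit mono PCM WAV file
#'
#' Minimal RIFF writer (16-bit signed little-endian mono PCM), matching the
#' recording format of the remote assessment platform.
#'
#' @param w List with `samples` in `[-1, 1]` and `sample_rate`, or a numeric
#'   vector (then `sample_rate` is taken from the argument).
#' @param path Output path.
#' @param sample_rate Sampling rate, Hz, when `w` is a bare vector.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, sample_rate = 16000) {
  if (is.list(w)) { sample_rate <- w$sample_rate; w <- w$samples }
  pcm <- as.integer(round(pmax(-1, pmin(1, w)) * 32767))
  con <- file(path, "wb"); on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * length(pcm)), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * length(pcm)), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit mono PCM WAV file
#'
#' @param path WAV path. Only 16-bit mono PCM is accepted.
#' @return List with `samples` (numeric in `[-1, 1]`) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  if (!identical(readChar(con, 4), "RIFF")) verr("schema", "not a RIFF file")
  readBin(con, integer(), size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) verr("schema", "not a WAVE file")
  sample_rate <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      ba_bits <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L || ba_bits[2] != 16L)
        verr("schema", "only 16-bit mono PCM WAV is supported")
      if (sz > 16) readBin(con, raw(), n = sz - 16)
    } else if (identical(id, "data")) {
      samples <- readBin(con, integer(), n = sz / 2, size = 2,
                         endian = "little", signed = TRUE) / 32767
    } else readBin(con, raw(), n = sz)
    if (!is.null(sample_rate) && !is.null(samples)) break
  }
  if (is.null(samples)) verr("schema", "no data chunk found")
  list(samples = samples, sample_rate = sample_rate)
}
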