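#' Low-level descriptor and functional naming of the reduced feature set
#'
#' The per-trial acoustic vector is built from 18 low-level descriptors
#' (F0, RMS energy, zero-crossing rate, spectral centroid, spectral rolloff,
#' spectral flux, and MFCC 1-12) computed on a 10 ms frame grid, each
#' aggregated by 14 statistical functionals, giving 252 features per trial.
#' This is a documented reduction of the very large utterance-level
#' paralinguistic sets used in production toolkits: the pipeline only needs a
#' fixed, load-sensitive vector.
#'
#' @return Character vectors of the descriptor and functional names, in the
#'   fixed output order `{lld}_{functional}`.
#' @export
lld_names <- function() {
  c("f0", "rms", "zcr", "centroid", "rolloff", "flux", paste0("mfcc", 1:12))
}

#' @rdname lld_names
#' @export
functional_names <- function() {
  c("mean", "sd", "skewness", "kurtosis", "min", "max", "range",
    "q25", "q50", "q75", "iqr", "slope", "offset", "mse")
}

#' Slice a waveform into fixed-length analysis frames
#'
#' @param samples Numeric waveform in `[-1, 1]`.
#' @param sample_rate Sampling rate, Hz.
#' @param frame_duration Frame length, seconds (default 10 ms, a horizon over
#'   which speech can be treated as stationary).
#' @param hop Hop between frame starts, seconds.
#' @return Matrix (frames x samples-per-frame); the trailing partial frame is
#'   dropped.
#' @export
frame_signal <- function(samples, sample_rate = 16000,
                         frame_duration = 0.010, hop = 0.010) {
  if (frame_duration <= 0 || hop <= 0)
    verr("invalid_parameter", "frame_duration and hop must be positive")
  flen <- floor(frame_duration * sample_rate)
  hlen <- max(1L, floor(hop * sample_rate))
  if (length(samples) < flen)
    verr("empty_input", "waveform shorter than one frame (%d < %d samples)",
         length(samples), flen)
  starts <- seq.int(1L, length(samples) - flen + 1L, by = hlen)
  matrix(samples[outer(starts, 0:(flen - 1L), `+`)], nrow = length(starts))
}

# Triangular mel filter bank (n_mel filters spanning 0..sr/2) applied to a
# magnitude spectrum with n_bins bins of an n_fft-point FFT.
mel_filterbank <- function(n_mel, n_bins, n_fft, sample_rate) {
  hz2mel <- function(f) 2595 * log10(1 + f / 700)
  mel2hz <- function(m) 700 * (10^(m / 2595) - 1)
  pts <- mel2hz(seq(hz2mel(0), hz2mel(sample_rate / 2), length.out = n_mel + 2))
  bins <- (0:(n_bins - 1)) * sample_rate / n_fft
  fb <- matrix(0, n_mel, n_bins)
  for (m in seq_len(n_mel)) {
    l <- pts[m]; c <- pts[m + 1]; r <- pts[m + 2]
    up <- (bins - l) / (c - l); down <- (r - bins) / (r - c)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Per-frame F0 by normalized autocorrelation with a voicing decision: the
# smallest candidate lag within 5% of the global peak wins (octave guard);
# frames whose peak falls below the voicing threshold are unvoiced (F0 = 0).
frame_f0 <- function(frame, sample_rate, f0_range, voicing_threshold) {
  x <- frame - mean(frame)
  n <- length(x)
  lmin <- max(2L, ceiling(sample_rate / f0_range[2]))
  lmax <- min(floor(sample_rate / f0_range[1]), n - 2L)
  if (sum(x^2) < 1e-12 || lmin > lmax) return(0)
  lags <- lmin:lmax
  r <- vapply(lags, function(l) {
    a <- x[1:(n - l)]; b <- x[(l + 1):n]
    den <- sqrt(sum(a^2) * sum(b^2))
    if (den < 1e-12) 0 else sum(a * b) / den
  }, numeric(1))
  pk <- max(r)
  if (pk < voicing_threshold) return(0)
  sample_rate / lags[which(r >= 0.95 * pk)[1]]
}

#' Low-level descriptors of framed audio
#'
#' Computes, per frame: F0 (autocorrelation peak within `f0_range`, 0 when
#' the normalized peak falls below `voicing_threshold` or the frame is
#' silent), RMS energy, zero-crossing rate, spectral centroid, spectral
#' rolloff (`rolloff_pct` of spectral energy), spectral flux, and MFCC 1-12
#' (Hann window, magnitude FFT, `n_mel`-filter mel bank to half the sample
#' rate, log energies, DCT-II). The lower end of `f0_range` is effectively
#' clipped to periods that fit in one frame (about 101 Hz for 10 ms frames at
#' 16 kHz); pass longer frames for low-pitched material.
#'
#' @param frames Matrix from [frame_signal()].
#' @param sample_rate Sampling rate, Hz.
#' @param f0_range F0 search range, Hz.
#' @param voicing_threshold Normalized autocorrelation floor for voicing.
#' @param rolloff_pct Spectral-energy fraction of the rolloff point.
#' @param n_mel Mel filter count.
#' @return Matrix (frames x 18) with columns [lld_names()].
#' @export
compute_llds <- function(frames, sample_rate = 16000, f0_range = c(50, 500),
                         voicing_threshold = 0.3, rolloff_pct = 0.85,
                         n_mel = 26L) {
  if (is.null(dim(frames)) || nrow(frames) < 1L)
    verr("empty_input", "frames must be a non-empty matrix")
  nfr <- nrow(frames); flen <- ncol(frames)
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(flen - 1)) / (flen - 1))
  n_bins <- flen %/% 2 + 1L
  S <- Mod(mvfft(t(frames) * win))[1:n_bins, , drop = FALSE]  # bins x frames
  freqs <- (0:(n_bins - 1)) * sample_rate / flen

  tot <- colSums(S)
  centroid <- ifelse(tot > 1e-12, colSums(freqs * S) / pmax(tot, 1e-12), 0)
  rolloff <- vapply(seq_len(nfr), function(i) {
    if (tot[i] <= 1e-12) return(0)
    freqs[which(cumsum(S[, i]) >= rolloff_pct * tot[i])[1]]
  }, numeric(1))
  flux <- c(0, if (nfr > 1)
    sqrt(colSums((S[, -1, drop = FALSE] - S[, -nfr, drop = FALSE])^2)))

  rms <- sqrt(rowMeans(frames^2))
  sgn <- sign(frames)
  zcr <- if (flen > 1)
    rowSums(abs(sgn[, -1, drop = FALSE] - sgn[, -flen, drop = FALSE]) > 0) /
      (flen - 1)
  else rep(0, nfr)

  f0 <- vapply(seq_len(nfr), function(i)
    frame_f0(frames[i, ], sample_rate, f0_range, voicing_threshold),
    numeric(1))

  fb <- mel_filterbank(n_mel, n_bins, flen, sample_rate)
  loge <- log(pmax(fb %*% S, 1e-10))            # n_mel x frames
  j <- seq_len(n_mel)
  dct <- vapply(1:12, function(k) cos(pi * k * (j - 0.5) / n_mel),
                numeric(n_mel))                 # n_mel x 12
  mfcc <- t(loge) %*% dct                       # frames x 12

  out <- cbind(f0 = f0, rms = rms, zcr = zcr, centroid = centroid,
               rolloff = rolloff, flux = flux, mfcc)
  colnames(out) <- lld_names()
  out
}

#' Aggregate descriptor series into one per-trial feature vector
#'
#' Applies the 14 functionals ([functional_names()]) to every descriptor
#' column: central moments, extremes, quartiles, and an ordinary
#' least-squares line over the frame index 0..n-1 (slope, offset, residual
#' mean squared error). Skewness and kurtosis of a constant series are
#' defined as 0.
#'
#' @param s Descriptor matrix from [compute_llds()] (frames x descriptors).
#' @return Named numeric vector of length `14 * ncol(s)` in the fixed order
#'   `{lld}_{functional}`.
#' @export
compute_functionals <- function(s) {
  if (is.null(dim(s)) || nrow(s) < 2L)
    verr("insufficient_frames", "need >= 2 frames (SD and slope undefined)")
  n <- nrow(s)
  t <- 0:(n - 1)
  vt <- sum((t - mean(t))^2)
  out <- apply(s, 2, function(x) {
    m <- mean(x); sdev <- sd(x)
    q <- unname(quantile(x, c(0.25, 0.5, 0.75)))
    slope <- sum((t - mean(t)) * (x - m)) / vt
    offset <- m - slope * mean(t)
    mse <- mean((x - offset - slope * t)^2)
    c(mean = m, sd = sdev,
      skewness = if (sdev > 0) e1071::skewness(x) else 0,
      kurtosis = if (sdev > 0) e1071::kurtosis(x) else 0,
      min = min(x), max = max(x), range = max(x) - min(x),
      q25 = q[1], q50 = q[2], q75 = q[3], iqr = q[3] - q[1],
      slope = slope, offset = offset, mse = mse)
  })
  setNames(as.vector(out),
           as.vector(outer(functional_names(), colnames(s),
                           function(f, l) paste(l, f, sep = "_"))))
}

#' Extract the per-trial feature vector from a waveform
#'
#' Convenience wrapper: [frame_signal()] then [compute_llds()] then
#' [compute_functionals()].
#'
#' @param samples Numeric waveform in `[-1, 1]`, or a list with `samples` and
#'   `sample_rate` (as returned by [synthesize_trial_audio()] / [read_wav()]).
#' @param sample_rate Sampling rate, Hz (ignored when `samples` carries one).
#' @param ... Passed to [compute_llds()].
#' @return Named numeric vector of 252 features.
#' @export
extract_trial_features <- function(samples, sample_rate = 16000, ...) {
  if (is.list(samples)) {
    sample_rate <- samples$sample_rate
    samples <- samples$samples
  }
  compute_functionals(compute_llds(frame_signal(samples, sample_rate),
                                   sample_rate, ...))
}
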