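#' White Gaussian noise
#' @param duration seconds
#' @param rate sampling rate in Hz
#' @param seed integer seed (reproducible; the caller's RNG is untouched)
#' @export
white_noise <- function(duration, rate = 44100, seed = 1) {
  n <- round(duration * rate)
  mono_signal(with_local_seed(seed, rnorm(n)), rate)
}

#' Pink (1/f power) noise via FFT spectral shaping
#' @inheritParams white_noise
#' @export
pink_noise <- function(duration, rate = 44100, seed = 1) {
  n <- round(duration * rate)
  x <- with_local_seed(seed, rnorm(n))
  nfft <- next_pow2(n)
  f <- c(0, seq_len(nfft - 1)) * rate / nfft
  f[f > rate / 2] <- rate - f[f > rate / 2]        # mirror for neg freqs
  g <- ifelse(f < 1, 0, 1 / sqrt(f))
  y <- Re(fft(fft(c(x, numeric(nfft - n))) * g, inverse = TRUE)) / nfft
  y <- y[seq_len(n)]
  mono_signal(y / sqrt(mean(y^2)), rate)
}

# Welch power spectrum estimate on an nfft grid (one-sided, length nfft/2+1)
welch_psd <- function(x, nfft = 2048) {
  s <- x$samples
  hop <- nfft %/% 2
  w <- hann_window(nfft)
  nseg <- max(1L, (length(s) - nfft) %/% hop + 1L)
  acc <- numeric(nfft %/% 2 + 1)
  for (k in seq_len(nseg)) {
    seg <- s[((k - 1) * hop + 1):((k - 1) * hop + nfft)] * w
    X <- fft(seg)
    acc <- acc + abs(X[seq_len(nfft %/% 2 + 1)])^2
  }
  acc / (nseg * sum(w^2))
}

#' Generate stationary speech-shaped noise (SSN)
#'
#' A 2048-tap linear-phase FIR filter is derived from the difference between
#' the estimated magnitude spectrum of a white Gaussian noise sample and that
#' of the reference signal; filtering fresh white noise with it yields
#' stationary Gaussian noise whose long-term spectrum matches the
#' reference's. The output RMS is equalised to the reference RMS.
#'
#' @param reference a `mono_signal` whose long-term spectrum is to be matched
#'   (>= 10 s recommended for a stable estimate)
#' @param duration output duration in seconds
#' @param seed integer seed
#' @param n_taps FIR length (default 2048)
#' @return a `mono_signal`
#' @export
generate_ssn <- function(reference, duration, seed = 1, n_taps = 2048) {
  stopifnot(inherits(reference, "mono_signal"))
  if (n_taps <= 0) stop("n_taps must be positive")
  rate <- reference$rate
  nfft <- n_taps

  p_ref <- welch_psd(reference, nfft)
  wn <- white_noise(max(duration, 10), rate, seed = seed + 1000L)
  p_wht <- welch_psd(wn, nfft)
  mag <- sqrt(p_ref / pmax(p_wht, .Machine$double.eps))
  mag[!is.finite(mag)] <- 0

  # linear-phase FIR by frequency sampling: zero-phase ifft, centre, taper
  full <- c(mag, rev(mag[2:(nfft %/% 2)]))
  h <- Re(fft(full, inverse = TRUE)) / nfft
  h <- c(h[(nfft %/% 2 + 1):nfft], h[1:(nfft %/% 2)])
  h <- h * hann_window(n_taps)

  n <- round(duration * rate)
  x <- white_noise(duration + n_taps / rate, rate, seed = seed)
  y <- fft_conv(x$samples, h)[n_taps:(n_taps + n - 1)]
  y <- y * signal_rms(reference) / sqrt(mean(y^2))
  mono_signal(y, rate)
}

#' Generate a speech-like modulated masker
#'
#' A speech-spectrum carrier (SSN derived from `reference`) multiplied by a
#' slowly varying envelope with a modulation spectrum dominated by 2-8 Hz,
#' emulating the syllabic envelope of running speech including near-silent
#' gaps, while keeping the long-term spectrum of the unmodulated noise. The
#' envelope is a lognormal transform of band-limited (2-8 Hz) Gaussian
#' noise; its dynamic range leaves well over 5% of 12-ms frames more than
#' 20 dB below the mean power, which is what gives a short-time model
#' glimpses to exploit. RMS is equalised to the unmodulated SSN.
#'
#' @inheritParams generate_ssn
#' @param mod_depth modulation depth in \[0, 1\]; 0 returns unmodulated SSN,
#'   1 full speech-like modulation
#' @export
generate_speechlike <- function(reference, duration, seed = 1,
                                mod_depth = 1, n_taps = 2048) {
  carrier <- generate_ssn(reference, duration, seed = seed, n_taps = n_taps)
  if (mod_depth <= 0) return(carrier)
  rate <- carrier$rate
  n <- length(carrier$samples)

  lf <- with_local_seed(seed + 2000L, rnorm(n + round(2 * rate)))
  bp <- signal::butter(2, c(2, 8) / (rate / 2), type = "pass")
  e <- signal::filter(bp, lf)
  e <- e[(round(2 * rate) + 1):(round(2 * rate) + n)]   # drop filter warm-up
  e <- (e - mean(e)) / sqrt(mean((e - mean(e))^2))
  env <- exp(1.2 * mod_depth * e)

  y <- carrier$samples * env
  y <- y * signal_rms(carrier) / sqrt(mean(y^2))
  mono_signal(y, rate)
}

#' Average target sentences into a stationary target representation
#'
#' Sample-wise mean of the sentences after discarding the first `skip`
#' seconds of each and truncating all to the duration of the shortest; the
#' RMS of the average is then equalised to `reference_rms` (typically the
#' collocated masker's RMS).
#'
#' @param sentences list of `mono_signal`s (>= 2), equal rates
#' @param skip initial portion to discard, seconds (default 0.68)
#' @param reference_rms RMS the averaged signal is scaled to
#' @return a `mono_signal`
#' @export
average_target <- function(sentences, skip = 0.68, reference_rms) {
  if (length(sentences) < 2) stop("need at least two sentences")
  rates <- vapply(sentences, function(s) s$rate, numeric(1))
  if (length(unique(rates)) != 1) stop("sentences must share a sampling rate")
  rate <- rates[1]
  nskip <- round(skip * rate)
  lens <- vapply(sentences, function(s) length(s$samples), numeric(1))
  if (any(lens <= nskip)) stop("every sentence must be longer than `skip`")
  nkeep <- min(lens) - nskip
  acc <- Reduce(`+`, lapply(sentences,
                            function(s) s$samples[(nskip + 1):(nskip + nkeep)]))
  avg <- acc / length(sentences)
  avg <- avg * reference_rms / sqrt(mean(avg^2))
  mono_signal(avg, rate)
}
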