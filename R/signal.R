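#' Mono signal container
#'
#' A sampled single-channel waveform: numeric samples (linear amplitude,
#' dimensionless) plus a sampling rate in Hz. All synthesis in this package
#' defaults to 44.1 kHz; functions combining signals require equal rates and
#' never resample silently.
#'
#' @param samples numeric vector of finite amplitudes
#' @param rate sampling rate in Hz (> 0)
#' @return an object of class `mono_signal`
#' @export
mono_signal <- function(samples, rate) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number (Hz)")
  samples <- as.numeric(samples)
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("`samples` must be finite")
  structure(list(samples = samples, rate = rate), class = "mono_signal")
}

#' Binaural (two-ear) signal
#'
#' @param left,right `mono_signal` objects of equal length and rate
#' @return an object of class `binaural_signal`
#' @export
binaural_signal <- function(left, right) {
  stopifnot(inherits(left, "mono_signal"), inherits(right, "mono_signal"))
  if (left$rate != right$rate)
    stop("left and right sampling rates differ; resampling is not implicit")
  if (length(left$samples) != length(right$samples))
    stop("left and right must have equal length")
  structure(list(left = left, right = right, rate = left$rate),
            class = "binaural_signal")
}

#' @export
print.mono_signal <- function(x, ...) {
  cat(sprintf("<mono_signal> %d samples @ %g Hz (%.3f s), rms %.4g\n",
              length(x$samples), x$rate, length(x$samples) / x$rate,
              signal_rms(x)))
  invisible(x)
}

#' @export
print.binaural_signal <- function(x, ...) {
  cat(sprintf("<binaural_signal> %d samples @ %g Hz (%.3f s), rms L %.4g / R %.4g\n",
              length(x$left$samples), x$rate,
              length(x$left$samples) / x$rate,
              signal_rms(x$left), signal_rms(x$right)))
  invisible(x)
}

#' Signal duration in seconds
#' @param x a `mono_signal` or `binaural_signal`
#' @export
signal_duration <- function(x) {
  if (inherits(x, "binaural_signal")) x <- x$left
  length(x$samples) / x$rate
}

#' Root-mean-square amplitude
#' @param x a `mono_signal` (or numeric vector)
#' @export
signal_rms <- function(x) {
  s <- if (inherits(x, "mono_signal")) x$samples else as.numeric(x)
  sqrt(mean(s^2))
}

#' Scale a signal by a linear factor
#' @param x `mono_signal` or `binaural_signal`
#' @param factor linear gain
#' @export
signal_scale <- function(x, factor) {
  if (inherits(x, "binaural_signal"))
    return(binaural_signal(signal_scale(x$left, factor),
                           signal_scale(x$right, factor)))
  mono_signal(x$samples * factor, x$rate)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# FFT-based linear convolution, full length (n + m - 1).
fft_conv <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nfft <- 2^ceiling(log2(n))
  y <- Re(fft(fft(c(x, numeric(nfft - length(x)))) *
              fft(c(h, numeric(nfft - length(h)))), inverse = TRUE)) / nfft
  y[seq_len(n)]
}

# Next power of two
next_pow2 <- function(n) 2^ceiling(log2(n))
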