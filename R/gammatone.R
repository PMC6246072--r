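#' Equivalent rectangular bandwidth (ERB) at a frequency
#'
#' `erb_hz(f) = 24.7 * (4.37 * f / 1000 + 1)` (Glasberg & Moore). At 1 kHz the
#' ERB is about 132.6 Hz.
#'
#' @param f frequency in Hz
#' @export
erb_hz <- function(f) 24.7 * (4.37 * f / 1000 + 1)

#' ERB-rate (auditory frequency scale)
#'
#' `erb_rate(f) = 21.4 * log10(4.37 * f / 1000 + 1)`.
#'
#' @param f frequency in Hz
#' @export
erb_rate <- function(f) 21.4 * log10(4.37 * f / 1000 + 1)

#' Inverse of [erb_rate()]
#' @param e ERB-rate value
#' @export
erb_rate_inv <- function(e) (10^(e / 21.4) - 1) * 1000 / 4.37

#' Design an ERB-spaced gammatone filterbank
#'
#' Centre frequencies are equally spaced on the ERB-rate scale with
#' `density` filters per ERB (default 2, i.e. spacing of half an ERB). The
#' first centre sits at `fmin`; subsequent centres step by `1/density` ERB
#' and never exceed `fmax`. Each filter is a 4th-order gammatone with
#' bandwidth `1.019 * erb_hz(fc)`.
#'
#' @param fmin,fmax analysis range in Hz (20 <= fmin < fmax)
#' @param density filters per ERB
#' @return object of class `gammatone_bank` with fields `fc` (centres, Hz,
#'   ascending), `bw` (3-dB-equivalent bandwidth parameter, Hz), `density`,
#'   `fmin`, `fmax`
#' @export
design_gammatone_bank <- function(fmin = 80, fmax = 10000, density = 2) {
  if (!is.finite(fmin) || !is.finite(fmax) || fmin < 20 || fmin >= fmax)
    stop("invalid frequency range: need 20 <= fmin < fmax")
  if (density <= 0) stop("density must be positive")
  e <- seq(erb_rate(fmin), erb_rate(fmax), by = 1 / density)
  fc <- erb_rate_inv(e)
  structure(list(fc = fc, bw = 1.019 * erb_hz(fc), density = density,
                 fmin = fmin, fmax = fmax, n_bands = length(fc)),
            class = "gammatone_bank")
}

#' @export
print.gammatone_bank <- function(x, ...) {
  cat(sprintf("<gammatone_bank> %d bands, %.1f-%.1f Hz, %g per ERB\n",
              x$n_bands, min(x$fc), max(x$fc), x$density))
  invisible(x)
}

#' Filter a signal through a gammatone bank
#'
#' Returns real band signals (columns), same length as the input. The
#' realization is a cascade of four complex one-pole resonators per band,
#' magnitude-normalised at the centre frequency; phase alignment across bands
#' is not attempted because all downstream statistics are per band.
#'
#' @param x a `mono_signal`
#' @param bank a `gammatone_bank`
#' @param complex if `TRUE`, return the complex (analytic-like) band signals
#' @return numeric (or complex) matrix, `length(x) x n_bands`
#' @export
filter_bands <- function(x, bank, complex = FALSE) {
  stopifnot(inherits(x, "mono_signal"), inherits(bank, "gammatone_bank"))
  if (length(x$samples) == 0) stop("empty signal")
  if (max(bank$fc) > x$rate / 2)
    stop("bank extends beyond the Nyquist frequency")
  if (complex)
    .gammatone_bands_complex_cpp(x$samples, x$rate, bank$fc, bank$bw)
  else
    .gammatone_bands_cpp(x$samples, x$rate, bank$fc, bank$bw)
}

#' Short-time frame grid
#'
#' 24-ms Hann windows with 50% overlap (12-ms hop) by default; the Hann
#' taper halves the effective duration to about 12 ms.
#'
#' @param frame_length frame length in seconds
#' @param hop hop in seconds (default `frame_length / 2`)
#' @param window taper identifier; only `"hann"` and `"rect"` are provided
#' @export
frame_grid <- function(frame_length = 0.024, hop = frame_length / 2,
                       window = "hann") {
  if (frame_length <= 0 || hop <= 0) stop("frame_length and hop must be > 0")
  window <- match.arg(window, c("hann", "rect"))
  structure(list(frame_length = frame_length, hop = hop, window = window),
            class = "frame_grid")
}

# Periodic Hann taper of length n (periodic form keeps 50%-overlapped
# windows summing to a constant).
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

grid_samples <- function(grid, rate) {
  L <- max(1L, round(grid$frame_length * rate))
  H <- max(1L, round(grid$hop * rate))
  w <- if (grid$window == "hann") hann_window(L) else rep(1, L)
  list(L = L, H = H, w = w)
}

#' Slice a signal into tapered frames
#'
#' Trailing samples that do not fill a frame are discarded; the frame count
#' is `floor((N - L) / H) + 1`.
#'
#' @param x a `mono_signal`
#' @param grid a [frame_grid()]
#' @return matrix `L x n_frames` of tapered frames
#' @export
frame_signal <- function(x, grid = frame_grid()) {
  stopifnot(inherits(x, "mono_signal"), inherits(grid, "frame_grid"))
  g <- grid_samples(grid, x$rate)
  n <- length(x$samples)
  if (n < g$L) stop("signal shorter than one frame")
  nt <- (n - g$L) %/% g$H + 1L
  idx <- outer(seq_len(g$L), (seq_len(nt) - 1L) * g$H, "+")
  matrix(x$samples[idx] * g$w, nrow = g$L)
}

#' Framed (or long-term) interaural statistics per gammatone band
#'
#' For every band and frame: tapered power per ear, interaural phase (the
#' argument of the windowed cross-power between the left and right band
#' signals) and interaural coherence. Coherence is the maximum over lags
#' within +-1 ms of the magnitude of the normalised complex interaural
#' cross-correlation, i.e. the analytic-envelope form of the conventional
#' cross-correlation maximum; ties go to the smaller |lag|. Passing
#' `grid = "long-term"` computes a single statistic over the whole signal
#' (rectangular taper).
#'
#' Frames in which both ears carry exactly zero power are flagged undefined
#' (`NA` phase/coherence); consumers decide how to treat them.
#'
#' @param x a `binaural_signal`
#' @param bank a `gammatone_bank`
#' @param grid a [frame_grid()] or the string `"long-term"`
#' @param lag_max maximum cross-correlation lag in seconds (default 1 ms)
#' @param lag_step lag sampling step in seconds for the coherence search
#'   (default 0.25 ms; the complex-envelope objective is smooth on the scale
#'   of the band's inverse bandwidth, so a coarse grid suffices)
#' @return object of class `frame_stats`: matrices `power_l`, `power_r`,
#'   `phase`, `coherence` (`n_bands x n_frames`), plus `fc` and grid info
#' @export
interaural_stats <- function(x, bank, grid = frame_grid(),
                             lag_max = 1e-3, lag_step = 2.5e-4) {
  stopifnot(inherits(x, "binaural_signal"), inherits(bank, "gammatone_bank"))
  n <- length(x$left$samples)
  if (identical(grid, "long-term")) {
    L <- n; H <- n; w <- rep(1, n)
    long_term <- TRUE
  } else {
    stopifnot(inherits(grid, "frame_grid"))
    g <- grid_samples(grid, x$rate)
    L <- g$L; H <- g$H; w <- g$w
    long_term <- FALSE
  }
  if (n < L) stop("signal shorter than one frame")
  res <- .frame_stats_cpp(x$left$samples, x$right$samples, x$rate,
                          bank$fc, bank$bw, L, H, w,
                          max(1L, round(lag_max * x$rate)),
                          max(1L, round(lag_step * x$rate)))
  structure(list(power_l = res$power_l, power_r = res$power_r,
                 phase = res$phase, coherence = res$coherence,
                 fc = bank$fc, n_frames = res$n_frames,
                 long_term = long_term, rate = x$rate),
            class = "frame_stats")
}

#' @export
print.frame_stats <- function(x, ...) {
  cat(sprintf("<frame_stats> %d bands x %d frame(s)%s\n",
              nrow(x$power_l), x$n_frames,
              if (x$long_term) " [long-term]" else ""))
  invisible(x)
}
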