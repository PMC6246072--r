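#' Equalization-cancellation parameters
#'
#' Internal-noise constants limiting the binaural unmasking advantage:
#' amplitude jitter `sigma_eps` and time jitter `sigma_delta` of the
#' equalization-cancellation process. The defaults (0.25 and 105 us) are
#' the standard values of the EC model lineage; they enter the unmasking
#' expression through `k = (1 + sigma_eps^2) * exp(omega^2 * sigma_delta^2)`.
#'
#' @param sigma_eps amplitude-jitter coefficient (>= 0)
#' @param sigma_delta time jitter in seconds (>= 0)
#' @param floor_at_zero if `TRUE` (default) the unmasking advantage is
#'   floored at 0 dB (binaural listening is never allowed to hurt)
#' @export
ec_parameters <- function(sigma_eps = 0.25, sigma_delta = 105e-6,
                          floor_at_zero = TRUE) {
  if (sigma_eps < 0 || sigma_delta < 0) stop("jitter parameters must be >= 0")
  structure(list(sigma_eps = sigma_eps, sigma_delta = sigma_delta,
                 floor_at_zero = floor_at_zero), class = "ec_parameters")
}

#' Model configuration
#'
#' @param bank analysis filterbank ([design_gammatone_bank()])
#' @param grid short-time frame grid ([frame_grid()]); 24-ms half-overlapping
#'   Hann windows by default
#' @param ceiling maximum better-ear ratio per band and frame, dB (default
#'   20); prevents the target-to-masker ratio diverging in interferer pauses
#' @param ec [ec_parameters()]
#' @param weights `"sii"` for speech-intelligibility-index band-importance
#'   weights interpolated to the filterbank centres (renormalised), or
#'   `"uniform"`
#' @param masker_duration seconds of masker analysed per condition
#'   (default 120)
#' @param average `"db"` (default) averages per-frame broadband ratios in the
#'   dB domain; `"power"` averages linear ratios and converts once
#' @export
model_config <- function(bank = design_gammatone_bank(),
                         grid = frame_grid(),
                         ceiling = 20,
                         ec = ec_parameters(),
                         weights = c("sii", "uniform"),
                         masker_duration = 120,
                         average = c("db", "power")) {
  weights <- match.arg(weights)
  average <- match.arg(average)
  if (!is.finite(ceiling)) stop("ceiling must be finite")
  w <- band_weights(bank, weights)
  structure(list(bank = bank, grid = grid, ceiling = ceiling, ec = ec,
                 weights = w, weights_kind = weights,
                 masker_duration = masker_duration, average = average),
            class = "model_config")
}

# ANSI S3.5-1997 one-third-octave band-importance function (speech),
# interpolated to the filterbank centres on a log-frequency axis and
# renormalised to sum to one.
sii_band_importance <- function() {
  list(f = c(160, 200, 250, 315, 400, 500, 630, 800, 1000, 1250, 1600,
             2000, 2500, 3150, 4000, 5000, 6300, 8000),
       w = c(0.0083, 0.0095, 0.0150, 0.0289, 0.0440, 0.0578, 0.0653,
             0.0711, 0.0818, 0.0844, 0.0882, 0.0898, 0.0868, 0.0844,
             0.0771, 0.0527, 0.0364, 0.0185))
}

#' Band-importance weights for a filterbank
#' @param bank a `gammatone_bank`
#' @param kind `"sii"` or `"uniform"`
#' @return numeric vector summing to 1
#' @export
band_weights <- function(bank, kind = c("sii", "uniform")) {
  kind <- match.arg(kind)
  if (kind == "uniform") return(rep(1 / bank$n_bands, bank$n_bands))
  tab <- sii_band_importance()
  w <- approx(log(tab$f), tab$w, xout = log(bank$fc), rule = 2)$y
  w / sum(w)
}

#' Long-term target statistics
#'
#' Per-band power at each ear and interaural phase of the target ear
#' signals, computed once over the whole signal. These time-invariant
#' statistics are later combined with the short-term interferer statistics,
#' so that target speech pauses cannot masquerade as intelligibility loss.
#'
#' @param target_ears `binaural_signal` of the target rendered to the ears
#' @param bank a `gammatone_bank`
#' @return object of class `target_stats` with vectors `power_l`, `power_r`,
#'   `phase` and `fc`
#' @export
target_stats <- function(target_ears, bank) {
  stopifnot(inherits(target_ears, "binaural_signal"))
  if (all(target_ears$left$samples == 0) && all(target_ears$right$samples == 0))
    stop("silent target")
  st <- interaural_stats(target_ears, bank, grid = "long-term")
  structure(list(power_l = st$power_l[, 1], power_r = st$power_r[, 1],
                 phase = st$phase[, 1], fc = bank$fc),
            class = "target_stats")
}

#' Better-ear target-to-interferer ratio
#'
#' Per band and frame, the larger of the two ears' ratios of long-term
#' target power to short-term interferer power (in dB), capped at
#' `ceiling`. Frames in which the interferer power is zero at both ears are
#' set to the ceiling (the cap exists precisely to bound such pauses);
#' bands with zero target power yield `-Inf`.
#'
#' @param ts [target_stats()]
#' @param fs interferer [interaural_stats()] on the same bank/grid
#' @param ceiling cap in dB
#' @return matrix `n_bands x n_frames` of better-ear ratios in dB
#' @export
better_ear <- function(ts, fs, ceiling = 20) {
  stopifnot(inherits(ts, "target_stats"), inherits(fs, "frame_stats"))
  if (length(ts$power_l) != nrow(fs$power_l))
    stop("target and interferer statistics use different banks")
  rl <- 10 * log10(ts$power_l / fs$power_l)
  rr <- 10 * log10(ts$power_r / fs$power_r)
  be <- pmax(rl, rr)
  be[fs$power_l == 0 & fs$power_r == 0] <- ceiling
  be[ts$power_l == 0 & ts$power_r == 0] <- -Inf
  pmin(be, ceiling)
}

#' Binaural unmasking advantage
#'
#' Equalization-cancellation BMLD expression per band and frame:
#' `BU = 10 log10( (k - cos(phi_T - phi_I)) / (k - rho) )` with
#' `k = (1 + sigma_eps^2) exp(omega^2 sigma_delta^2)`, `omega = 2 pi fc`,
#' `phi_T`/`phi_I` the target/interferer interaural phases and `rho` the
#' interferer interaural coherence. The advantage is set to zero whenever
#' the interferer power vanishes at either ear in a band and frame, and is
#' floored at 0 dB when `ec$floor_at_zero`.
#'
#' @param ts [target_stats()]
#' @param fs interferer [interaural_stats()]
#' @param ec [ec_parameters()]
#' @return matrix `n_bands x n_frames` of unmasking advantages in dB
#' @export
binaural_unmasking <- function(ts, fs, ec = ec_parameters()) {
  stopifnot(inherits(ts, "target_stats"), inherits(fs, "frame_stats"))
  if (length(ts$phase) != nrow(fs$phase))
    stop("target and interferer statistics use different banks")
  rho <- fs$coherence
  bad <- !is.na(rho) & (rho < 0 | rho > 1 + 1e-9)
  if (any(bad)) stop("coherence outside [0, 1]")
  rho <- pmin(rho, 1)
  k <- (1 + ec$sigma_eps^2) * exp((2 * pi * ts$fc)^2 * ec$sigma_delta^2)
  bu <- 10 * log10((k - cos(ts$phase - fs$phase)) / (k - rho))
  bu[fs$power_l == 0 | fs$power_r == 0] <- 0
  bu[is.na(bu)] <- 0
  if (ec$floor_at_zero) bu <- pmax(bu, 0)
  bu
}

#' Integrate band/frame components into the binaural ratio
#'
#' Per-frame broadband effective ratio = band-importance-weighted sum of
#' `BE + BU`; the scalar binaural ratio is the average across frames (in
#' the dB domain by default). The independently integrated `BE` and `BU`
#' components add up exactly to the binaural ratio.
#'
#' @param be,bu matrices from [better_ear()] / [binaural_unmasking()]
#' @param cfg a [model_config()]
#' @return object of class `model_output` with `ratio`, `be_component`,
#'   `bu_component` (dB scalars), `frame_ratio` (per frame), and the band
#'   means `band_be`, `band_bu`
#' @export
integrate_model <- function(be, bu, cfg) {
  if (nrow(be) != length(cfg$weights) || !all(dim(be) == dim(bu)))
    stop("band weights and component matrices do not match")
  w <- cfg$weights
  fr_be <- as.vector(crossprod(w, be))
  fr_bu <- as.vector(crossprod(w, bu))
  fr <- fr_be + fr_bu
  if (cfg$average == "db") {
    be_c <- mean(fr_be); bu_c <- mean(fr_bu); ratio <- mean(fr)
  } else {
    ratio <- 10 * log10(mean(10^(fr / 10)))
    be_c <- 10 * log10(mean(10^(fr_be / 10)))
    bu_c <- ratio - be_c
  }
  structure(list(ratio = ratio, be_component = be_c, bu_component = bu_c,
                 frame_ratio = fr, band_be = rowMeans(be), band_bu = rowMeans(bu),
                 n_frames = ncol(be), fc = cfg$bank$fc),
            class = "model_output")
}

#' @export
print.model_output <- function(x, ...) {
  cat(sprintf(paste0("<model_output> binaural ratio %.2f dB ",
                     "(better-ear %.2f + binaural unmasking %.2f), %d frame(s)\n"),
              x$ratio, x$be_component, x$bu_component, x$n_frames))
  invisible(x)
}

#' Predict one condition (short-term model)
#'
#' End-to-end wrapper: long-term target statistics once, short-term
#' interferer statistics over `cfg$masker_duration`, better-ear and
#' binaural-unmasking components, band and frame integration.
#'
#' @param rendering a [render_scene()] result (or any list with `target`
#'   and `interferer` `binaural_signal`s)
#' @param cfg a [model_config()]
#' @return a `model_output`
#' @export
predict_condition <- function(rendering, cfg = model_config()) {
  interferer <- rendering$interferer
  nmax <- round(cfg$masker_duration * interferer$rate)
  if (length(interferer$left$samples) > nmax) {
    interferer <- binaural_signal(
      mono_signal(interferer$left$samples[1:nmax], interferer$rate),
      mono_signal(interferer$right$samples[1:nmax], interferer$rate))
  }
  ts <- target_stats(rendering$target, cfg$bank)
  fs <- interaural_stats(interferer, cfg$bank, cfg$grid)
  integrate_model(better_ear(ts, fs, cfg$ceiling),
                  binaural_unmasking(ts, fs, cfg$ec), cfg)
}

#' Long-term model variant
#'
#' Identical computation with a single whole-signal frame: one long-term
#' interferer statistic instead of the short-time sequence. For stationary
#' interferers the two variants nearly coincide; fluctuating interferers
#' let the short-term model exploit masker dips.
#'
#' @inheritParams predict_condition
#' @export
long_term_model <- function(rendering, cfg = model_config()) {
  interferer <- rendering$interferer
  nmax <- round(cfg$masker_duration * interferer$rate)
  if (length(interferer$left$samples) > nmax) {
    interferer <- binaural_signal(
      mono_signal(interferer$left$samples[1:nmax], interferer$rate),
      mono_signal(interferer$right$samples[1:nmax], interferer$rate))
  }
  ts <- target_stats(rendering$target, cfg$bank)
  fs <- interaural_stats(interferer, cfg$bank, grid = "long-term")
  integrate_model(better_ear(ts, fs, cfg$ceiling),
                  binaural_unmasking(ts, fs, cfg$ec), cfg)
}

#' Predicted hearing-aid disadvantage
#'
#' Binaural ratios are inversely related to SRTs, so the predicted SRT
#' increase caused by the hearing aids is the unaided minus the aided
#' binaural ratio.
#'
#' @param aided,unaided `model_output`s for the two conditions
#' @return dB (positive = aids predicted to hurt intelligibility)
#' @export
ha_disadvantage <- function(aided, unaided) {
  unaided$ratio - aided$ratio
}

#' Predicted spatial release from masking
#'
#' Separated-minus-collocated binaural ratio; because better-ear and
#' unmasking components integrate independently, the release decomposes
#' exactly into a better-ear and a binaural-unmasking share.
#'
#' @param separated,collocated `model_output`s
#' @return list with `srm`, `be_share`, `bu_share` (dB)
#' @export
predicted_srm <- function(separated, collocated) {
  list(srm = separated$ratio - collocated$ratio,
       be_share = separated$be_component - collocated$be_component,
       bu_share = separated$bu_component - collocated$bu_component)
}
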