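# Shared fixtures, all generated in code under fixed seeds.

fixture_rate <- 44100

# small filterbank for fast unit tests
small_bank <- function() design_gammatone_bank(100, 4000, 2)

# delay a mono signal by an integer number of samples (zero-padded head)
delay_samples <- function(x, d) {
  mono_signal(c(numeric(d), x$samples[seq_len(length(x$samples) - d)]), x$rate)
}

# a synthetic exponentially decaying BRIR with a unit direct impulse
toy_brir <- function(azimuth = 0, scale_right = 1, rate = fixture_rate,
                     dur = 0.35, seed = 1) {
  n <- round(dur * rate)
  ir <- with_local_seed(seed, c(1, 0.05 * rnorm(n - 1) * exp(-(1:(n - 1)) / 2000)))
  structure(list(ir = binaural_signal(mono_signal(ir, rate),
                                      mono_signal(scale_right * ir, rate)),
                 azimuth = azimuth, distance = 1.3, aided = FALSE,
                 t30 = 0.2, rate = rate), class = "brir")
}

# identity (single-impulse, diotic) BRIR
identity_brir <- function(rate = fixture_rate) {
  imp <- mono_signal(c(1, numeric(31)), rate)
  structure(list(ir = binaural_signal(imp, imp), azimuth = 0, distance = 1.3,
                 aided = FALSE, t30 = 0, rate = rate), class = "brir")
}

# Schroeder-fitted T30 (-5 to -35 dB) of an impulse response vector
schroeder_t30 <- function(ir, rate) {
  e <- rev(cumsum(rev(ir^2)))
  db <- 10 * log10(e / e[1])
  t <- (seq_along(ir) - 1) / rate
  i5 <- which(db <= -5)[1]
  i35 <- which(db <= -35)[1]
  sl <- coef(lm(db[i5:i35] ~ t[i5:i35]))[2]
  -60 / sl
}

# anechoic diotic collocated rendering used by the model tests: target and
# three stationary SSN maskers through the frontal anechoic BRIR
diotic_scene <- function(duration = 20, seed = 40, t30 = 0) {
  cfg <- scene_config(t30 = t30, seed = seed)
  brirs <- condition_brirs(lapply(cfg$azimuths, function(a) simulate_brir(cfg, a)),
                           ltass_noise(10, seed = seed + 1))
  ref <- ltass_noise(10, seed = seed + 1)
  target <- generate_ssn(ref, duration + 1, seed = seed + 2)
  maskers <- lapply(seed + 3:5, function(s) generate_ssn(ref, duration + 1, seed = s))
  list(cfg = cfg, brirs = brirs, ref = ref, target = target, maskers = maskers)
}
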