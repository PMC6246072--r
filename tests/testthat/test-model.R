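# Better-ear / binaural-unmasking model components and their integration.

fake_target_stats <- function(power_l, power_r, phase, fc) {
  structure(list(power_l = power_l, power_r = power_r, phase = phase, fc = fc),
            class = "target_stats")
}
fake_frame_stats <- function(power_l, power_r, phase, coherence) {
  structure(list(power_l = power_l, power_r = power_r, phase = phase,
                 coherence = coherence, n_frames = ncol(power_l),
                 long_term = FALSE), class = "frame_stats")
}

test_that("binaural unmasking matches brute-force closed-form evaluation", {
  # independent oracle: scalar evaluation of the EC BMLD expression
  bmld_oracle <- function(f, phi_t, phi_i, rho,
                          se = 0.25, sd = 105e-6) {
    k <- (1 + se^2) * exp((2 * pi * f)^2 * sd^2)
    max(10 * log10((k - cos(phi_t - phi_i)) / (k - rho)), 0)
  }
  set.seed(101)
  n <- 1000
  f <- runif(n, 80, 10000)
  phi_t <- runif(n, -pi, pi)
  phi_i <- runif(n, -pi, pi)
  rho <- runif(n, 0, 1)
  got <- vapply(seq_len(n), function(i) {
    ts <- fake_target_stats(1, 1, phi_t[i], f[i])
    fs <- fake_frame_stats(matrix(1), matrix(1), matrix(phi_i[i]),
                           matrix(rho[i]))
    binaural_unmasking(ts, fs)[1, 1]
  }, numeric(1))
  want <- vapply(seq_len(n), function(i)
    bmld_oracle(f[i], phi_t[i], phi_i[i], rho[i]), numeric(1))
  expect_lt(max(abs(got - want)), 1e-9)

  # worked point: 500 Hz, antiphasic target in a coherent interferer
  ts <- fake_target_stats(1, 1, pi, 500)
  fs <- fake_frame_stats(matrix(1), matrix(1), matrix(0), matrix(1))
  expect_equal(binaural_unmasking(ts, fs)[1, 1], 10.73, tolerance = 0.005)
})

test_that("unmasking guards: identical phases, zero-power ears, bad rho", {
  ts <- fake_target_stats(1, 1, 0.3, 500)
  fs_same <- fake_frame_stats(matrix(1), matrix(1), matrix(0.3), matrix(1))
  expect_equal(binaural_unmasking(ts, fs_same)[1, 1], 0)

  fs_zero <- fake_frame_stats(matrix(0), matrix(1), matrix(0), matrix(1))
  expect_equal(binaural_unmasking(ts, fs_zero)[1, 1], 0)

  fs_bad <- fake_frame_stats(matrix(1), matrix(1), matrix(0), matrix(1.2))
  expect_error(binaural_unmasking(ts, fs_bad), "coherence")

  # depends only on the interaural phase difference
  off <- 1.1
  a <- binaural_unmasking(fake_target_stats(1, 1, 0.4, 700),
                          fake_frame_stats(matrix(1), matrix(1),
                                           matrix(-0.9), matrix(0.8)))
  b <- binaural_unmasking(fake_target_stats(1, 1, 0.4 + off, 700),
                          fake_frame_stats(matrix(1), matrix(1),
                                           matrix(-0.9 + off), matrix(0.8)))
  expect_equal(a, b, tolerance = 1e-12)

  # unfloored variant can go negative
  ec <- ec_parameters(floor_at_zero = FALSE)
  neg <- binaural_unmasking(fake_target_stats(1, 1, 0, 500),
                            fake_frame_stats(matrix(1), matrix(1),
                                             matrix(0), matrix(0.2)), ec)
  expect_lt(neg[1, 1], 0)
})

test_that("better-ear ratio picks the best ear and respects the ceiling", {
  ts <- fake_target_stats(1, 0.25, 0, 500)
  fs <- fake_frame_stats(matrix(0.01), matrix(0.25), matrix(0), matrix(1))
  expect_equal(better_ear(ts, fs, 20)[1, 1], 20)          # capped exactly

  fs2 <- fake_frame_stats(matrix(0.001), matrix(0.25), matrix(0), matrix(1))
  expect_equal(better_ear(ts, fs2, 20)[1, 1], 20)         # capped from 30
  expect_equal(better_ear(ts, fs2, 40)[1, 1], 30)

  fs3 <- fake_frame_stats(matrix(1), matrix(0.25), matrix(0), matrix(1))
  expect_equal(better_ear(ts, fs3, 20)[1, 1], 0)          # equal powers

  fs0 <- fake_frame_stats(matrix(0), matrix(0), matrix(NA_real_),
                          matrix(NA_real_))
  expect_equal(better_ear(ts, fs0, 20)[1, 1], 20)         # pause -> ceiling

  ts0 <- fake_target_stats(0, 0, 0, 500)
  expect_equal(better_ear(ts0, fs3, 20)[1, 1], -Inf)
})

test_that("integration is the weighted frame-averaged sum of components", {
  bank <- design_gammatone_bank(100, 4000, 2)
  cfg <- model_config(bank = bank, weights = "uniform", masker_duration = 1)
  nb <- bank$n_bands
  be <- matrix(3, nb, 10)
  bu <- matrix(1.5, nb, 10)
  out <- integrate_model(be, bu, cfg)
  expect_equal(out$ratio, 4.5)
  expect_equal(out$be_component, 3)
  expect_equal(out$bu_component, 1.5)
  expect_equal(out$ratio, out$be_component + out$bu_component)

  out2 <- integrate_model(be, matrix(0, nb, 10), cfg)
  expect_equal(out2$ratio, out2$be_component)

  expect_error(integrate_model(matrix(1, 3, 2), matrix(1, 3, 2), cfg),
               "do not match")

  w <- band_weights(bank, "sii")
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(w >= 0))
})

test_that("target statistics: diotic phase zero, delays and scaling behave", {
  bank <- small_bank()
  x <- white_noise(2, seed = 21)
  ts <- target_stats(binaural_signal(x, x), bank)
  expect_true(all(ts$phase == 0))

  d <- round(300e-6 * fixture_rate)
  tsd <- target_stats(binaural_signal(x, delay_samples(x, d)), bank)
  low <- which(bank$fc < 700)
  expect_equal(tsd$phase[low], 2 * pi * bank$fc[low] * d / fixture_rate,
               tolerance = 0.05)

  ts2 <- target_stats(binaural_signal(signal_scale(x, 2), signal_scale(x, 2)),
                      bank)
  expect_equal(ts2$power_l, 4 * ts$power_l, tolerance = 1e-9)
  expect_equal(ts2$phase, ts$phase)

  silent <- mono_signal(numeric(1000), fixture_rate)
  expect_error(target_stats(binaural_signal(silent, silent), bank), "silent")
})

test_that("doubling the interferer level costs 6 dB of binaural ratio", {
  sc <- diotic_scene(duration = 6, seed = 60)
  rend <- render_scene(sc$brirs, sc$target, sc$maskers, sc$cfg, "collocated")
  cfg <- model_config(masker_duration = 6)
  base <- predict_condition(rend, cfg)
  rend2 <- rend
  rend2$interferer <- signal_scale(rend$interferer, 2)
  louder <- predict_condition(rend2, cfg)
  expect_equal(base$ratio - louder$ratio, 6, tolerance = 0.3)
})

test_that("collocated scenes yield a null binaural-unmasking component", {
  # anechoic collocated rendering is diotic: BU exactly zero
  sc <- diotic_scene(duration = 6, seed = 61, t30 = 0)
  rend <- render_scene(sc$brirs, sc$target, sc$maskers, sc$cfg, "collocated")
  out <- predict_condition(rend, model_config(masker_duration = 6))
  expect_lt(abs(out$bu_component), 1e-9)

  # reverberant collocated rendering: small decorrelation only
  scr <- diotic_scene(duration = 10, seed = 62, t30 = 0.2)
  rr <- render_scene(scr$brirs, scr$target, scr$maskers, scr$cfg, "collocated")
  outr <- predict_condition(rr, model_config(masker_duration = 10))
  expect_lt(outr$bu_component, 0.2)
})

test_that("separated anechoic interferer unmasks in the low bands", {
  sc <- diotic_scene(duration = 6, seed = 63, t30 = 0)
  rend <- render_scene(sc$brirs, sc$target, sc$maskers, sc$cfg, "separated")
  cfg <- model_config(masker_duration = 6)
  out <- predict_condition(rend, cfg)
  low <- cfg$bank$fc < 1500
  expect_gt(mean(out$band_bu[low]), 0)
  expect_gt(out$bu_component, 0.2)
})

test_that("dip listening grows monotonically with modulation depth", {
  sc <- diotic_scene(duration = 10, seed = 64, t30 = 0)
  cfg <- model_config(masker_duration = 10)
  gaps <- vapply(c(0, 0.5, 1), function(depth) {
    maskers <- lapply(sc$cfg$seed + 3:5, function(s)
      generate_speechlike(sc$ref, 11, seed = s, mod_depth = depth))
    rend <- render_scene(sc$brirs, sc$target, maskers, sc$cfg, "collocated")
    st <- predict_condition(rend, cfg)
    lt <- long_term_model(rend, cfg)
    st$ratio - lt$ratio
  }, numeric(1))
  expect_true(all(gaps >= 0))          # short-term model never loses
  expect_true(all(diff(gaps) > 0))     # advantage grows with depth
})

test_that("model outputs are deterministic and the ceiling binds", {
  sc <- diotic_scene(duration = 4, seed = 65, t30 = 0)
  rend <- render_scene(sc$brirs, sc$target, sc$maskers, sc$cfg, "collocated")
  cfg <- model_config(masker_duration = 4)
  expect_identical(long_term_model(rend, cfg)$ratio,
                   long_term_model(rend, cfg)$ratio)

  ts <- target_stats(rend$target, cfg$bank)
  fs <- interaural_stats(rend$interferer, cfg$bank, cfg$grid)
  expect_lte(max(better_ear(ts, fs, cfg$ceiling)), cfg$ceiling)
})

test_that("disadvantage and release are pure differences of ratios", {
  a <- structure(list(ratio = 2, be_component = 1.5, bu_component = 0.5),
                 class = "model_output")
  b <- structure(list(ratio = 3.5, be_component = 2.5, bu_component = 1.0),
                 class = "model_output")
  expect_equal(ha_disadvantage(aided = a, unaided = b), 1.5)
  expect_equal(ha_disadvantage(aided = b, unaided = b), 0)
  s <- predicted_srm(separated = b, collocated = a)
  expect_equal(s$srm, 1.5)
  expect_equal(s$srm, s$be_share + s$bu_share)   # exact decomposition
})
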