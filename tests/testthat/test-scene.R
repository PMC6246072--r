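# Synthetic scene stage: Woodworth ITDs, image-source BRIRs, BTE transform,
# BRIR conditioning and scene rendering.

test_that("Woodworth ITD has the textbook values and symmetries", {
  expect_equal(itd_woodworth(0), 0)
  expect_equal(itd_woodworth(180), 0)
  # frozen from direct formula evaluation: (0.0875/343)*(pi/2 + 1)
  expect_equal(itd_woodworth(90), 6.558e-4, tolerance = 1e-3)
  expect_equal(itd_woodworth(-90), -itd_woodworth(90))
  expect_equal(itd_woodworth(120), itd_woodworth(60))   # front-back mirror
  expect_equal(itd_woodworth(270), itd_woodworth(-90))  # wrapping
})

test_that("anechoic BRIR carries the Woodworth delay and mirror symmetry", {
  cfg <- scene_config(t30 = 0, seed = 2)
  fs <- cfg$rate
  b90 <- simulate_brir(cfg, 90)
  itd <- binratio:::cross_corr_itd(b90$ir$left$samples, b90$ir$right$samples, fs)
  expect_lt(abs(itd - itd_woodworth(90)), 1 / fs)

  # direct sound only: a single sinc cluster per ear
  el <- b90$ir$left$samples^2
  expect_gt(sum(el[1:(round(0.006 * fs))]) / sum(el), 0.999)

  bm <- simulate_brir(cfg, -90)
  expect_equal(b90$ir$left$samples, bm$ir$right$samples, tolerance = 1e-12)
  expect_equal(b90$ir$right$samples, bm$ir$left$samples, tolerance = 1e-12)

  b0 <- simulate_brir(cfg, 0)
  expect_equal(b0$ir$left$samples, b0$ir$right$samples, tolerance = 1e-12)
})

test_that("reverberant BRIR meets the configured T30 within 20%", {
  cfg <- scene_config(t30 = 0.2, seed = 5)
  b <- simulate_brir(cfg, 90)
  for (ch in list(b$ir$left$samples, b$ir$right$samples)) {
    t30 <- schroeder_t30(ch, cfg$rate)
    expect_gt(t30, 0.16)
    expect_lt(t30, 0.24)
  }
  expect_identical(simulate_brir(cfg, 90)$ir$left$samples,
                   b$ir$left$samples)   # seeded reproducibility
})

test_that("head shadow creates frequency-growing ILD for lateral sources", {
  cfg <- scene_config(t30 = 0, seed = 2)
  bank <- design_gammatone_bank(200, 10000, 2)
  ssn <- generate_ssn(ltass_noise(10, seed = 1), 4, seed = 2)
  b90 <- simulate_brir(cfg, 90)
  ears <- binaural_signal(
    mono_signal(binratio:::fft_conv(ssn$samples, b90$ir$left$samples), cfg$rate),
    mono_signal(binratio:::fft_conv(ssn$samples, b90$ir$right$samples), cfg$rate))
  sp <- ear_spectra(ears, bank)
  ild <- sp$level_l - sp$level_r
  lo <- mean(ild[bank$fc < 500])
  hi <- mean(ild[bank$fc > 4000])
  expect_lt(hi, lo - 5)          # right-side source: shadow cuts left at HF
  expect_lt(abs(lo), 2)
})

test_that("scene geometry errors are caught", {
  expect_error(scene_config(listener = c(10, 10, 10)), "inside the room")
  expect_error(scene_config(radius = -1), "radius")
  cfg <- scene_config(room = c(2.6, 2.6, 2.5), radius = 1.35)
  expect_error(simulate_brir(cfg, 0), "ring")
})

test_that("BTE transform boosts lateral high-frequency ILD by ~5 dB and
           compresses ITD by the configured factor", {
  cfg <- scene_config(seed = 5)
  fs <- cfg$rate
  bank <- design_gammatone_bank(100, 10000, 2)
  ssn <- generate_ssn(ltass_noise(10, seed = 1), 4, seed = 2)
  rend <- function(brir) binaural_signal(
    mono_signal(binratio:::fft_conv(ssn$samples, brir$ir$left$samples), fs),
    mono_signal(binratio:::fft_conv(ssn$samples, brir$ir$right$samples), fs))

  b90 <- simulate_brir(cfg, 90)
  a90 <- apply_bte_transform(b90)
  pu <- cue_profile(rend(b90), bank)
  pa <- cue_profile(rend(a90), bank)
  expect_equal(abs(pa$ild_above_2k) - abs(pu$ild_above_2k), 5, tolerance = 0.5)
  expect_lte(abs(pa$itd_summary), abs(pu$itd_summary))

  itd_u <- binratio:::cross_corr_itd(b90$ir$left$samples, b90$ir$right$samples, fs)
  itd_a <- binratio:::cross_corr_itd(a90$ir$left$samples, a90$ir$right$samples, fs)
  expect_lt(abs(itd_a - 0.9 * itd_u), 1 / fs)

  # frontal source: broadband ILD essentially unchanged
  b0 <- simulate_brir(cfg, 0)
  a0 <- apply_bte_transform(b0)
  ild_u <- 20 * log10(signal_rms(b0$ir$left) / signal_rms(b0$ir$right))
  ild_a <- 20 * log10(signal_rms(a0$ir$left) / signal_rms(a0$ir$right))
  expect_lt(abs(ild_a - ild_u), 1)

  # ear-canal resonance region attenuated re the flat insertion gain
  eu <- ear_spectra(rend(b0), bank, average = "ears")
  ea <- ear_spectra(rend(a0), bank, average = "ears")
  notch <- bank$fc > 2000 & bank$fc < 3000
  mid <- bank$fc > 700 & bank$fc < 1300
  gain_notch <- mean(ea$level[notch] - eu$level[notch])
  gain_mid <- mean(ea$level[mid] - eu$level[mid])
  expect_lt(gain_notch, gain_mid - 4)
  expect_equal(gain_mid, 10, tolerance = 1)     # flat insertion gain

  expect_error(apply_bte_transform(a90), "twice")
  expect_true(a90$aided)
  expect_equal(length(a90$ir$left$samples), length(b90$ir$left$samples))
})

test_that("conditioning truncates to 300 ms and balances the direct sound", {
  fs <- fixture_rate
  ref <- ltass_noise(10, seed = 1)

  unbal <- toy_brir(azimuth = 0, scale_right = 2)
  cb <- condition_brirs(list(unbal), ref)
  expect_equal(attr(cb, "correction"), 0.5, tolerance = 1e-9)
  expect_equal(signal_duration(cb[[1]]$ir), 0.3)
  expect_equal(signal_rms(cb[[1]]$ir$right) / signal_rms(cb[[1]]$ir$left), 1,
               tolerance = 1e-9)

  bal <- toy_brir(azimuth = 0, scale_right = 1)
  cb2 <- condition_brirs(list(bal), ref)
  expect_equal(attr(cb2, "correction"), 1, tolerance = 1e-6)

  expect_error(condition_brirs(list(toy_brir(azimuth = 90)), ref), "frontal")
})

test_that("rendering through an identity BRIR returns the calibrated input", {
  fs <- fixture_rate
  cfg <- scene_config(t30 = 0)
  ref <- ltass_noise(10, seed = 1)
  target <- white_noise(2, fs, seed = 9)
  maskers <- lapply(1:3, function(s) generate_ssn(ref, 2, seed = s))
  r <- render_scene(list(identity_brir()), target, maskers, cfg,
                    layout = "collocated")
  expected <- target$samples * cfg$masker_rms / signal_rms(target)
  n <- length(expected)
  expect_equal(r$target$left$samples[1:n], expected, tolerance = 1e-12)
  expect_equal(r$target$left$samples, r$target$right$samples)
  # summed interferer power matches a direct-summation oracle
  feeds <- maskers
  aw <- vapply(feeds, binratio:::a_weighted_rms, numeric(1))
  feeds <- Map(function(m, w) m$samples * mean(aw) / w, feeds, aw)
  tot <- sqrt(sum(vapply(feeds, function(s) mean(s^2), numeric(1))))
  oracle <- Reduce(`+`, feeds) * cfg$masker_rms / tot
  expect_equal(r$interferer$left$samples[1:n], oracle[1:n], tolerance = 1e-9)
  expect_equal(signal_rms(r$interferer$left), cfg$masker_rms, tolerance = 0.02)
})

test_that("aided playback attenuation scales all feeds by -10 dB", {
  cfg_u <- scene_config(t30 = 0)
  cfg_a <- scene_config(t30 = 0, aided = TRUE)
  ref <- ltass_noise(10, seed = 1)
  target <- white_noise(1, seed = 9)
  maskers <- lapply(1:3, function(s) generate_ssn(ref, 1, seed = s))
  ru <- render_scene(list(identity_brir()), target, maskers, cfg_u, "collocated")
  ra <- render_scene(list(identity_brir()), target, maskers, cfg_a, "collocated")
  expect_equal(ra$target$left$samples,
               10^(-10 / 20) * ru$target$left$samples, tolerance = 1e-12)
  expect_equal(ra$interferer$left$samples,
               10^(-10 / 20) * ru$interferer$left$samples, tolerance = 1e-12)
})

test_that("separated rendering demands one BRIR per masker azimuth", {
  cfg <- scene_config(t30 = 0)
  ref <- ltass_noise(10, seed = 1)
  maskers <- lapply(1:3, function(s) generate_ssn(ref, 0.5, seed = s))
  expect_error(render_scene(list(identity_brir()), white_noise(0.5, seed = 1),
                            maskers, cfg, layout = "separated"),
               "one BRIR per masker")
})

test_that("BRIR sets round-trip through WAV + JSON bundles", {
  cfg <- scene_config(t30 = 0, seed = 3)
  brirs <- lapply(c(0, 90), function(a) simulate_brir(cfg, a))
  dir <- tempfile()
  write_brir_set(brirs, dir)
  back <- read_brir_set(dir)
  expect_equal(length(back), 2L)
  expect_equal(back[[2]]$azimuth, 90)
  expect_equal(back[[1]]$ir$left$samples, brirs[[1]]$ir$left$samples,
               tolerance = 1e-6)
  expect_equal(back[[1]]$rate, cfg$rate)
  unlink(dir, recursive = TRUE)
})
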