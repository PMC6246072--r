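#' Spherical head model for synthetic binaural cues
#'
#' Stands in for a head-and-torso simulator: Woodworth ITDs from a rigid
#' sphere plus a first-order high-shelf head-shadow cut at the contralateral
#' ear whose depth grows with |sin(azimuth)|.
#'
#' @param radius head radius in metres
#' @param c speed of sound in m/s
#' @param shadow_depth maximum high-frequency shadow attenuation in dB
#'   (reached for a source at +-90 degrees)
#' @param shadow_corner shelf corner frequency in Hz
#' @export
head_model <- function(radius = 0.0875, c = 343, shadow_depth = 12,
                       shadow_corner = 1500) {
  structure(list(radius = radius, c = c, shadow_depth = shadow_depth,
                 shadow_corner = shadow_corner), class = "head_model")
}

#' Woodworth interaural time difference
#'
#' `ITD = (a/c) * (theta + sin(theta))` for a rigid sphere of radius `a`,
#' with `theta` the lateral angle in radians. Sources behind the listener
#' mirror the frontal value (front-back symmetric); the sign follows the
#' azimuth convention: 0 deg front, positive clockwise (to the right),
#' range (-180, 180]. Positive ITD means the left ear lags (source on the
#' right).
#'
#' @param azimuth source azimuth in degrees
#' @param head a [head_model()]
#' @return ITD in seconds
#' @export
itd_woodworth <- function(azimuth, head = head_model()) {
  az <- ((azimuth + 180) %% 360) - 180
  th <- abs(az)
  th <- ifelse(th > 90, 180 - th, th) * pi / 180
  sign(az) * (head$radius / head$c) * (th + sin(th))
}

#' Acoustic scene configuration
#'
#' Describes the synthetic listening room and playback geometry: a ring of
#' sources at 1.3 m around the listener (0, +90, -90, 180 degrees), room
#' reverberation time T30 of 0.2 s, and the aided playback scheme (flat
#' 10-dB insertion gain in the hearing-aid path, loudspeaker feeds reduced
#' by 10 dB so the presentation level stays approximately constant).
#'
#' @param room room dimensions (x, y, z) in metres
#' @param t30 target reverberation time in seconds; 0 gives an anechoic room
#' @param radius source ring radius in metres
#' @param azimuths source azimuths in degrees
#' @param listener listener position (x, y, z) in metres; default room centre
#'   at ear height 1.2 m
#' @param aided logical: hearing-aid condition
#' @param insertion_gain flat hearing-aid insertion gain in dB
#' @param playback_attenuation dB applied to all loudspeaker feeds when aided
#' @param masker_rms digital RMS reference for the summed maskers
#'   (default 10^(-25/20), i.e. -25 dBFS)
#' @param rate sampling rate in Hz
#' @param seed integer seed for reflection jitter
#' @param head a [head_model()]
#' @export
scene_config <- function(room = c(6, 5, 3), t30 = 0.2, radius = 1.3,
                         azimuths = c(0, 90, -90, 180),
                         listener = c(room[1] / 2, room[2] / 2, 1.2),
                         aided = FALSE, insertion_gain = 10,
                         playback_attenuation = if (aided) 10 else 0,
                         masker_rms = 10^(-25 / 20),
                         rate = 44100, seed = 1, head = head_model()) {
  if (radius <= 0) stop("radius must be positive")
  if (t30 < 0) stop("t30 must be >= 0")
  if (any(listener <= 0) || any(listener >= room))
    stop("listener must be inside the room")
  structure(list(room = room, t30 = t30, radius = radius,
                 azimuths = azimuths, listener = listener, aided = aided,
                 insertion_gain = insertion_gain,
                 playback_attenuation = playback_attenuation,
                 masker_rms = masker_rms, rate = rate, seed = seed,
                 head = head), class = "scene_config")
}

# First-order high-shelf filter (unity low-frequency gain, `gain_db` at high
# frequencies, corner `fc`), applied via bilinear transform.
high_shelf <- function(x, gain_db, fc, rate) {
  G <- 10^(gain_db / 20)
  k <- tan(pi * fc / rate)
  b <- c(1 + G / k, 1 - G / k) / (1 + 1 / k)
  a <- c(1, (1 - 1 / k) / (1 + 1 / k))
  as.numeric(signal::filter(b, a, x))
}

# Frequency-independent wall reflectance calibrated on the enumerated image
# set. The image-source field does not decay at exactly the Eyring rate
# (late energy is dominated by grazing, low-reflection-order directions),
# so instead of a closed-form absorption we root-find the reflectance beta
# such that a Schroeder backward integration over the actual arrivals
# (energy beta^(2n)/d^2 at time d/c), fitted between -5 and -35 dB, yields
# the target T30.
calibrate_reflectance <- function(t, refl, d, t30, dur) {
  grid <- seq(0, dur, by = 1e-3)
  bin <- findInterval(t, grid)
  fitted <- function(beta) {
    e <- rowsum(beta^(2 * refl) / d^2, bin)
    env <- numeric(length(grid))
    env[as.integer(rownames(e))] <- e[, 1]
    s <- rev(cumsum(rev(env)))
    db <- 10 * log10(s / s[1])
    i5 <- which(db <= -5)[1]
    i35 <- which(db <= -35)[1]
    # the -35 dB point must fall well before the truncation edge, where the
    # backward integral collapses and the fit is meaningless
    if (is.na(i35) || grid[i35] > 0.8 * dur) return(1e9)
    if (i35 <= i5 + 1) return(0)         # decays within two bins
    -60 * (grid[i35] - grid[i5]) / (db[i35] - db[i5])
  }
  uniroot(function(b) fitted(b) - t30, c(0.2, 0.995), tol = 1e-4)$root
}
inject_impulses <- function(n, times, amps, rate) {
  v <- numeric(n)
  if (length(times) == 0) return(v)
  pos <- times * rate
  base <- floor(pos)
  frac <- pos - base
  for (k in -3:4) {
    u <- k - frac
    w <- ifelse(abs(u) < 4,
                ifelse(u == 0, 1, sin(pi * u) / (pi * u)) *
                  (0.5 + 0.5 * cos(pi * u / 4)),
                0)
    idx <- base + k + 1L
    ok <- idx >= 1L & idx <= n & w != 0
    if (any(ok)) {
      s <- rowsum((amps * w)[ok], idx[ok])
      v[as.integer(rownames(s))] <- v[as.integer(rownames(s))] + s[, 1]
    }
  }
  v
}

#' Simulate a binaural room impulse response
#'
#' Image-source simulation with frequency-independent wall absorption chosen
#' from the configured T30 via Eyring's formula. Each arrival is rendered
#' with the Woodworth ITD of its direction and a head-shadow high-shelf cut
#' at the contralateral ear (depth scaled by |sin(azimuth)|). Reflection
#' arrival times receive a small seeded jitter to avoid the sparse regular
#' echo lattice of an ideal rectangular room. `t30 = 0` yields the direct
#' sound only.
#'
#' @param cfg a [scene_config()]
#' @param azimuth source azimuth in degrees (source placed on the ring)
#' @return object of class `brir`: fields `ir` (a `binaural_signal`),
#'   `azimuth`, `distance`, `aided`, `t30`
#' @export
simulate_brir <- function(cfg, azimuth) {
  stopifnot(inherits(cfg, "scene_config"))
  rate <- cfg$rate
  head <- cfg$head
  L <- cfg$listener
  az <- ((azimuth + 180) %% 360) - 180
  src <- c(L[1] + cfg$radius * cos(az * pi / 180),
           L[2] - cfg$radius * sin(az * pi / 180),
           L[3])
  if (any(src <= 0) || any(src >= cfg$room))
    stop("source ring does not fit inside the room")

  dur <- 0.35                                   # raw length before conditioning
  n <- round(dur * rate)
  cs <- head$c

  # direct path
  d0 <- sqrt(sum((src - L)^2))
  direct <- list(t = d0 / cs, amp = 1 / d0, az = az)

  arrivals <- data.frame(t = direct$t, amp = direct$amp, az = direct$az)
  if (cfg$t30 > 0) {
    dmax <- cs * dur
    nx <- ceiling(dmax / (2 * cfg$room[1]))
    ny <- ceiling(dmax / (2 * cfg$room[2]))
    nz <- ceiling(dmax / (2 * cfg$room[3]))
    g <- expand.grid(mx = -nx:nx, my = -ny:ny, mz = -nz:nz,
                     px = 0:1, py = 0:1, pz = 0:1)
    ix <- (1 - 2 * g$px) * src[1] + 2 * g$mx * cfg$room[1]
    iy <- (1 - 2 * g$py) * src[2] + 2 * g$my * cfg$room[2]
    iz <- (1 - 2 * g$pz) * src[3] + 2 * g$mz * cfg$room[3]
    refl <- abs(g$mx - g$px) + abs(g$mx) + abs(g$my - g$py) + abs(g$my) +
      abs(g$mz - g$pz) + abs(g$mz)
    dx <- ix - L[1]; dy <- iy - L[2]; dz <- iz - L[3]
    d <- sqrt(dx^2 + dy^2 + dz^2)
    keep <- refl >= 1 & d <= dmax
    if (any(keep)) {
      beta <- calibrate_reflectance(c(direct$t, d[keep] / cs),
                                    c(0, refl[keep]), c(d0, d[keep]),
                                    cfg$t30, dur)
      # jitter decorrelates the regular echo lattice; random polarity keeps
      # the dense late field incoherent so arrival energies add
      rng <- with_local_seed(cfg$seed + round(10 * abs(az)), {
        list(jit = runif(sum(keep), -2e-4, 2e-4),
             sgn = sample(c(-1, 1), sum(keep), replace = TRUE))
      })
      arrivals <- rbind(arrivals, data.frame(
        t = pmax(d[keep] / cs + rng$jit, direct$t),
        amp = rng$sgn * beta^refl[keep] / d[keep],
        az = atan2(-dy[keep], dx[keep]) * 180 / pi))
    }
  }

  # group arrivals into azimuth bins; per bin apply ITD per arrival and the
  # shadow shelf once per contralateral ear
  binw <- 10
  bins <- round(arrivals$az / binw)
  left <- numeric(n); right <- numeric(n)
  for (b in unique(bins)) {
    sel <- bins == b
    az_b <- b * binw
    itd <- itd_woodworth(arrivals$az[sel], head)
    tl <- arrivals$t[sel] + itd / 2
    tr <- arrivals$t[sel] - itd / 2
    el <- inject_impulses(n, tl, arrivals$amp[sel], rate)
    er <- inject_impulses(n, tr, arrivals$amp[sel], rate)
    depth <- head$shadow_depth * abs(sin(az_b * pi / 180))
    if (depth > 0.01) {
      if (az_b > 0) el <- high_shelf(el, -depth, head$shadow_corner, rate)
      else er <- high_shelf(er, -depth, head$shadow_corner, rate)
    }
    left <- left + el
    right <- right + er
  }

  structure(list(ir = binaural_signal(mono_signal(left, rate),
                                      mono_signal(right, rate)),
                 azimuth = az, distance = cfg$radius, aided = FALSE,
                 t30 = cfg$t30, rate = rate),
            class = "brir")
}

#' @export
print.brir <- function(x, ...) {
  cat(sprintf("<brir> azimuth %g deg, %.2f m, %s, %.0f ms @ %g Hz\n",
              x$azimuth, x$distance, if (x$aided) "aided" else "unaided",
              1000 * signal_duration(x$ir), x$rate))
  invisible(x)
}

#' Behind-the-ear microphone transform
#'
#' Emulates the measured acoustic effect of listening through BTE
#' hearing-aid microphones: loss of the 2-3 kHz ear-canal resonance (a
#' configurable notch), a high-frequency ILD boost for lateral sources
#' (the head baffles the above-pinna microphones), slightly compressed
#' ITDs, a mild high-frequency energy loss, and the flat insertion gain.
#'
#' @param notch_depth ear-canal-resonance removal depth in dB
#' @param notch_freq notch centre in Hz
#' @param notch_width notch width (Gaussian sigma) in octaves
#' @param ild_boost high-frequency ILD increase in dB for sources with
#'   |azimuth| >= 45 degrees
#' @param ild_corner frequency above which the boost applies, Hz
#' @param itd_scale multiplicative ITD compression factor (<= 1)
#' @param insertion_gain flat gain in dB
#' @param hf_loss additional high-frequency loss in dB reached at 10 kHz
#'   (applied to both ears)
#' @export
bte_transform <- function(notch_depth = 8, notch_freq = 2500,
                          notch_width = 0.5, ild_boost = 5,
                          ild_corner = 2000, itd_scale = 0.9,
                          insertion_gain = 10, hf_loss = 2) {
  if (itd_scale > 1) stop("itd_scale must be <= 1")
  structure(list(notch_depth = notch_depth, notch_freq = notch_freq,
                 notch_width = notch_width, ild_boost = ild_boost,
                 ild_corner = ild_corner, itd_scale = itd_scale,
                 insertion_gain = insertion_gain, hf_loss = hf_loss),
            class = "bte_transform")
}

# ITD of a binaural impulse response / signal pair by interaural
# cross-correlation over +-lag_max; positive = left lags (source right).
cross_corr_itd <- function(left, right, rate, lag_max = 1e-3) {
  lm <- round(lag_max * rate)
  n <- length(left)
  cc <- vapply(-lm:lm, function(lag) {
    if (lag >= 0) sum(left[(1 + lag):n] * right[1:(n - lag)])
    else sum(left[1:(n + lag)] * right[(1 - lag):n])
  }, numeric(1))
  # order by |lag| so ties resolve to the smaller magnitude
  lags <- -lm:lm
  o <- order(abs(lags), lags)
  (lags[o])[which.max(cc[o])] / rate
}

#' Apply the BTE transform to a BRIR
#'
#' Magnitude shaping (notch, ILD boost, high-frequency loss, insertion
#' gain) is applied zero-phase in the frequency domain; the ITD compression
#' is applied as a fractional-delay phase ramp that advances the lagging
#' ear by `(1 - itd_scale) * ITD`, where the ITD is estimated from the
#' unaided response by interaural cross-correlation. Applying the transform
#' to an already-aided BRIR is an error.
#'
#' @param brir an unaided `brir`
#' @param t a [bte_transform()]
#' @return an aided `brir` of the same length and rate
#' @export
apply_bte_transform <- function(brir, t = bte_transform()) {
  stopifnot(inherits(brir, "brir"), inherits(t, "bte_transform"))
  if (brir$aided) stop("BRIR is already aided; transform cannot be applied twice")
  rate <- brir$rate
  l <- brir$ir$left$samples
  r <- brir$ir$right$samples
  n <- length(l)
  nfft <- next_pow2(2 * n)
  f <- (0:(nfft / 2)) * rate / nfft

  smoothstep <- function(f, lo, hi) {
    u <- (log(pmax(f, 1)) - log(lo)) / (log(hi) - log(lo))
    u <- pmin(pmax(u, 0), 1)
    u * u * (3 - 2 * u)
  }
  g_common <- -t$notch_depth *
    exp(-(log2(pmax(f, 1) / t$notch_freq))^2 / (2 * t$notch_width^2)) -
    t$hf_loss * smoothstep(f, 4000, 10000) + t$insertion_gain
  boost <- t$ild_boost * smoothstep(f, 0.95 * t$ild_corner, 1.05 * t$ild_corner)

  lateral <- abs(brir$azimuth) >= 45
  g_l <- g_common + if (lateral && brir$azimuth < 0) boost else 0
  g_r <- g_common + if (lateral && brir$azimuth > 0) boost else 0

  itd <- cross_corr_itd(l, r, rate)
  delta <- (1 - t$itd_scale) * itd          # advance left by delta

  shape <- function(x, gain_db, advance) {
    X <- fft(c(x, numeric(nfft - n)))
    half <- 10^(gain_db / 20) * exp(2i * pi * f * advance)
    full <- c(half, Conj(rev(half[2:(nfft / 2)])))
    Re(fft(X * full, inverse = TRUE))[1:n] / nfft
  }
  out <- brir
  out$ir <- binaural_signal(mono_signal(shape(l, g_l, delta), rate),
                            mono_signal(shape(r, g_r, 0), rate))
  out$aided <- TRUE
  out$transform <- t
  out
}

#' Truncate and balance a BRIR set
#'
#' All responses are truncated to 300 ms. The first 3.85 ms of the frontal
#' (0 degree) response -- the direct sound before the first room reflection
#' -- are filtered with the long-term magnitude spectrum of the target
#' speech; a single scalar correction is then applied to the right-ear
#' channel of every BRIR in the set so that the two ears' filtered
#' direct-sound RMS match.
#'
#' @param brirs list of `brir` objects, containing the frontal (0 deg) one
#' @param target_ref `mono_signal` providing the target spectrum
#' @return list of conditioned `brir`s, with the applied right-ear factor in
#'   `attr(, "correction")`
#' @export
condition_brirs <- function(brirs, target_ref) {
  stopifnot(is.list(brirs), inherits(target_ref, "mono_signal"))
  azs <- vapply(brirs, function(b) b$azimuth, numeric(1))
  i0 <- which(azs == 0)
  if (length(i0) == 0) stop("the set must contain the frontal (0 deg) BRIR")
  rate <- brirs[[1]]$rate
  n300 <- round(0.3 * rate)
  trunc1 <- function(x) mono_signal(head(x$samples, n300), rate)

  front <- brirs[[i0[1]]]
  nd <- round(0.00385 * rate)
  spec_filter <- function(seg) {
    nfft <- 4096
    p <- welch_psd(target_ref, 2048)
    mag <- sqrt(p)
    fgrid <- (0:(nfft / 2)) * rate / nfft
    fref <- (0:1024) * rate / 2048
    m <- approx(fref, mag, xout = fgrid, rule = 2)$y
    X <- fft(c(seg, numeric(nfft - length(seg))))
    full <- c(m, rev(m[2:(nfft / 2)]))
    Re(fft(X * full, inverse = TRUE)) / nfft
  }
  rl <- sqrt(mean(spec_filter(head(front$ir$left$samples, nd))^2))
  rr <- sqrt(mean(spec_filter(head(front$ir$right$samples, nd))^2))
  corr <- rl / rr

  out <- lapply(brirs, function(b) {
    b$ir <- binaural_signal(trunc1(b$ir$left),
                            signal_scale(trunc1(b$ir$right), corr))
    b
  })
  attr(out, "correction") <- corr
  out
}

# A-weighted RMS via closed-form A-curve applied to the FFT power spectrum.
a_weighted_rms <- function(x) {
  s <- x$samples
  nfft <- next_pow2(length(s))
  f <- (0:(nfft / 2)) * x$rate / nfft
  ra <- (12194^2 * f^4) /
    ((f^2 + 20.6^2) * sqrt((f^2 + 107.7^2) * (f^2 + 737.9^2)) * (f^2 + 12194^2))
  ra <- ra * 10^(2 / 20)
  X <- fft(c(s, numeric(nfft - length(s))))
  p <- abs(X[1:(nfft / 2 + 1)])^2
  p[2:(nfft / 2)] <- 2 * p[2:(nfft / 2)]
  sqrt(sum(p * ra^2) / (nfft * length(s)))
}

#' Render a scene: target ears and summed-interferer ears
#'
#' Convolves the target with the frontal BRIR and each masker with its
#' source BRIR (in `collocated` layout every masker uses the frontal BRIR,
#' as when all maskers play from the target loudspeaker), returning the two
#' model inputs: the target ear signals and the sum of all masker ear
#' signals. Maskers are first equalised to a common A-weighted power and
#' the summed masker scaled to the scene's digital reference level
#' (`cfg$masker_rms`); the target feed is set to the same total RMS, so
#' broadband source-side SNR is 0 dB. When `cfg$aided`, all loudspeaker
#' feeds are attenuated by `cfg$playback_attenuation` dB before convolution.
#'
#' @param brirs list of `brir`s covering the needed azimuths (frontal plus,
#'   for separated layout, one per masker azimuth)
#' @param target `mono_signal` target feed
#' @param maskers list of `mono_signal` masker feeds
#' @param cfg a [scene_config()]
#' @param layout `"separated"` (maskers at the non-zero azimuths of
#'   `cfg$azimuths`, in order) or `"collocated"`
#' @return object of class `scene_rendering`: `target` and `interferer`
#'   `binaural_signal`s
#' @export
render_scene <- function(brirs, target, maskers, cfg,
                         layout = c("separated", "collocated")) {
  layout <- match.arg(layout)
  stopifnot(inherits(target, "mono_signal"), is.list(maskers))
  azs <- vapply(brirs, function(b) b$azimuth, numeric(1))
  i0 <- which(azs == 0)
  if (length(i0) == 0) stop("frontal BRIR required for the target")
  masker_azs <- setdiff(cfg$azimuths, 0)
  if (layout == "separated") {
    idx <- match(((masker_azs + 180) %% 360) - 180, azs)
    if (anyNA(idx) || length(maskers) != length(idx))
      stop("need one BRIR per masker azimuth and one masker per loudspeaker")
  } else {
    idx <- rep(i0[1], length(maskers))
  }

  aw <- vapply(maskers, a_weighted_rms, numeric(1))
  feeds <- Map(function(m, w) signal_scale(m, mean(aw) / w), maskers, aw)
  tot <- sqrt(sum(vapply(feeds, function(m) mean(m$samples^2), numeric(1))))
  feeds <- lapply(feeds, signal_scale, factor = cfg$masker_rms / tot)
  tgt <- signal_scale(target, cfg$masker_rms / signal_rms(target))

  att <- 10^(-cfg$playback_attenuation / 20)
  if (cfg$aided && cfg$playback_attenuation != 0) {
    feeds <- lapply(feeds, signal_scale, factor = att)
    tgt <- signal_scale(tgt, att)
  }

  conv_bin <- function(x, brir) {
    binaural_signal(
      mono_signal(fft_conv(x$samples, brir$ir$left$samples), x$rate),
      mono_signal(fft_conv(x$samples, brir$ir$right$samples), x$rate))
  }
  target_ears <- conv_bin(tgt, brirs[[i0[1]]])
  masker_ears <- Map(function(m, i) conv_bin(m, brirs[[i]]), feeds, idx)
  nmin <- min(vapply(masker_ears, function(b) length(b$left$samples), numeric(1)))
  sl <- Reduce(`+`, lapply(masker_ears, function(b) b$left$samples[1:nmin]))
  sr <- Reduce(`+`, lapply(masker_ears, function(b) b$right$samples[1:nmin]))

  structure(list(target = target_ears,
                 interferer = binaural_signal(mono_signal(sl, cfg$rate),
                                              mono_signal(sr, cfg$rate)),
                 layout = layout, aided = cfg$aided, rate = cfg$rate),
            class = "scene_rendering")
}

#' Write a BRIR set as WAV files with a JSON sidecar
#' @param brirs list of `brir`s
#' @param dir output directory (created if needed)
#' @export
write_brir_set <- function(brirs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- lapply(seq_along(brirs), function(i) {
    b <- brirs[[i]]
    fn <- sprintf("brir_%03d.wav", i)
    write_wav(b$ir, file.path(dir, fn), bits = 32)
    list(file = fn, azimuth = b$azimuth, distance = b$distance,
         aided = b$aided, t30 = b$t30, rate = b$rate)
  })
  jsonlite::write_json(meta, file.path(dir, "brirs.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a BRIR set written by [write_brir_set()]
#' @param dir directory containing `brirs.json`
#' @export
read_brir_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "brirs.json"))
  lapply(meta, function(m) {
    structure(list(ir = read_wav(file.path(dir, m$file)),
                   azimuth = m$azimuth, distance = m$distance,
                   aided = m$aided, t30 = m$t30, rate = m$rate),
              class = "brir")
  })
}
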