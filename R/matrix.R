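#' Idealised speech-spectrum reference noise
#'
#' Stationary noise with a long-term-average-speech-shaped spectrum
#' (flat from 100 to 500 Hz, falling 9 dB per octave above), used as the
#' synthetic stand-in for an interfering-talker recording when deriving
#' speech-shaped noise.
#'
#' @inheritParams white_noise
#' @export
ltass_noise <- function(duration, rate = 44100, seed = 1) {
  n <- round(duration * rate)
  x <- with_local_seed(seed, rnorm(n))
  nfft <- next_pow2(n)
  f <- c(0, seq_len(nfft - 1)) * rate / nfft
  f[f > rate / 2] <- rate - f[f > rate / 2]
  g <- ifelse(f < 100, (pmax(f, 1) / 100)^2, 1)        # soft low cut
  hi <- f > 500
  g[hi] <- 10^(-9 / 20 * log2(f[hi] / 500))            # -9 dB/oct
  y <- Re(fft(fft(c(x, numeric(nfft - n))) * g, inverse = TRUE)) / nfft
  y <- y[seq_len(n)]
  mono_signal(y / sqrt(mean(y^2)), rate)
}

#' Experiment configuration for the condition matrix
#'
#' Describes the eight-condition matrix: masker kind (stationary
#' speech-shaped noise or speech-like modulated) x layout (separated:
#' maskers at +90, -90, 180 degrees; collocated: everything from the
#' frontal loudspeaker) x aided/unaided.
#'
#' @param scene base [scene_config()] (the aided flag is set per condition)
#' @param model a [model_config()]
#' @param bte a [bte_transform()] or `NULL` to bypass the hearing-aid path
#' @param masker_duration seconds of masker analysed per condition
#' @param seed master seed; all per-condition seeds derive from it
#' @param n_listeners number of simulated listeners for staircase SRTs
#'   (0 = model predictions only)
#' @param srt_offset constant linking binaural ratio to a listener's true
#'   SRT: `srt = srt_offset - ratio`
#' @export
experiment_config <- function(scene = scene_config(),
                              model = model_config(),
                              bte = bte_transform(),
                              masker_duration = 120,
                              seed = 1,
                              n_listeners = 0,
                              srt_offset = -8) {
  model$masker_duration <- masker_duration
  structure(list(scene = scene, model = model, bte = bte,
                 masker_duration = masker_duration, seed = seed,
                 n_listeners = n_listeners, srt_offset = srt_offset),
            class = "experiment_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(cfg[setdiff(names(cfg), "hash")], tmp, version = 2)
  unname(tools::md5sum(tmp))
}

#' Run the full condition matrix
#'
#' Builds the synthetic BRIR sets (unaided, and aided via the BTE
#' transform), generates the maskers and the stationary target surrogate,
#' renders every condition and evaluates the short-term model. Returns the
#' per-condition binaural ratios with their better-ear/binaural-unmasking
#' components, plus derived spatial-release and hearing-aid-disadvantage
#' tables, and (optionally) simulated staircase SRTs.
#'
#' Identical configurations produce bit-identical results; the
#' configuration hash is recorded in the result for provenance.
#'
#' @param cfg an [experiment_config()]
#' @param conditions optional subset of the 8 conditions as a data frame
#'   with columns `masker`, `layout`, `aided`; incomplete matrices are
#'   computed with a warning
#' @param verbose print per-stage timing
#' @return object of class `matrix_result`: `conditions` (one row per
#'   condition), `srm`, `disadvantage`, `listener_srts` (or `NULL`),
#'   `hash`
#' @export
run_matrix <- function(cfg = experiment_config(), conditions = NULL,
                       verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  full <- expand.grid(masker = c("ssn", "modulated"),
                      layout = c("separated", "collocated"),
                      aided = c(FALSE, TRUE), stringsAsFactors = FALSE)
  if (is.null(conditions)) conditions <- full
  else if (nrow(conditions) < nrow(full))
    warning("partial condition matrix; computing the requested subset")

  rate <- cfg$scene$rate
  seed <- cfg$seed
  say <- function(fmt, ...) if (verbose)
    message(sprintf("[%s] ", format(Sys.time(), "%H:%M:%S")), sprintf(fmt, ...))

  t0 <- Sys.time()
  ref <- ltass_noise(20, rate, seed = seed + 11L)
  target <- generate_ssn(ref, cfg$masker_duration + 1, seed = seed + 17L)
  mask_seeds <- seed + c(23L, 29L, 31L)
  maskers <- list(
    ssn = lapply(mask_seeds, function(s)
      generate_ssn(ref, cfg$masker_duration + 1, seed = s)),
    modulated = lapply(mask_seeds, function(s)
      generate_speechlike(ref, cfg$masker_duration + 1, seed = s)))
  say("stimuli generated (%.1f s)", as.numeric(Sys.time() - t0, units = "secs"))

  build_set <- function(aided) {
    sc <- cfg$scene
    sc$aided <- aided
    sc$playback_attenuation <- if (aided) cfg$scene$insertion_gain else 0
    raw <- lapply(sc$azimuths, function(a) simulate_brir(sc, a))
    if (aided && !is.null(cfg$bte))
      raw <- lapply(raw, apply_bte_transform, t = cfg$bte)
    list(scene = sc, brirs = condition_brirs(raw, ref))
  }
  sets <- list(unaided = build_set(FALSE), aided = build_set(TRUE))
  say("BRIR sets built (%.1f s)", as.numeric(Sys.time() - t0, units = "secs"))

  rows <- vector("list", nrow(conditions))
  outputs <- vector("list", nrow(conditions))
  for (i in seq_len(nrow(conditions))) {
    cnd <- conditions[i, ]
    set <- if (cnd$aided) sets$aided else sets$unaided
    rend <- render_scene(set$brirs, target, maskers[[cnd$masker]],
                         set$scene, layout = cnd$layout)
    out <- predict_condition(rend, cfg$model)
    outputs[[i]] <- out
    rows[[i]] <- data.frame(masker = cnd$masker, layout = cnd$layout,
                            aided = cnd$aided, ratio = out$ratio,
                            be_component = out$be_component,
                            bu_component = out$bu_component)
    say("condition %s/%s/%s: ratio %.2f dB (%.1f s)", cnd$masker, cnd$layout,
        if (cnd$aided) "aided" else "unaided", out$ratio,
        as.numeric(Sys.time() - t0, units = "secs"))
  }
  res <- do.call(rbind, rows)

  pick <- function(masker, layout, aided) {
    j <- which(res$masker == masker & res$layout == layout & res$aided == aided)
    if (length(j)) res$ratio[j] else NA_real_
  }
  srm_tab <- do.call(rbind, lapply(unique(res$masker), function(m) {
    do.call(rbind, lapply(c(FALSE, TRUE), function(a) {
      data.frame(masker = m, aided = a,
                 predicted_srm = pick(m, "separated", a) -
                   pick(m, "collocated", a))
    }))
  }))
  dis_tab <- do.call(rbind, lapply(unique(res$masker), function(m) {
    do.call(rbind, lapply(unique(res$layout), function(l) {
      data.frame(masker = m, layout = l,
                 predicted_disadvantage = pick(m, l, FALSE) - pick(m, l, TRUE))
    }))
  }))

  listener_srts <- NULL
  if (cfg$n_listeners > 0) {
    offsets <- cfg$srt_offset +
      with_local_seed(seed + 41L, rnorm(cfg$n_listeners, 0, 1))
    listener_srts <- do.call(rbind, lapply(seq_len(cfg$n_listeners), function(k) {
      do.call(rbind, lapply(seq_len(nrow(res)), function(i) {
        true_srt <- offsets[k] - res$ratio[i]
        tr <- run_track(psychometric_listener(true_srt),
                        seed = seed + 1000L * k + i)
        data.frame(listener = k, masker = res$masker[i],
                   layout = res$layout[i], aided = res$aided[i],
                   true_srt = true_srt, srt = tr$srt, se = tr$se,
                   n_trials = tr$n_trials)
      }))
    }))
  }

  structure(list(conditions = res, srm = srm_tab, disadvantage = dis_tab,
                 listener_srts = listener_srts, outputs = outputs,
                 hash = config_hash(cfg)),
            class = "matrix_result")
}

#' @export
print.matrix_result <- function(x, ...) {
  cat("<matrix_result> config", x$hash, "\n")
  print(x$conditions, row.names = FALSE)
  cat("\nPredicted hearing-aid disadvantage (dB):\n")
  print(x$disadvantage, row.names = FALSE)
  invisible(x)
}

#' Write matrix results as CSV files
#' @param result a [run_matrix()] result
#' @param dir output directory
#' @export
write_matrix_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- function(df) { df$config_hash <- result$hash; df }
  write.csv(stamp(result$conditions), file.path(dir, "conditions.csv"),
            row.names = FALSE)
  write.csv(stamp(result$srm), file.path(dir, "srm.csv"), row.names = FALSE)
  write.csv(stamp(result$disadvantage), file.path(dir, "disadvantage.csv"),
            row.names = FALSE)
  if (!is.null(result$listener_srts))
    write.csv(stamp(result$listener_srts), file.path(dir, "listener_srts.csv"),
              row.names = FALSE)
  invisible(dir)
}
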