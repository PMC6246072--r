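#' Synthetic psychometric listener
#'
#' Responds to a sentence at a given target level with probability
#' `(1 - lapse) * logistic(level; srt, slope)`, where `slope` is the
#' psychometric slope in probability per dB at the midpoint (logistic scale
#' parameter `k = 4 * slope`).
#'
#' @param srt true 50%-correct target level in dB
#' @param slope probability per dB at the midpoint (> 0)
#' @param lapse lapse rate in \[0, 0.1\]
#' @export
psychometric_listener <- function(srt, slope = 0.15, lapse = 0) {
  if (slope <= 0) stop("slope must be positive")
  if (lapse < 0 || lapse > 0.1) stop("lapse must be in [0, 0.1]")
  structure(list(srt = srt, slope = slope, lapse = lapse),
            class = "psychometric_listener")
}

#' Probability of a correct response at a level
#' @param listener a [psychometric_listener()]
#' @param level target level in dB
#' @export
p_correct <- function(listener, level) {
  (1 - listener$lapse) * plogis(4 * listener$slope * (level - listener$srt))
}

#' Simulate one response
#' @inheritParams p_correct
#' @param seed optional seed; if `NULL` the current RNG stream is used
#' @return logical: correct?
#' @export
respond <- function(listener, level, seed = NULL) {
  p <- p_correct(listener, level)
  if (is.null(seed)) runif(1) < p else with_local_seed(seed, runif(1) < p)
}

# Maximum-likelihood SRT with fixed slope; SE from the observed curvature.
ml_srt <- function(levels, correct, slope) {
  k <- 4 * slope
  eps <- 1e-6
  nll <- function(s) {
    p <- pmin(pmax(plogis(k * (levels - s)), eps), 1 - eps)
    -sum(ifelse(correct, log(p), log(1 - p)))
  }
  lo <- min(levels) - 20
  hi <- max(levels) + 20
  opt <- optimize(nll, c(lo, hi))
  h <- 0.1
  d2 <- (nll(opt$minimum + h) - 2 * opt$objective + nll(opt$minimum - h)) / h^2
  se <- if (d2 > 0) 1 / sqrt(d2) else Inf
  list(srt = opt$minimum, se = se)
}

#' Run an adaptive 1-up-1-down track
#'
#' The target level decreases by `step` after a correct response and
#' increases after an incorrect one, converging on the 50% point. The run
#' terminates at the first trial from `min_trials` (16) onwards at which the
#' standard error of the threshold estimate falls below `se_target`
#' (0.8 dB), or at `max_trials` (32). The threshold estimator is a
#' maximum-likelihood fit of a fixed-slope logistic to all (level, response)
#' pairs, with the SE taken from the likelihood curvature; the mean of the
#' reversal levels is retained as a cross-check.
#'
#' @param listener a [psychometric_listener()]
#' @param start starting level in dB
#' @param step step size in dB (> 0)
#' @param seed integer seed for the response draws
#' @param min_trials,max_trials termination bounds on the trial count
#' @param se_target SE stopping criterion in dB
#' @param fit_slope slope (probability/dB) assumed by the estimator
#' @return object of class `adaptive_track`: `levels`, `correct`, `srt`,
#'   `se`, `n_trials`, `reversal_mean`
#' @export
run_track <- function(listener, start = 0, step = 2, seed = 1,
                      min_trials = 16, max_trials = 32, se_target = 0.8,
                      fit_slope = 0.15) {
  if (step <= 0) stop("step must be positive")
  with_local_seed(seed, {
    levels <- numeric(0)
    correct <- logical(0)
    level <- start
    est <- list(srt = NA_real_, se = Inf)
    for (i in seq_len(max_trials)) {
      levels[i] <- level
      correct[i] <- runif(1) < p_correct(listener, level)
      level <- level + if (correct[i]) -step else step
      if (i >= min_trials) {
        est <- ml_srt(levels, correct, fit_slope)
        if (est$se < se_target) break
      }
    }
    # reversal: the response differs from the previous one
    rev_idx <- which(diff(correct) != 0) + 1L
    reversal_mean <- if (length(rev_idx)) mean(levels[rev_idx]) else NA_real_
    structure(list(levels = levels, correct = correct,
                   srt = est$srt, se = est$se, n_trials = length(levels),
                   reversal_mean = reversal_mean, step = step, start = start),
              class = "adaptive_track")
  })
}

#' @export
print.adaptive_track <- function(x, ...) {
  cat(sprintf("<adaptive_track> %d trials, SRT %.2f dB (SE %.2f)\n",
              x$n_trials, x$srt, x$se))
  invisible(x)
}

#' Measured spatial release from masking
#'
#' Collocated minus separated SRT: positive values mean spatial separation
#' released masking.
#'
#' @param separated,collocated SRTs in dB
#' @export
srm <- function(separated, collocated) collocated - separated

#' Measured hearing-aid disadvantage
#'
#' Aided minus unaided SRT: positive values mean the hearing aids raised
#' the threshold.
#'
#' @param aided,unaided SRTs in dB
#' @export
ha_disadvantage_measured <- function(aided, unaided) aided - unaided

#' Write trial logs for a set of tracks
#' @param tracks named list of `adaptive_track`s (names = condition labels)
#' @param path CSV path
#' @export
write_trial_log <- function(tracks, path) {
  rows <- do.call(rbind, lapply(names(tracks), function(nm) {
    tr <- tracks[[nm]]
    data.frame(condition = nm, trial = seq_len(tr$n_trials),
               level = tr$levels, correct = tr$correct)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
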