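#' Kinetics extraction settings
#'
#' @param sg_window Savitzky-Golay window length in samples used for the
#'   smoothed derivative (default 11, i.e. 110 ms at 100 fps; shortened
#'   automatically for short windows).
#' @param sg_order Savitzky-Golay polynomial order (default 3).
#' @param baseline_frac Fraction of each beat window, from its start, averaged
#'   to estimate the pre-upstroke baseline force.
#' @param prominence_frac Peak prominence threshold for unpaced (auto)
#'   segmentation, as a fraction of the global trace amplitude.
#' @param complete_frac A beat window counts as complete only if the force at
#'   both of its boundaries is within this fraction of the global amplitude
#'   above the global minimum (incomplete first/last beats are discarded).
#' @return A list of kinetics settings.
#' @export
kinetics_params <- function(sg_window = 11, sg_order = 3, baseline_frac = 0.1,
                            prominence_frac = 0.2, complete_frac = 0.25) {
  list(sg_window = sg_window, sg_order = sg_order,
       baseline_frac = baseline_frac, prominence_frac = prominence_frac,
       complete_frac = complete_frac)
}

#' Segment a force trace into single twitches
#'
#' With a known pacing frequency, one window per pacing period is formed:
#' the largest peak in each period is kept (ectopic extra peaks within a
#' period are ignored) and window boundaries are placed at the baseline
#' minima between consecutive peaks. Without pacing, peaks are detected by a
#' prominence criterion (`prominence_frac` of the global amplitude) — useful
#' for tissues that retain the auto-pacing phenotype. Incomplete first/last
#' beats (force at the window edge not back near baseline) are discarded.
#'
#' @param force An `eht_force` data frame (or any data frame with `time_s`
#'   and `force_uN`), or a numeric vector with `time` supplied.
#' @param pacing_frequency Pacing rate in Hz, or `NULL` for auto detection.
#' @param params Settings from [kinetics_params()].
#' @param time Time axis in seconds when `force` is a bare numeric vector.
#' @return A list of beat windows, each `list(start, end, start_time)` with
#'   integer sample indices into the trace; attributes `time` and `force`
#'   hold the trace, `noise_sd` the estimated noise level.
#' @export
segment_beats <- function(force, pacing_frequency = NULL,
                          params = kinetics_params(), time = NULL) {
  tf <- as_time_force(force, time)
  t <- tf$time; f <- tf$force
  n <- length(f)
  if (n < 4L) stop("force trace too short to segment", call. = FALSE)

  noise <- stats::mad(diff(f)) / sqrt(2)
  gmin <- min(f); gmax <- max(f); amp <- gmax - gmin
  if (amp <= max(6 * noise, .Machine$double.eps * 100)) {
    stop(sprintf(
      "no beats detected: trace amplitude %.4g is not above the noise floor (estimated noise sd %.4g)",
      amp, noise), call. = FALSE)
  }

  # candidate local maxima
  d <- diff(f)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (length(cand) == 0L) cand <- which.max(f)

  if (!is.null(pacing_frequency)) {
    if (pacing_frequency <= 0) stop("`pacing_frequency` must be positive", call. = FALSE)
    P <- 1 / pacing_frequency
    if (t[n] - t[1] < 2 * P) {
      stop("trace must span at least two pacing periods", call. = FALSE)
    }
    cand <- cand[f[cand] >= gmin + 0.5 * amp]
    if (length(cand) == 0L) {
      stop(sprintf("no beats detected above the noise floor (noise sd %.4g)", noise),
           call. = FALSE)
    }
    period <- floor((t[cand] - t[1]) / P)
    peaks <- vapply(split(cand, period),
                    function(ix) ix[which.max(f[ix])], integer(1))
    peaks <- sort(unname(peaks))
  } else {
    thr <- gmin + params$prominence_frac * amp
    cand <- cand[f[cand] >= thr]
    if (length(cand) == 0L) {
      stop(sprintf("no beats detected above the noise floor (noise sd %.4g)", noise),
           call. = FALSE)
    }
    # merge candidates not separated by a sufficiently deep valley
    peaks <- cand[1]
    for (p in cand[-1]) {
      last <- peaks[length(peaks)]
      valley <- min(f[last:p])
      if (valley <= min(f[last], f[p]) - params$prominence_frac * amp) {
        peaks <- c(peaks, p)
      } else if (f[p] > f[last]) {
        peaks[length(peaks)] <- p
      }
    }
  }

  np <- length(peaks)
  argmin_between <- function(i, j) i - 1L + which.min(f[i:j])
  bounds <- integer(np + 1L)
  bounds[1] <- argmin_between(1L, peaks[1])
  if (np > 1) {
    for (k in seq_len(np - 1)) {
      bounds[k + 1] <- argmin_between(peaks[k], peaks[k + 1])
    }
  }
  bounds[np + 1] <- argmin_between(peaks[np], n)

  lvl <- gmin + params$complete_frac * amp
  windows <- list()
  for (k in seq_len(np)) {
    lo <- bounds[k]; hi <- bounds[k + 1]
    if (f[lo] <= lvl && f[hi] <= lvl && hi - lo >= 3L) {
      windows[[length(windows) + 1L]] <-
        list(start = lo, end = hi, start_time = t[lo])
    }
  }
  structure(windows, time = t, force = f, noise_sd = noise,
            pacing_frequency = pacing_frequency)
}

as_time_force <- function(force, time = NULL) {
  if (is.data.frame(force)) {
    if (!all(c("time_s", "force_uN") %in% names(force))) {
      stop("data frame must have `time_s` and `force_uN` columns", call. = FALSE)
    }
    list(time = force$time_s, force = force$force_uN)
  } else {
    if (is.null(time)) stop("`time` required when `force` is a vector", call. = FALSE)
    stopifnot(length(time) == length(force))
    list(time = as.numeric(time), force = as.numeric(force))
  }
}

# first crossing of `level` between indices in [from, to]; rising or falling;
# sub-sample position by linear interpolation. NA when no crossing exists.
cross_time <- function(t, f, level, from, to, rising = TRUE) {
  if (to <= from) return(NA_real_)
  for (i in from:(to - 1L)) {
    ok <- if (rising) f[i] <= level && f[i + 1L] > level
          else        f[i] >= level && f[i + 1L] < level
    if (ok) {
      if (f[i + 1L] == f[i]) return(t[i])
      return(t[i] + (level - f[i]) / (f[i + 1L] - f[i]) * (t[i + 1L] - t[i]))
    }
  }
  NA_real_
}

#' Kinetic features of a single twitch
#'
#' Baseline is the mean of the first `baseline_frac` of the window; amplitude
#' is peak minus baseline. Contraction times t10/t90 run from the upstroke
#' onset (last baseline crossing before the peak) to the first crossings of
#' baseline + 10% and + 90% of the amplitude. Relaxation times run from the
#' peak sample to the crossings of baseline + 90% and + 10% of the amplitude
#' on the decay — i.e. 10% and 90% of relaxation completed. All crossings are
#' located by linear interpolation between samples, making the features
#' sub-frame accurate. Velocities are the extrema of the Savitzky-Golay
#' smoothed derivative over the upstroke and decay.
#'
#' @param force Numeric force vector (one beat window: one upstroke, one
#'   decay) or a data frame with `time_s`/`force_uN`.
#' @param time Time axis in seconds (when `force` is a vector).
#' @param params Settings from [kinetics_params()].
#' @return An object of class `eht_beat`: a list with `peak_force`,
#'   `baseline_force`, `amplitude`, `contraction_velocity`,
#'   `relaxation_velocity`, `t10_contraction`, `t90_contraction`,
#'   `t10_relaxation`, `t90_relaxation`, `beat_start_time`, `failed` (flag;
#'   a window with no usable baseline crossing is excluded from summaries).
#' @export
beat_features <- function(force, time = NULL, params = kinetics_params()) {
  tf <- as_time_force(force, time)
  t <- tf$time; f <- tf$force
  m <- length(f)
  if (m < 10L) stop("beat window must contain at least 10 samples", call. = FALSE)

  res <- list(peak_force = NA_real_, baseline_force = NA_real_,
              amplitude = NA_real_, contraction_velocity = NA_real_,
              relaxation_velocity = NA_real_, t10_contraction = NA_real_,
              t90_contraction = NA_real_, t10_relaxation = NA_real_,
              t90_relaxation = NA_real_, beat_start_time = t[1],
              failed = TRUE)
  class(res) <- "eht_beat"

  nb <- max(1L, round(params$baseline_frac * m))
  baseline <- mean(f[seq_len(nb)])
  pk <- which.max(f)
  peak <- f[pk]
  ampl <- peak - baseline
  res$peak_force <- peak
  res$baseline_force <- baseline
  res$amplitude <- ampl
  if (ampl <= 0 || pk <= 1L || pk >= m) return(res)  # garbage window

  # upstroke onset: last baseline crossing before the peak
  onset_i <- NA_integer_
  for (i in (pk - 1L):1L) {
    if (f[i] <= baseline) { onset_i <- i; break }
  }
  if (is.na(onset_i)) return(res)
  t_onset <- cross_time(t, f, baseline, onset_i, pk, rising = TRUE)
  if (is.na(t_onset)) t_onset <- t[onset_i]

  c10 <- cross_time(t, f, baseline + 0.1 * ampl, onset_i, pk, rising = TRUE)
  c90 <- cross_time(t, f, baseline + 0.9 * ampl, onset_i, pk, rising = TRUE)
  r10 <- cross_time(t, f, baseline + 0.9 * ampl, pk, m, rising = FALSE)
  r90 <- cross_time(t, f, baseline + 0.1 * ampl, pk, m, rising = FALSE)
  if (anyNA(c(c10, c90, r10, r90))) return(res)
  res$t10_contraction <- c10 - t_onset
  res$t90_contraction <- c90 - t_onset
  res$t10_relaxation <- r10 - t[pk]
  res$t90_relaxation <- r90 - t[pk]

  # velocities from the Savitzky-Golay smoothed derivative
  dt <- stats::median(diff(t))
  nw <- min(params$sg_window, m)
  if (nw %% 2 == 0) nw <- nw - 1L
  deriv <- if (nw >= params$sg_order + 2) {
    signal::sgolayfilt(f, p = params$sg_order, n = nw, m = 1, ts = dt)
  } else {
    c(diff(f) / diff(t), 0)
  }
  res$contraction_velocity <- max(deriv[onset_i:pk])
  res$relaxation_velocity <- max(-deriv[pk:m])
  res$failed <- FALSE
  res
}

#' Extract features for every segmented beat
#'
#' @param beats Beat windows from [segment_beats()].
#' @param params Settings from [kinetics_params()].
#' @return A data frame with one row per window (all [beat_features()]
#'   fields plus `failed`); failed windows are retained here and excluded by
#'   [summarize_recording()].
#' @export
beats_table <- function(beats, params = kinetics_params()) {
  t <- attr(beats, "time"); f <- attr(beats, "force")
  rows <- lapply(beats, function(w) {
    ft <- beat_features(f[w$start:w$end], t[w$start:w$end], params)
    as.data.frame(unclass(ft))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    template <- beat_features(c(0, 0, 0.2, 0.6, 1, 1, 0.6, 0.2, 0, 0),
                              seq(0, 0.9, by = 0.1))
    out <- as.data.frame(unclass(template))[0, ]
  }
  out
}

#' Summarize twitch kinetics over a recording
#'
#' Per-field mean and standard deviation (sample formula) over all complete,
#' non-failed beats, plus the observed beat rate.
#'
#' @param beats A data frame from [beats_table()], a list of `eht_beat`
#'   objects, or beat windows from [segment_beats()].
#' @param duration Recording duration in seconds.
#' @param pacing_frequency Pacing rate in Hz (`NA` for spontaneous).
#' @return An object of class `eht_summary`: a list with `n_beats`,
#'   `beat_rate`, `pacing_frequency`, `mean` and `sd` (named numeric vectors
#'   over the feature fields).
#' @export
summarize_recording <- function(beats, duration, pacing_frequency = NA_real_) {
  df <- if (is.data.frame(beats)) {
    beats
  } else if (length(beats) && inherits(beats[[1]], "eht_beat")) {
    do.call(rbind, lapply(beats, function(b) as.data.frame(unclass(b))))
  } else {
    beats_table(beats)
  }
  df <- df[!df$failed, , drop = FALSE]
  if (nrow(df) == 0L) {
    stop("cannot summarize: no valid beats", call. = FALSE)
  }
  fields <- c("peak_force", "baseline_force", "amplitude",
              "contraction_velocity", "relaxation_velocity",
              "t10_contraction", "t90_contraction",
              "t10_relaxation", "t90_relaxation")
  mu <- vapply(fields, function(k) mean(df[[k]]), numeric(1))
  sdv <- vapply(fields, function(k) if (nrow(df) > 1) stats::sd(df[[k]]) else 0,
                numeric(1))
  structure(list(n_beats = nrow(df), beat_rate = nrow(df) / duration,
                 pacing_frequency = pacing_frequency, mean = mu, sd = sdv),
            class = "eht_summary")
}

#' @export
print.eht_summary <- function(x, ...) {
  cat(sprintf("<eht_summary> %d beats, %.3g Hz beat rate\n", x$n_beats, x$beat_rate))
  m <- cbind(mean = x$mean, sd = x$sd)
  print(round(m, 4))
  invisible(x)
}
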