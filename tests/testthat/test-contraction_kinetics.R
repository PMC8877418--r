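# Frozen expected values for the raised-cosine twitch F(t) = A/2 (1 - cos(2 pi t / d)),
# A = 10, d = 0.4 s, computed with an independent dense-grid oracle (1e5 points,
# crossings by linear interpolation) and confirmed against the closed forms
# t10 = (d/2pi) acos(0.8), t90 = (d/2pi) acos(-0.8), max dF/dt = A pi / d:
RC <- list(t10c = 0.04096655, t90c = 0.15903345, interval = 0.11806690,
           t10r = 0.04096655, t90r = 0.15903345, vmax = 78.53982)

test_that("raised-cosine features match the analytic oracle at dense sampling", {
  spec <- twitch_spec(amplitude = 10, pacing_frequency = 1, duty = 0.4)
  tw <- make_twitch_trace(spec, duration = 3, frame_rate = 2000)
  segs <- segment_beats(tw$trace$value, pacing_frequency = 1,
                        time = tw$trace$time_s)
  bt <- beats_table(segs)
  b <- bt[1, ]
  expect_equal(b$peak_force, 10, tolerance = 1e-4)
  expect_equal(b$t10_contraction, RC$t10c, tolerance = 1e-3)
  expect_equal(b$t90_contraction, RC$t90c, tolerance = 1e-3)
  expect_equal(b$t90_contraction - b$t10_contraction, RC$interval, tolerance = 1e-3)
  expect_equal(b$t10_relaxation, RC$t10r, tolerance = 1e-3)
  expect_equal(b$t90_relaxation, RC$t90r, tolerance = 1e-3)
  expect_equal(b$contraction_velocity, RC$vmax, tolerance = 1e-3)
  expect_equal(b$relaxation_velocity, RC$vmax, tolerance = 1e-3)
})

test_that("features scale correctly under time and amplitude rescaling", {
  mk <- function(A, duty, fr) {
    tw <- make_twitch_trace(twitch_spec(amplitude = A, duty = duty),
                            duration = 3, frame_rate = fr)
    segs <- segment_beats(tw$trace$value, 1, time = tw$trace$time_s)
    beats_table(segs)[1, ]
  }
  b1 <- mk(10, 0.4, 1000)
  b2 <- mk(10, 0.2, 1000)  # twitch compressed in time by k = 2
  expect_equal(b2$t90_contraction / b1$t90_contraction, 0.5, tolerance = 0.02)
  expect_equal(b2$t90_relaxation / b1$t90_relaxation, 0.5, tolerance = 0.02)
  expect_equal(b2$contraction_velocity / b1$contraction_velocity, 2, tolerance = 0.02)
  expect_equal(b2$peak_force, b1$peak_force, tolerance = 1e-6)

  b3 <- mk(30, 0.4, 1000)  # amplitude scaled by c = 3
  expect_equal(b3$peak_force / b1$peak_force, 3, tolerance = 1e-6)
  expect_equal(b3$contraction_velocity / b1$contraction_velocity, 3, tolerance = 1e-6)
  expect_equal(b3$t10_contraction, b1$t10_contraction, tolerance = 1e-9)
  expect_equal(b3$t90_relaxation, b1$t90_relaxation, tolerance = 1e-9)
})

test_that("feature extraction commutes with time shift", {
  tw <- make_twitch_trace(twitch_spec(amplitude = 10), duration = 3,
                          frame_rate = 500)
  segs <- segment_beats(tw$trace$value, 1, time = tw$trace$time_s)
  w <- segs[[1]]
  t <- attr(segs, "time"); f <- attr(segs, "force")
  b0 <- beat_features(f[w$start:w$end], t[w$start:w$end])
  b1 <- beat_features(f[w$start:w$end], t[w$start:w$end] + 17.3)
  expect_equal(b1$beat_start_time, b0$beat_start_time + 17.3)
  for (k in c("peak_force", "amplitude", "t10_contraction", "t90_contraction",
              "t10_relaxation", "t90_relaxation", "contraction_velocity")) {
    expect_equal(b1[[k]], b0[[k]], tolerance = 1e-9)
  }
})

test_that("segmentation recovers the programmed beat count across pacing rates", {
  for (pacing in c(0.5, 1, 2, 3)) {
    tw <- make_twitch_trace(twitch_spec(amplitude = 5, pacing_frequency = pacing),
                            duration = 10, frame_rate = 100)
    segs <- segment_beats(tw$trace$value, pacing, time = tw$trace$time_s)
    expect_length(segs, tw$ground_truth$beat_count)
  }
  # 10 s at 1 Hz: 10 complete windows, first and last retained
  tw1 <- make_twitch_trace(twitch_spec(amplitude = 10), 10, 100)
  expect_length(segment_beats(tw1$trace$value, 1, time = tw1$trace$time_s), 10)
})

test_that("auto segmentation finds unpaced beats and their rate", {
  tw <- make_twitch_trace(twitch_spec(amplitude = 8, pacing_frequency = 2),
                          duration = 5, frame_rate = 100)
  segs <- segment_beats(tw$trace$value, pacing_frequency = NULL,
                        time = tw$trace$time_s)
  expect_length(segs, 10)
  sm <- summarize_recording(segs, duration = 5)
  expect_equal(sm$beat_rate, 2)
})

test_that("a flat trace raises a no-beats error with a noise estimate", {
  t <- seq(0, 5, 0.01)
  expect_error(segment_beats(rep(1, length(t)), 1, time = t), "no beats")
  set.seed(3)
  expect_error(segment_beats(rnorm(length(t), 0, 0.01), 1, time = t),
               "noise")
})

test_that("summaries use the sample SD and per-field means", {
  tw <- make_twitch_trace(twitch_spec(amplitude = 10), 10, 100)
  segs <- segment_beats(tw$trace$value, 1, time = tw$trace$time_s)
  bt <- beats_table(segs)
  sm <- summarize_recording(bt, 10, 1)
  expect_equal(sm$n_beats, 10)
  expect_equal(sm$beat_rate, 1)
  expect_lt(max(sm$sd[c("amplitude", "t10_contraction")]), 1e-8)  # identical beats

  # hand-computable case: amplitudes 8, 10, 12 -> mean 10, SD 2
  df <- bt[1:3, ]
  scale <- c(8, 10, 12) / df$amplitude
  for (k in c("peak_force", "baseline_force", "amplitude",
              "contraction_velocity", "relaxation_velocity")) {
    df[[k]] <- df[[k]] * scale
  }
  sm3 <- summarize_recording(df, 3, 1)
  expect_equal(unname(sm3$mean["amplitude"]), 10, tolerance = 1e-9)
  expect_equal(unname(sm3$sd["amplitude"]), 2, tolerance = 1e-9)

  expect_error(summarize_recording(bt[0, ], 10, 1), "no valid beats")
})

test_that("noisy twitch trains are recovered within stated tolerances", {
  frame_dt <- 1 / 100
  for (seed in c(1, 2, 3)) {
    spec <- twitch_spec(amplitude = 10, noise_sd = 0.02, seed = seed)
    tw <- make_twitch_trace(spec, duration = 10, frame_rate = 100)
    segs <- segment_beats(tw$trace$value, 1, time = tw$trace$time_s)
    expect_length(segs, 10)
    sm <- summarize_recording(beats_table(segs), 10, 1)
    gt <- tw$ground_truth
    expect_lt(abs(sm$mean["amplitude"] - gt$amplitude) / gt$amplitude, 0.03)
    for (k in c("t10_contraction", "t90_contraction",
                "t10_relaxation", "t90_relaxation")) {
      expect_lt(abs(sm$mean[k] - gt[[k]]), frame_dt + 0.05 * gt[[k]])
    }
    expect_lt(abs(sm$mean["contraction_velocity"] - gt$contraction_velocity) /
                gt$contraction_velocity, 0.10)
    expect_lt(abs(sm$mean["relaxation_velocity"] - gt$relaxation_velocity) /
                gt$relaxation_velocity, 0.10)
  }
})

test_that("garbage windows are flagged as failed, not summarized", {
  t <- seq(0, 1, length.out = 50)
  b <- beat_features(seq(1, 0, length.out = 50), t)  # monotone decay, no upstroke
  expect_true(b$failed)
})
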