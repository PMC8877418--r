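# Shared fixture builders: everything is generated in code at test time.

# A paced recording of two oscillating markers with programmed deflection.
paced_video <- function(amplitude_um = 20, duration = 3, frame_rate = 100,
                        pixel_size = 2, noise_sd = 0, seed = NULL,
                        pacing = 1, duty = 0.4) {
  spec <- twitch_spec(amplitude = amplitude_um, pacing_frequency = pacing,
                      duty = duty)
  tw <- make_twitch_trace(spec, duration = duration, frame_rate = frame_rate)
  vid <- render_marker_video(tw$trace, pixel_size = pixel_size,
                             frame_rate = frame_rate,
                             noise = list(sd = noise_sd), seed = seed)
  c(vid, list(twitch = tw))
}

# A noiseless frame with dark disks at given (x, y) centers.
disk_frame <- function(centers, radius = 8, width = 200, height = 120,
                       fg = 0.08, bg = 0.92) {
  f <- matrix(bg, height, width)
  for (i in seq_len(nrow(centers))) {
    f <- ehtforce:::add_disk(f, centers[i, 1], centers[i, 2], radius, bg - fg)
  }
  f
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected) / abs(expected)), tol)
}
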