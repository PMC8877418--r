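# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Every generator is a pure function of its seed and parameters.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Parametric twitch specification
#'
#' Defaults emulate the acquisition conditions of the platform: 1 Hz field
#' pacing with a twitch occupying 40% of the period, recorded at 100 fps.
#'
#' @param amplitude Peak amplitude (um of deflection or uN of force,
#'   depending on what the trace will stand in for).
#' @param pacing_frequency Pacing rate in Hz.
#' @param duty Twitch duration as a fraction of the pacing period.
#' @param shape `"raised_cosine"` (symmetric) or `"asymmetric_two_phase"`
#'   (distinct rise/decay half-cosines).
#' @param rise_fraction Fraction of the twitch duration spent contracting
#'   (only used by the asymmetric shape).
#' @param phase Fraction of a pacing period of relaxed baseline preceding the
#'   first twitch onset. Acquisition is not synchronized with the stimulus in
#'   practice, so a recording opens mid-baseline; the default places the
#'   first upstroke 0.3 periods in.
#' @param noise_sd Additive Gaussian noise, as a fraction of the amplitude.
#' @param seed RNG seed for the noise (`NULL` = noiseless determinism).
#' @return A `twitch_spec` list.
#' @export
twitch_spec <- function(amplitude = 10, pacing_frequency = 1, duty = 0.4,
                        shape = c("raised_cosine", "asymmetric_two_phase"),
                        rise_fraction = 0.5, phase = 0.3, noise_sd = 0,
                        seed = NULL) {
  shape <- match.arg(shape)
  stopifnot(amplitude > 0, pacing_frequency > 0,
            duty > 0, duty < 1, rise_fraction > 0, rise_fraction < 1,
            phase >= 0, phase < 1, duty + phase <= 1)
  structure(list(amplitude = amplitude, pacing_frequency = pacing_frequency,
                 duty = duty, shape = shape, rise_fraction = rise_fraction,
                 phase = phase, noise_sd = noise_sd, seed = seed),
            class = "twitch_spec")
}

# Unit-amplitude twitch value at phase tt in [0, d); 0 outside.
twitch_value <- function(tt, d, shape, rise_fraction) {
  v <- numeric(length(tt))
  inside <- tt >= 0 & tt < d
  if (shape == "raised_cosine") {
    v[inside] <- (1 - cos(2 * pi * tt[inside] / d)) / 2
  } else {
    tp <- rise_fraction * d
    ris <- inside & tt < tp
    dec <- inside & tt >= tp
    v[ris] <- (1 - cos(pi * tt[ris] / tp)) / 2
    v[dec] <- (1 + cos(pi * (tt[dec] - tp) / (d - tp))) / 2
  }
  v
}

# Ground-truth features of one noiseless twitch, derived numerically on a
# dense grid (1e5 intervals over the twitch) — the documented oracle for all
# shapes; sub-grid crossing times by linear interpolation.
twitch_ground_truth <- function(spec) {
  d <- spec$duty / spec$pacing_frequency
  A <- spec$amplitude
  n <- 1e5L
  tt <- seq(0, d, length.out = n + 1L)
  f <- A * twitch_value(tt, d, spec$shape, spec$rise_fraction)
  f[length(f)] <- 0
  pk <- which.max(f)
  crossing <- function(level, from, to, rising) {
    cross_time(tt, f, level, from, to, rising)
  }
  dfdt <- diff(f) / diff(tt)
  list(
    peak_force = A, baseline_force = 0, amplitude = A,
    t10_contraction = crossing(0.1 * A, 1L, pk, TRUE),
    t90_contraction = crossing(0.9 * A, 1L, pk, TRUE),
    t10_relaxation = crossing(0.9 * A, pk, n + 1L, FALSE) - tt[pk],
    t90_relaxation = crossing(0.1 * A, pk, n + 1L, FALSE) - tt[pk],
    contraction_velocity = max(dfdt[1:(pk - 1L)]),
    relaxation_velocity = max(-dfdt[pk:n]),
    twitch_duration = d
  )
}

#' Generate a parametric twitch train with known ground truth
#'
#' One twitch per pacing period, starting at phase zero, zero baseline in
#' between; optional seeded additive Gaussian noise. The returned ground
#' truth holds the analytically known single-twitch features (derived on a
#' dense 1e5-point grid) and the programmed beat count.
#'
#' @param spec A [twitch_spec()].
#' @param duration Trace length in seconds (>= one pacing period).
#' @param frame_rate Sampling rate in Hz.
#' @return A list with `trace` (data frame `time_s`, `value`) and
#'   `ground_truth` (single-twitch features plus `beat_count`).
#' @export
make_twitch_trace <- function(spec, duration = 10, frame_rate = 100) {
  stopifnot(inherits(spec, "twitch_spec"))
  P <- 1 / spec$pacing_frequency
  if (duration < P) stop("`duration` must cover at least one pacing period", call. = FALSE)
  n <- round(duration * frame_rate)
  t <- (seq_len(n) - 1L) / frame_rate
  d <- spec$duty * P
  t0 <- spec$phase * P  # first upstroke onset
  v <- spec$amplitude *
    twitch_value((t - t0) %% P, d, spec$shape, spec$rise_fraction)
  if (spec$noise_sd > 0) {
    v <- v + with_seed(spec$seed,
                       stats::rnorm(n, 0, spec$noise_sd * spec$amplitude))
  }
  gt <- twitch_ground_truth(spec)
  gt$beat_count <- floor((duration - t0 - d) / P + 1e-9) + 1L
  list(trace = data.frame(time_s = t, value = v), ground_truth = gt)
}

# Anti-aliased disk coverage of each pixel in a bounding box, by 4x4
# supersampling; pixel centers at integer coordinates (x right, y down).
add_disk <- function(frame, cx, cy, r, depth) {
  h <- nrow(frame); w <- ncol(frame)
  xs <- max(1L, floor(cx - r - 1)):min(w, ceiling(cx + r + 1))
  ys <- max(1L, floor(cy - r - 1)):min(h, ceiling(cy + r + 1))
  off <- (seq_len(4) - 2.5) / 4
  cov <- matrix(0, length(ys), length(xs))
  for (oy in off) for (ox in off) {
    dx2 <- (xs + ox - cx)^2
    dy2 <- (ys + oy - cy)^2
    cov <- cov + (outer(dy2, dx2, "+") <= r^2)
  }
  frame[ys, xs] <- frame[ys, xs] - depth * (cov / 16)
  frame
}

#' Render a two-marker cantilever video from a deflection trace
#'
#' Two anti-aliased dark disks on a light background, each displaced toward
#' the other by half the programmed deflection per frame — emulating the
#' carbon-black cantilever tops of a paced tissue. Optional seeded Gaussian
#' sensor noise and slow sinusoidal illumination drift. Frames are quantized
#' to the 16-bit intensity grid so a written TIFF round-trips bit-identically.
#'
#' @param trace Deflection in micrometers: a numeric vector, or a data frame
#'   with a `value` or `deflection_um` column (e.g. from
#'   [make_twitch_trace()]).
#' @param pixel_size Micrometers per pixel.
#' @param frame_rate Frames per second.
#' @param layout List: `width`, `height` (px), `gap_px` (relaxed
#'   inter-marker distance), `radius_px`, `fg` (marker intensity), `bg`
#'   (background intensity), `center_y` (marker row, defaults to mid-height).
#' @param noise List: `sd` (Gaussian sensor noise), `drift_amp` and
#'   `drift_period` (s) for illumination drift.
#' @param seed RNG seed for the sensor noise.
#' @param identifier Label for the resulting recording.
#' @return A list with `recording` (an `eht_recording`) and `ground_truth`
#'   (data frame: `frame`, `x1`, `y1`, `x2`, `y2`, `distance_um`,
#'   `deflection_um` — exact programmed sub-pixel centroids).
#' @export
render_marker_video <- function(trace, pixel_size = 2, frame_rate = 100,
                                layout = list(), noise = list(), seed = NULL,
                                identifier = "synthetic") {
  if (is.data.frame(trace)) {
    trace <- if ("deflection_um" %in% names(trace)) trace$deflection_um else trace$value
  }
  lay <- utils::modifyList(
    list(width = 160L, height = 90L, gap_px = 100, radius_px = 8,
         fg = 0.08, bg = 0.92, center_y = NULL), layout)
  nz <- utils::modifyList(list(sd = 0, drift_amp = 0, drift_period = 5), noise)
  if (is.null(lay$center_y)) lay$center_y <- (lay$height + 1) / 2

  s_px <- trace / 2 / pixel_size  # per-marker displacement toward the other
  cxL0 <- (lay$width + 1) / 2 - lay$gap_px / 2
  cxR0 <- (lay$width + 1) / 2 + lay$gap_px / 2
  min_sep <- lay$gap_px - 2 * max(s_px)
  if (min_sep < 4 * lay$radius_px) {
    stop("programmed excursion brings markers closer than two diameters", call. = FALSE)
  }
  if (cxL0 - max(abs(s_px)) < lay$radius_px + 2 ||
      cxR0 + max(abs(s_px)) > lay$width - lay$radius_px - 1) {
    stop("markers leave the frame under the programmed excursion", call. = FALSE)
  }

  n <- length(trace)
  depth <- lay$bg - lay$fg
  drift <- if (nz$drift_amp > 0) {
    nz$drift_amp * sin(2 * pi * (seq_len(n) - 1L) / frame_rate / nz$drift_period)
  } else rep(0, n)

  frames <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      fr <- matrix(lay$bg + drift[i], lay$height, lay$width)
      fr <- add_disk(fr, cxL0 + s_px[i], lay$center_y, lay$radius_px, depth)
      fr <- add_disk(fr, cxR0 - s_px[i], lay$center_y, lay$radius_px, depth)
      if (nz$sd > 0) fr <- fr + matrix(stats::rnorm(length(fr), 0, nz$sd),
                                       nrow(fr), ncol(fr))
      round(pmin(pmax(fr, 0), 1) * 65535) / 65535  # 16-bit grid
    })
  })

  x1 <- cxL0 + s_px; x2 <- cxR0 - s_px
  gt <- data.frame(
    frame = seq_len(n), x1 = x1, y1 = lay$center_y, x2 = x2, y2 = lay$center_y,
    distance_um = (x2 - x1) * pixel_size,
    deflection_um = (lay$gap_px - (x2 - x1)) * pixel_size
  )
  list(recording = new_recording(frames, frame_rate, pixel_size, identifier),
       ground_truth = gt)
}

#' Synthetic dose-response table on a Hill curve
#'
#' @param ic50 Half-maximal inhibitory concentration (molar).
#' @param hill Hill coefficient.
#' @param concentrations Molar concentrations; a 0 entry is reported as
#'   response 1 exactly (the normalization anchor, never noised).
#' @param noise_sd Gaussian noise added to the non-zero responses.
#' @param seed RNG seed.
#' @return Data frame with `concentration_M` and `response`.
#' @export
make_dose_table <- function(ic50, hill, concentrations, noise_sd = 0, seed = NULL) {
  stopifnot(ic50 > 0, hill > 0)
  r <- ifelse(concentrations == 0, 1, 1 / (1 + (concentrations / ic50)^hill))
  if (noise_sd > 0) {
    nz <- concentrations > 0
    r[nz] <- r[nz] + with_seed(seed, stats::rnorm(sum(nz), 0, noise_sd))
  }
  data.frame(concentration_M = concentrations, response = r)
}

#' Synthetic tissue silhouette with analytic area
#'
#' Renders a dark shape of exactly known area on a light background with
#' 4x supersampled anti-aliased edges, for validating area segmentation.
#'
#' @param shape `"disk"`, `"ellipse"` or `"capsule"` (rectangle with
#'   semicircular caps).
#' @param dims_mm Shape dimensions in mm: disk `c(r)`; ellipse `c(a, b)`
#'   (semi-axes); capsule `c(total_length, width)`.
#' @param pixel_size Micrometers per pixel.
#' @param noise_sd Seeded Gaussian sensor noise.
#' @param seed RNG seed.
#' @param rotation_deg Rotation of the shape, degrees counter-clockwise.
#' @param fg,bg Shape and background intensity.
#' @param margin_px Background margin around the shape.
#' @return A list with `image` (matrix), `pixel_size` and `area_mm2`
#'   (analytic).
#' @export
make_tissue_silhouette <- function(shape = c("disk", "ellipse", "capsule"),
                                   dims_mm = 1, pixel_size = 10, noise_sd = 0,
                                   seed = NULL, rotation_deg = 0,
                                   fg = 0.15, bg = 0.9, margin_px = 12) {
  shape <- match.arg(shape)
  px_mm <- 1000 / pixel_size  # px per mm
  half_ext_mm <- switch(shape,
    disk = dims_mm[1],
    ellipse = max(dims_mm[1:2]),
    capsule = dims_mm[1] / 2
  )
  half_ext <- half_ext_mm * px_mm
  w <- h <- 2L * ceiling(half_ext + margin_px) + 1L
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  th <- rotation_deg * pi / 180

  inside <- function(x, y) {
    # rotate into shape frame (mm)
    xr <- (cos(th) * (x - cx) + sin(th) * (y - cy)) / px_mm
    yr <- (-sin(th) * (x - cx) + cos(th) * (y - cy)) / px_mm
    switch(shape,
      disk = xr^2 + yr^2 <= dims_mm[1]^2,
      ellipse = (xr / dims_mm[1])^2 + (yr / dims_mm[2])^2 <= 1,
      capsule = {
        hl <- dims_mm[1] / 2 - dims_mm[2] / 2  # half length of the straight part
        dx <- pmax(abs(xr) - hl, 0)
        dx^2 + yr^2 <= (dims_mm[2] / 2)^2
      }
    )
  }
  area_mm2 <- switch(shape,
    disk = pi * dims_mm[1]^2,
    ellipse = pi * dims_mm[1] * dims_mm[2],
    capsule = (dims_mm[1] - dims_mm[2]) * dims_mm[2] + pi * (dims_mm[2] / 2)^2
  )

  xs <- seq_len(w); ys <- seq_len(h)
  off <- (seq_len(4) - 2.5) / 4
  cov <- matrix(0, h, w)
  for (oy in off) for (ox in off) {
    cov <- cov + outer(ys + oy, xs + ox, function(y, x) inside(x, y))
  }
  img <- bg - (bg - fg) * cov / 16
  if (noise_sd > 0) {
    img <- img + with_seed(seed, matrix(stats::rnorm(length(img), 0, noise_sd), h, w))
    img <- pmin(pmax(img, 0), 1)
  }
  list(image = img, pixel_size = pixel_size, area_mm2 = area_mm2)
}
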