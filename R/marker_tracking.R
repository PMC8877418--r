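#' Default marker-detection settings
#'
#' The cantilever tops are stained with carbon-black PDMS, so they image as
#' near-black disks on a light background. Detection is a global Otsu
#' threshold on the inverted frame, connected-component labelling, and
#' filters on blob area and circularity (4*pi*A / P^2). Centroids are
#' sub-pixel: intensity-weighted on the background-subtracted inverted image
#' over the blob grown by one pixel (to include anti-aliased rim pixels).
#'
#' @param min_area Minimum blob area in px^2 kept by the filter.
#' @param max_area Maximum blob area in px^2 (`Inf` disables).
#' @param min_circularity Minimum circularity 4*pi*A/P^2; 1 is a perfect disk.
#' @param min_contrast Minimum frame intensity range below which the frame is
#'   treated as blank (no detections).
#' @param max_gap Longest run of frames without a valid marker pair that is
#'   bridged by linear interpolation (longer runs are a tracking failure).
#' @param per_post_deflection If `TRUE`, report deflection per post (total
#'   inter-marker change divided by 2) instead of the total change.
#' @param baseline_distance Optional fixed relaxed inter-marker distance in
#'   micrometers; by default the maximum distance over the recording.
#' @return A list of detection settings.
#' @export
detection_params <- function(min_area = 9, max_area = Inf, min_circularity = 0.5,
                             min_contrast = 0.1, max_gap = 5,
                             per_post_deflection = FALSE,
                             baseline_distance = NULL) {
  list(
    min_area = min_area, max_area = max_area, min_circularity = min_circularity,
    min_contrast = min_contrast, max_gap = max_gap,
    per_post_deflection = isTRUE(per_post_deflection),
    baseline_distance = baseline_distance
  )
}

#' Detect dark circular markers in one frame
#'
#' @param frame Numeric matrix in `[0, 1]` (row = y, column = x; pixel centers
#'   at integer coordinates).
#' @param params Settings from [detection_params()].
#' @return A data frame with one row per detected marker: `x`, `y` (sub-pixel
#'   centroid, x right / y down), `area` (px^2), `circularity`; sorted by `x`.
#'   Zero rows when nothing passes the filters (a blank frame is permitted).
#' @export
detect_markers <- function(frame, params = detection_params()) {
  empty <- data.frame(x = numeric(0), y = numeric(0),
                      area = numeric(0), circularity = numeric(0))
  if (!is.matrix(frame) || !is.numeric(frame)) {
    stop("`frame` must be a numeric matrix", call. = FALSE)
  }
  rng <- range(frame, finite = TRUE)
  if (diff(rng) < params$min_contrast) return(empty)  # blank / featureless

  inv <- pmin(pmax(1 - frame, 0), 1)  # noise can leave the nominal range
  thr <- EBImage::otsu(inv, range = c(0, 1))
  mask <- inv > thr
  labm <- EBImage::imageData(EBImage::bwlabel(mask))
  nb <- max(labm)
  if (nb == 0) return(empty)

  area <- tabulate(labm[labm > 0], nbins = nb)
  perim <- pmax(boundary_counts(labm, nb), 1)
  circ <- 4 * pi * area / perim^2
  keep <- which(area >= params$min_area & area <= params$max_area &
                  circ >= params$min_circularity)
  if (length(keep) == 0L) return(empty)

  # background level of the inverted image (blobs are a small minority)
  bg <- stats::median(inv)
  h <- nrow(labm); w <- ncol(labm)
  idx_all <- which(labm > 0, arr.ind = TRUE)
  lab_of <- labm[idx_all]
  res <- lapply(keep, function(k) {
    sel <- idx_all[lab_of == k, , drop = FALSE]
    # bounding box grown by 1 px to capture anti-aliased rim pixels
    ys <- max(1L, min(sel[, 1]) - 1L):min(h, max(sel[, 1]) + 1L)
    xs <- max(1L, min(sel[, 2]) - 1L):min(w, max(sel[, 2]) + 1L)
    box_lab <- labm[ys, xs, drop = FALSE]
    wgt <- pmax(inv[ys, xs, drop = FALSE] - bg, 0)
    wgt[box_lab != 0 & box_lab != k] <- 0  # exclude neighbouring blobs
    sw <- sum(wgt)
    if (sw <= 0) return(NULL)
    # column = x, row = y; pixel centers at integer coordinates
    c(x = sum(rep(xs, each = length(ys)) * wgt) / sw,
      y = sum(rep(ys, times = length(xs)) * wgt) / sw,
      area = area[k], circularity = circ[k])
  })
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(res)) return(empty)
  out <- as.data.frame(res)
  out[order(out$x), , drop = FALSE]
}

# per-label count of pixels touching a different label (4-connectivity),
# a pixel-count perimeter estimate for the circularity filter
boundary_counts <- function(labm, nb) {
  h <- nrow(labm); w <- ncol(labm)
  shift <- function(di, dj) {
    M <- matrix(-1L, h, w)  # out-of-frame counts as boundary
    M[max(1, 1 + di):min(h, h + di), max(1, 1 + dj):min(w, w + dj)] <-
      labm[max(1, 1 - di):min(h, h - di), max(1, 1 - dj):min(w, w - dj)]
    M
  }
  b <- (shift(1, 0) != labm) | (shift(-1, 0) != labm) |
       (shift(0, 1) != labm) | (shift(0, -1) != labm)
  tabulate(labm[b & labm > 0], nbins = nb)
}

#' Track the two cantilever-top markers through a recording
#'
#' Runs [detect_markers()] on every frame, selects the marker pair by
#' nearest-neighbour continuity to the previous frame (first valid frame: the
#' two largest blobs, ties by leftmost x), and derives the inter-marker
#' distance and deflection time series. Short runs of frames with fewer than
#' two detections (up to `params$max_gap`) are bridged by linear interpolation
#' and flagged; longer runs abort tracking with the offending frame range.
#'
#' The relaxed baseline distance defaults to the maximum inter-marker
#' distance over the recording (the tissue fully relaxed), so recordings that
#' start mid-twitch are handled correctly; it can be overridden via
#' `params$baseline_distance`. Deflection is the total reduction of the
#' inter-marker distance, the quantity the beam equation consumes; set
#' `params$per_post_deflection` for the halved per-post convention.
#'
#' @param recording An `eht_recording` with at least two frames.
#' @param params Settings from [detection_params()].
#' @param roi Optional region of interest `list(x = c(xmin, xmax), y = c(ymin,
#'   ymax))` in pixels restricting detection; centroids are reported in full-
#'   frame coordinates.
#' @return An object of class `eht_deflection`: a data frame with columns
#'   `frame`, `time_s`, `x1`, `y1`, `x2`, `y2`, `distance_um`,
#'   `deflection_um`, `interpolated`; attributes `baseline_distance` (um),
#'   `pixel_size`, `frame_rate`, `identifier`.
#' @export
track_pair <- function(recording, params = detection_params(), roi = NULL) {
  stopifnot(inherits(recording, "eht_recording"))
  n <- length(recording$frames)
  if (n < 2L) stop("recording must have at least 2 frames", call. = FALSE)

  x_off <- 0; y_off <- 0
  frames <- recording$frames
  if (!is.null(roi)) {
    xr <- round(roi$x); yr <- round(roi$y)
    frames <- lapply(frames, function(f) f[yr[1]:yr[2], xr[1]:xr[2], drop = FALSE])
    x_off <- xr[1] - 1; y_off <- yr[1] - 1
  }

  cent <- matrix(NA_real_, n, 4,
                 dimnames = list(NULL, c("x1", "y1", "x2", "y2")))
  prev <- NULL
  for (i in seq_len(n)) {
    det <- detect_markers(frames[[i]], params)
    if (nrow(det) >= 2L) {
      if (is.null(prev)) {
        # first valid frame: two largest areas, ties broken by leftmost x
        o <- order(-det$area, det$x)
        pair <- det[sort(o[1:2]), ]
      } else {
        # keep the two blobs nearest the previous pair (summed distance)
        combos <- utils::combn(nrow(det), 2)
        cost <- apply(combos, 2, function(ij) {
          a <- det[ij[1], ]; b <- det[ij[2], ]
          d1 <- sqrt((a$x - prev[1])^2 + (a$y - prev[2])^2) +
                sqrt((b$x - prev[3])^2 + (b$y - prev[4])^2)
          d2 <- sqrt((b$x - prev[1])^2 + (b$y - prev[2])^2) +
                sqrt((a$x - prev[3])^2 + (a$y - prev[4])^2)
          min(d1, d2)
        })
        pair <- det[combos[, which.min(cost)], ]
      }
      pair <- pair[order(pair$x), ]  # canonical: left marker first
      cent[i, ] <- c(pair$x[1], pair$y[1], pair$x[2], pair$y[2])
      prev <- cent[i, ]
    }
  }

  valid <- !is.na(cent[, 1])
  if (!any(valid)) {
    stop("tracking failure: no frame yielded a valid marker pair (frames 1-",
         n, ")", call. = FALSE)
  }
  interpolated <- !valid
  runs <- rle(valid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  bad <- which(!runs$values & runs$lengths > params$max_gap)
  if (length(bad)) {
    stop(sprintf(
      "tracking failure: no valid marker pair in frames %d-%d (%d frames > max_gap = %d)",
      starts[bad[1]], ends[bad[1]], runs$lengths[bad[1]], params$max_gap
    ), call. = FALSE)
  }
  # bridge gaps (interior: linear interpolation; leading/trailing: nearest)
  if (any(!valid)) {
    vi <- which(valid)
    for (j in 1:4) {
      cent[, j] <- stats::approx(vi, cent[vi, j], xout = seq_len(n),
                                 rule = 2)$y
    }
  }

  px <- recording$pixel_size
  dist_um <- sqrt((cent[, "x2"] - cent[, "x1"])^2 +
                  (cent[, "y2"] - cent[, "y1"])^2) * px
  baseline <- if (!is.null(params$baseline_distance)) {
    params$baseline_distance
  } else {
    max(dist_um)
  }
  defl <- baseline - dist_um
  if (params$per_post_deflection) defl <- defl / 2

  out <- data.frame(
    frame = seq_len(n),
    time_s = (seq_len(n) - 1L) / recording$frame_rate,
    x1 = cent[, "x1"] + x_off, y1 = cent[, "y1"] + y_off,
    x2 = cent[, "x2"] + x_off, y2 = cent[, "y2"] + y_off,
    distance_um = dist_um,
    deflection_um = defl,
    interpolated = interpolated
  )
  structure(out,
            baseline_distance = baseline,
            pixel_size = px,
            frame_rate = recording$frame_rate,
            identifier = recording$identifier,
            class = c("eht_deflection", "data.frame"))
}
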