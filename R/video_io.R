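#' Read a time-lapse image stack as a Recording
#'
#' Loads a multi-page TIFF brightfield stack of one engineered heart tissue
#' spanning two marker-tipped cantilevers. Frames are converted to a single
#' grayscale channel (unweighted channel mean) and normalized to `[0, 1]`.
#' Acquisition metadata (frame rate, spatial calibration) is supplied
#' explicitly rather than parsed from container tags, which are unreliable
#' across TIFF dialects.
#'
#' @param path Path to a multi-page TIFF file.
#' @param frame_rate Acquisition rate in frames per second (> 0).
#' @param pixel_size Spatial calibration in micrometers per pixel (> 0).
#' @param identifier Free-text label (well/tissue/condition) carried through
#'   to all downstream output tables.
#'
#' @return An object of class `eht_recording`: a list with `frames` (list of
#'   numeric matrices, row = y, column = x, values in `[0, 1]`),
#'   `frame_rate`, `pixel_size`, `duration` (seconds, frame count divided by
#'   frame rate) and `identifier`.
#'
#' @examples
#' \dontrun{
#' rec <- load_recording("tissue_A1.tif", frame_rate = 100, pixel_size = 2)
#' rec$duration  # 10 s for a 1000-frame stack at 100 fps
#' }
#' @export
load_recording <- function(path, frame_rate, pixel_size, identifier = basename(path)) {
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || !is.finite(frame_rate) ||
      frame_rate <= 0) {
    stop("`frame_rate` must be a single positive number (frames/s)", call. = FALSE)
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || !is.finite(pixel_size) ||
      pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number (um/px)", call. = FALSE)
  }
  frames <- read_image_stack(path)
  if (length(frames) == 0L) {
    stop("no frames could be read from '", path, "'", call. = FALSE)
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("frames in '", path, "' do not share identical dimensions", call. = FALSE)
  }
  new_recording(frames, frame_rate, pixel_size, identifier)
}

new_recording <- function(frames, frame_rate, pixel_size, identifier) {
  structure(
    list(
      frames = frames,
      frame_rate = frame_rate,
      pixel_size = pixel_size,
      duration = length(frames) / frame_rate,
      identifier = identifier
    ),
    class = "eht_recording"
  )
}

#' @export
print.eht_recording <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<eht_recording> '%s': %d frames of %d x %d px, %.4g fps, %.4g um/px, %.4g s\n",
    x$identifier, length(x$frames), d[1], d[2], x$frame_rate, x$pixel_size, x$duration
  ))
  invisible(x)
}

#' Read a single snapshot with calibration
#'
#' Loads one brightfield snapshot (PNG or single/multi-page TIFF; the first
#' page is used) for whole-tissue area analysis. Multi-channel images are
#' collapsed to grayscale by the unweighted channel mean.
#'
#' @param path Path to a PNG or TIFF image.
#' @param pixel_size Micrometers per pixel (> 0).
#' @return A list with `image` (numeric matrix in `[0, 1]`) and `pixel_size`.
#' @export
load_snapshot <- function(path, pixel_size) {
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || !is.finite(pixel_size) ||
      pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number (um/px)", call. = FALSE)
  }
  frames <- read_image_stack(path)
  if (length(frames) == 0L) stop("no image could be read from '", path, "'", call. = FALSE)
  list(image = frames[[1]], pixel_size = pixel_size)
}

# Read a TIFF stack or PNG into a list of grayscale [0,1] matrices.
read_image_stack <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    stop("`path` must be a single file path", call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  if (file.info(path)$size == 0) stop("file is empty: '", path, "'", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    "tif" = ,
    "tiff" = tryCatch(tiff::readTIFF(path, all = TRUE),
                      error = function(e) stop("unreadable TIFF '", path, "': ",
                                               conditionMessage(e), call. = FALSE)),
    "png" = list(tryCatch(png::readPNG(path),
                          error = function(e) stop("unreadable PNG '", path, "': ",
                                                   conditionMessage(e), call. = FALSE))),
    stop("unsupported image container '.", ext, "' (expected TIFF or PNG)", call. = FALSE)
  )
  if (!is.list(raw)) raw <- list(raw)
  lapply(raw, to_grayscale)
}

# Collapse an HxW or HxWxC array to a grayscale matrix by unweighted channel
# mean; an alpha channel (4th) is dropped. Values are already in [0,1] from
# the tiff/png readers.
to_grayscale <- function(a) {
  if (is.matrix(a)) return(a)
  if (length(dim(a)) == 3L) {
    nc <- dim(a)[3]
    if (nc == 2L || nc == 4L) nc <- nc - 1L  # gray+alpha or RGBA: drop alpha
    out <- a[, , 1]
    if (nc > 1L) for (k in 2:nc) out <- out + a[, , k]
    return(out / nc)
  }
  stop("unexpected image array with ", length(dim(a)), " dimensions", call. = FALSE)
}

#' Write a Recording (or list of frames) to a multi-page TIFF
#'
#' Companion writer used by the synthetic-fixture generators; frames are
#' stored as 16-bit grayscale so an already-gray stack round-trips to within
#' quantization (exactly, for frames that are multiples of 1/65535).
#'
#' @param recording An `eht_recording` or a list of numeric matrices in `[0, 1]`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_recording_tiff <- function(recording, path) {
  frames <- if (inherits(recording, "eht_recording")) recording$frames else recording
  frames <- lapply(frames, function(f) pmin(pmax(f, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}
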