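#' Projected tissue area from a brightfield snapshot
#'
#' Automated stand-in for manual tracing: Otsu threshold on the (inverted,
#' when the tissue is dark on a light background) snapshot, largest connected
#' component, hole filling, and conversion of the pixel count to mm^2 through
#' the optical calibration. A user-supplied binary mask can override the
#' automatic segmentation to reproduce a hand tracing.
#'
#' @param snapshot A numeric matrix in `[0, 1]`, or a list with `image` and
#'   `pixel_size` as returned by [load_snapshot()].
#' @param pixel_size Micrometers per pixel (taken from `snapshot` when it
#'   carries one).
#' @param dark_tissue `TRUE` (default) when the tissue is darker than the
#'   background.
#' @param min_area_px Minimum component size in pixels; below this the frame
#'   is treated as empty and a segmentation error is raised.
#' @param mask Optional logical matrix (or 0/1 numeric) selecting tissue
#'   pixels directly, bypassing segmentation.
#' @return Area in mm^2 (scalar), with the segmented pixel count as
#'   attribute `n_pixels`.
#' @export
tissue_area <- function(snapshot, pixel_size = NULL, dark_tissue = TRUE,
                        min_area_px = 25, mask = NULL) {
  if (is.list(snapshot) && !is.null(snapshot$image)) {
    if (is.null(pixel_size)) pixel_size <- snapshot$pixel_size
    snapshot <- snapshot$image
  }
  stopifnot(is.matrix(snapshot))
  if (is.null(pixel_size) || pixel_size <= 0) {
    stop("`pixel_size` (um/px) must be supplied and positive", call. = FALSE)
  }
  if (is.null(mask)) {
    img <- if (dark_tissue) 1 - snapshot else snapshot
    rng <- range(img, finite = TRUE)
    if (diff(rng) < 0.05) {
      stop("segmentation error: snapshot has no contrast (blank frame?)", call. = FALSE)
    }
    thr <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
    lab <- EBImage::bwlabel(EBImage::Image(img > thr))
    nb <- max(lab)
    if (nb == 0) stop("segmentation error: no component found", call. = FALSE)
    sizes <- tabulate(as.integer(as.matrix(lab)), nbins = nb)
    k <- which.max(sizes)
    if (sizes[k] < min_area_px) {
      stop("segmentation error: largest component (", sizes[k],
           " px) below min area (", min_area_px, " px)", call. = FALSE)
    }
    comp <- EBImage::fillHull(EBImage::Image(as.matrix(lab) == k))
    mask <- as.matrix(comp) > 0
  } else {
    mask <- mask > 0
    if (sum(mask) < min_area_px) {
      stop("segmentation error: mask selects fewer than ", min_area_px,
           " pixels", call. = FALSE)
    }
  }
  n <- sum(mask)
  structure(n * (pixel_size / 1000)^2, n_pixels = n)
}

#' Early- and late-stage compaction of one tissue
#'
#' Early-stage compaction is the tissue area 5 days after formation as a
#' fraction of the 11 mm^2 seeding footprint at day 0; late-stage compaction
#' is the area at day 11, 15 and 20 normalized to the same tissue's day-5
#' area. Missing days yield missing metrics, not errors.
#'
#' @param areas Named numeric vector of areas in mm^2, names are days (e.g.
#'   `c("5" = 3.2, "11" = 2.9)`), or a data frame with `day` and `area_mm2`.
#' @param seeding_area Seeding footprint at day 0 in mm^2 (default 11).
#' @param tissue_id Optional identifier carried into the record.
#' @return An object of class `eht_compaction`: a list with `tissue_id`,
#'   `seeding_area`, `areas`, `early_compaction` (area(5)/seeding) and
#'   `late_compaction` (named vector over days 11/15/20 present,
#'   area(d)/area(5)).
#' @export
compaction_metrics <- function(areas, seeding_area = 11, tissue_id = NA_character_) {
  if (is.data.frame(areas)) {
    a <- areas$area_mm2
    names(a) <- as.character(areas$day)
    areas <- a
  }
  if (is.null(names(areas)) || any(!nzchar(names(areas)))) {
    stop("`areas` must be named by day", call. = FALSE)
  }
  if (any(areas <= 0, na.rm = TRUE)) stop("areas must be positive", call. = FALSE)
  if (!is.numeric(seeding_area) || seeding_area <= 0) {
    stop("`seeding_area` must be positive", call. = FALSE)
  }
  if (!"0" %in% names(areas)) areas <- c("0" = unname(seeding_area), areas)
  a5 <- unname(areas["5"])
  early <- if (is.na(a5)) NA_real_ else a5 / seeding_area
  late_days <- intersect(c("11", "15", "20"), names(areas))
  late <- if (is.na(a5)) {
    stats::setNames(rep(NA_real_, length(late_days)), late_days)
  } else {
    stats::setNames(unname(areas[late_days]) / a5, late_days)
  }
  structure(list(tissue_id = tissue_id, seeding_area = seeding_area,
                 areas = areas, early_compaction = early,
                 late_compaction = late),
            class = "eht_compaction")
}

#' Tissue-formation success rate
#'
#' A tissue counts as successful when it is homogeneously distributed around
#' the cantilevers without rupture at any timepoint (a manual annotation);
#' the rate is the percentage of successful tissues out of all tissues
#' produced, reported raw and rounded to the nearest integer percent.
#'
#' @param n_success Number of successful tissues (0 <= n_success <= n_total).
#' @param n_total Total number of tissues produced (> 0).
#' @return A list with `percent` (raw) and `percent_rounded`.
#' @examples
#' success_rate(11, 15)  # 73% (rounded)
#' @export
success_rate <- function(n_success, n_total) {
  if (!is.numeric(n_total) || length(n_total) != 1L || n_total <= 0) {
    stop("`n_total` must be a positive count", call. = FALSE)
  }
  if (!is.numeric(n_success) || length(n_success) != 1L ||
      n_success < 0 || n_success > n_total) {
    stop("`n_success` must satisfy 0 <= n_success <= n_total", call. = FALSE)
  }
  pct <- 100 * n_success / n_total
  list(percent = pct, percent_rounded = round(pct))
}

#' Cells seeded per tissue
#'
#' Seeding-dose arithmetic: final cell concentration times the cast volume,
#' with the mL/uL conversion handled internally. The platform protocol casts
#' 15 uL of a 16.3e6 cells/mL mix per tissue slot.
#'
#' @param final_concentration Cells per mL of the final cell + ECM mix.
#' @param volume_ul Volume cast per tissue in microliters.
#' @return A list with `cells` (raw) and `cells_3sf` (3 significant figures).
#' @examples
#' seeding_dose(16.3e6, 15)  # 244500 cells, 2.45e5 at 3 s.f.
#' @export
seeding_dose <- function(final_concentration, volume_ul) {
  if (!is.numeric(final_concentration) || final_concentration < 0 ||
      !is.numeric(volume_ul) || volume_ul < 0) {
    stop("inputs must be non-negative numbers", call. = FALSE)
  }
  cells <- final_concentration * volume_ul * 1e-3
  # 3 significant figures with halves rounded away from zero (2.445e5 -> 2.45e5),
  # matching protocol-style reporting rather than signif()'s round-half-even
  cells_3sf <- if (cells == 0) 0 else {
    p <- floor(log10(abs(cells))) - 2
    floor(abs(cells) / 10^p + 0.5) * 10^p * sign(cells)
  }
  list(cells = cells, cells_3sf = cells_3sf)
}
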