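#' Platform geometry for deflection-to-force conversion
#'
#' Holds the constants of the elastic-beam model of one PDMS cantilever
#' together with the optical calibration. The tissue grips the post at height
#' `a` from the base, so a point load there produces a tip deflection
#' `delta = F a^2 (3L - a) / (6 E I)` with `I = pi R^4 / 4`; inverting gives
#' the force from the measured marker deflection.
#'
#' The cantilever length L = 3 mm matches the platform; Young's modulus E,
#' radius R and tissue height a default to values typical for Sylgard 184 at
#' a 1:10 base:curing ratio and this post size, but **must be calibrated by
#' the user** for absolute forces. Every output table records the geometry
#' used.
#'
#' @param E_pa Young's modulus of the PDMS in pascals.
#' @param R_m Cantilever radius in meters.
#' @param L_m Cantilever length in meters (platform default 3 mm).
#' @param a_m Height of the tissue on the cantilever from the base, meters;
#'   must satisfy `0 < a <= L`.
#' @param pixel_size Micrometers per pixel (optical calibration), optional.
#' @param frame_rate Frames per second, optional.
#' @return An object of class `eht_geometry`.
#' @export
platform_geometry <- function(E_pa = 2.0e6, R_m = 0.25e-3, L_m = 3e-3,
                              a_m = 1.5e-3, pixel_size = NULL,
                              frame_rate = NULL) {
  for (nm in c("E_pa", "R_m", "L_m")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("`", nm, "` must be a single positive number", call. = FALSE)
    }
  }
  if (!is.numeric(a_m) || length(a_m) != 1L || !is.finite(a_m) || a_m <= 0) {
    stop("`a_m` must be a single positive number", call. = FALSE)
  }
  if (a_m > L_m) {
    stop("invalid geometry: tissue height a (", a_m,
         " m) exceeds cantilever length L (", L_m, " m)", call. = FALSE)
  }
  structure(list(E_pa = E_pa, R_m = R_m, L_m = L_m, a_m = a_m,
                 pixel_size = pixel_size, frame_rate = frame_rate),
            class = "eht_geometry")
}

#' @export
print.eht_geometry <- function(x, ...) {
  cat(sprintf(
    "<eht_geometry> E = %.4g Pa, R = %.4g m, L = %.4g m, a = %.4g m (k = %.4g uN/um)\n",
    x$E_pa, x$R_m, x$L_m, x$a_m, beam_force(1, x)
  ))
  invisible(x)
}

#' Convert cantilever deflection to contraction force
#'
#' Elastic beam bending: `F = 3 pi E R^4 delta / (2 a^2 (3L - a))`, the
#' inverse of the Euler-Bernoulli tip deflection of a cylindrical cantilever
#' under a point load applied at height `a`. Computation is in strict SI
#' internally; the result is reported in micronewtons.
#'
#' `delta` is the total reduction of the inter-marker distance (both posts
#' bending toward each other); negative values (a post pushed outward, or a
#' mis-estimated baseline) yield negative forces and are reported, not
#' clipped.
#'
#' @param delta_um Deflection in micrometers (scalar or vector).
#' @param geometry An `eht_geometry` from [platform_geometry()].
#' @return Force in micronewtons, same length as `delta_um`.
#' @examples
#' g <- platform_geometry(E_pa = 2e6, R_m = 0.25e-3, L_m = 3e-3, a_m = 1.5e-3)
#' beam_force(20, g)  # force at 20 um deflection
#' @export
beam_force <- function(delta_um, geometry) {
  stopifnot(inherits(geometry, "eht_geometry"))
  delta_m <- delta_um * 1e-6
  F_n <- 3 * pi * geometry$E_pa * geometry$R_m^4 * delta_m /
    (2 * geometry$a_m^2 * (3 * geometry$L_m - geometry$a_m))
  F_n * 1e6  # newtons -> micronewtons
}

#' Apply the beam equation to a deflection trace
#'
#' @param trace An `eht_deflection` from [track_pair()], or any data frame
#'   with `time_s` and `deflection_um` columns.
#' @param geometry An `eht_geometry`.
#' @return An object of class `eht_force`: a data frame with `frame` (if
#'   present), `time_s`, `deflection_um`, `force_uN`; the geometry is
#'   attached as attribute `geometry`, and `identifier`/`frame_rate` are
#'   carried over from the deflection trace when present.
#' @export
force_trace <- function(trace, geometry) {
  stopifnot(is.data.frame(trace))
  if (!all(c("time_s", "deflection_um") %in% names(trace))) {
    stop("`trace` must have `time_s` and `deflection_um` columns", call. = FALSE)
  }
  out <- data.frame(
    time_s = trace$time_s,
    deflection_um = trace$deflection_um,
    force_uN = beam_force(trace$deflection_um, geometry)
  )
  if ("frame" %in% names(trace)) out <- cbind(frame = trace$frame, out)
  structure(out,
            geometry = geometry,
            frame_rate = attr(trace, "frame_rate"),
            identifier = attr(trace, "identifier"),
            class = c("eht_force", "data.frame"))
}
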