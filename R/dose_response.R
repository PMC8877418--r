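#' Absolute inotropic gain relative to the drug-free baseline
#'
#' Differences of the per-recording mean amplitude and velocities between a
#' treated recording and the 0 nM baseline of the same tissue (the
#' isoproterenol protocol: treated minus basal, so negative inotropy is
#' representable as a negative gain).
#'
#' @param baseline,treated `eht_summary` objects from [summarize_recording()]
#'   for the same tissue.
#' @param identifier_baseline,identifier_treated Optional tissue identifiers;
#'   when both are given they must match.
#' @return A list with `gain_force` (uN), `gain_contraction_velocity`,
#'   `gain_relaxation_velocity` (uN/s), and the two summaries.
#' @export
gain_of_force <- function(baseline, treated,
                          identifier_baseline = NULL, identifier_treated = NULL) {
  stopifnot(inherits(baseline, "eht_summary"), inherits(treated, "eht_summary"))
  if (!is.null(identifier_baseline) && !is.null(identifier_treated) &&
      !identical(identifier_baseline, identifier_treated)) {
    stop("pairing error: baseline tissue '", identifier_baseline,
         "' does not match treated tissue '", identifier_treated, "'",
         call. = FALSE)
  }
  list(
    gain_force = unname(treated$mean["amplitude"] - baseline$mean["amplitude"]),
    gain_contraction_velocity =
      unname(treated$mean["contraction_velocity"] - baseline$mean["contraction_velocity"]),
    gain_relaxation_velocity =
      unname(treated$mean["relaxation_velocity"] - baseline$mean["relaxation_velocity"]),
    baseline_summary = baseline,
    treated_summary = treated
  )
}

#' Normalize a concentration series to the 0-concentration amplitude
#'
#' Each tissue's mean amplitude at every concentration is divided by that
#' same tissue's 0-concentration amplitude; tissues are averaged after
#' per-tissue normalization (not before), preserving the within-tissue
#' pairing of the dosing protocol.
#'
#' @param doses A data frame with columns `tissue_id`, `concentration_M` and
#'   `amplitude_uN` (per-recording mean amplitude).
#' @return A list with `concentrations` (sorted ascending, molar),
#'   `normalized_force` (cross-tissue mean of per-tissue normalized
#'   amplitudes) and `per_tissue` (the normalized long table).
#' @export
normalize_dose_series <- function(doses) {
  stopifnot(is.data.frame(doses))
  need <- c("tissue_id", "concentration_M", "amplitude_uN")
  if (!all(need %in% names(doses))) {
    stop("`doses` must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  out <- lapply(split(doses, doses$tissue_id), function(d) {
    base <- d$amplitude_uN[d$concentration_M == 0]
    if (length(base) == 0L) {
      stop("normalization error: tissue '", d$tissue_id[1],
           "' has no 0-concentration baseline", call. = FALSE)
    }
    base <- mean(base)
    if (!is.finite(base) || base <= 0) {
      stop("normalization error: tissue '", d$tissue_id[1],
           "' has non-positive baseline amplitude", call. = FALSE)
    }
    d$normalized_force <- d$amplitude_uN / base
    d
  })
  per_tissue <- do.call(rbind, out)
  rownames(per_tissue) <- NULL
  agg <- stats::aggregate(normalized_force ~ concentration_M, per_tissue, mean)
  agg <- agg[order(agg$concentration_M), ]
  list(concentrations = agg$concentration_M,
       normalized_force = agg$normalized_force,
       per_tissue = per_tissue)
}

#' Fit a descending Hill concentration-response curve
#'
#' Least-squares fit of `r(c) = 1 / (1 + (c / IC50)^h)` (top fixed at 1,
#' bottom at 0 — the response is normalized to the drug-free baseline and
#' L-type calcium block abolishes contraction at saturation), parameterized
#' as `(log10 IC50, h)` and optimized by Levenberg-Marquardt from a
#' multi-start grid of 16 log-spaced IC50 seeds spanning the tested non-zero
#' concentration range (h seeded at 1). The 0-concentration point anchors the
#' normalization but is excluded from the log-concentration fit domain.
#'
#' Failures (too few points, no dose dependence) are returned as a
#' non-converged fit with a diagnostic message, not raised, so batch runs
#' continue.
#'
#' @param concentrations Molar concentrations (may include the 0 anchor).
#' @param normalized_force Responses normalized to the 0-concentration
#'   amplitude.
#' @param weights Optional non-negative fit weights (same length).
#' @param free_bottom If `TRUE`, fit a free lower asymptote
#'   `r(c) = b + (1 - b)/(1 + (c/IC50)^h)` (three parameters).
#' @return An object of class `eht_dose_fit`: a list with `ic50` (molar),
#'   `hill_coefficient`, `bottom`, `residual_rms`, `fit_converged`,
#'   `message`, `concentrations`, `normalized_force`, `fitted`.
#' @export
fit_ic50 <- function(concentrations, normalized_force, weights = NULL,
                     free_bottom = FALSE) {
  stopifnot(length(concentrations) == length(normalized_force))
  fail <- function(msg) {
    structure(list(ic50 = NA_real_, hill_coefficient = NA_real_,
                   bottom = if (free_bottom) NA_real_ else 0,
                   residual_rms = NA_real_, fit_converged = FALSE,
                   message = msg, concentrations = concentrations,
                   normalized_force = normalized_force, fitted = NULL),
              class = "eht_dose_fit")
  }
  nz <- concentrations > 0
  c_nz <- concentrations[nz]
  r_nz <- normalized_force[nz]
  w <- if (is.null(weights)) rep(1, sum(nz)) else weights[nz]
  npar <- if (free_bottom) 3L else 2L
  if (length(unique(c_nz)) < max(4L, npar + 1L)) {
    return(fail(sprintf("too few distinct non-zero concentrations (%d)",
                        length(unique(c_nz)))))
  }
  x <- log10(c_nz)
  # dose dependence: responses must decrease with concentration overall
  sl <- stats::coef(stats::lm(r_nz ~ x, weights = w))[2]
  if (!is.finite(sl) || sl >= 0 || diff(range(r_nz)) < 1e-8) {
    return(fail("no dose dependence: responses are not decreasing with concentration"))
  }

  grid <- seq(min(x), max(x), length.out = 16)
  best <- NULL
  for (p0 in grid) {
    fit <- tryCatch({
      if (free_bottom) {
        minpack.lm::nlsLM(
          r_nz ~ b + (1 - b) / (1 + 10^(h * (x - p))),
          start = list(p = p0, h = 1, b = 0),
          lower = c(p = -Inf, h = 1e-3, b = -0.2),
          upper = c(p = Inf, h = 20, b = 0.9),
          weights = w,
          control = minpack.lm::nls.lm.control(maxiter = 200)
        )
      } else {
        minpack.lm::nlsLM(
          r_nz ~ 1 / (1 + 10^(h * (x - p))),
          start = list(p = p0, h = 1),
          lower = c(p = -Inf, h = 1e-3),
          upper = c(p = Inf, h = 20),
          weights = w,
          control = minpack.lm::nls.lm.control(maxiter = 200)
        )
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(w * stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(fail("optimizer failed from every start"))

  cf <- stats::coef(best$fit)
  ic50 <- 10^unname(cf["p"])
  h <- unname(cf["h"])
  b <- if (free_bottom) unname(cf["b"]) else 0
  pred <- b + (1 - b) / (1 + (c_nz / ic50)^h)
  structure(list(ic50 = ic50, hill_coefficient = h, bottom = b,
                 residual_rms = sqrt(mean((r_nz - pred)^2)),
                 fit_converged = TRUE, message = "ok",
                 concentrations = concentrations,
                 normalized_force = normalized_force,
                 fitted = pred),
            class = "eht_dose_fit")
}

#' Predicted response of a fitted Hill curve
#'
#' @param object An `eht_dose_fit`.
#' @param newdata Optional molar concentrations at which to predict.
#' @param ... Unused.
#' @export
predict.eht_dose_fit <- function(object, newdata = NULL, ...) {
  if (!object$fit_converged) stop("fit did not converge: ", object$message, call. = FALSE)
  cc <- if (is.null(newdata)) object$concentrations else newdata
  b <- object$bottom
  ifelse(cc == 0, 1,
         b + (1 - b) / (1 + (cc / object$ic50)^object$hill_coefficient))
}

#' @export
print.eht_dose_fit <- function(x, ...) {
  if (x$fit_converged) {
    cat(sprintf("<eht_dose_fit> IC50 = %.4g M, h = %.3g, residual RMS = %.3g\n",
                x$ic50, x$hill_coefficient, x$residual_rms))
  } else {
    cat("<eht_dose_fit> fit failure:", x$message, "\n")
  }
  invisible(x)
}
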