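#' Light environment descriptor
#'
#' Describes the ambient light regime of a time-lapse experiment: either
#' constant light at irradiance `A`, or a graded light--dark (LD) cycle in
#' which irradiance follows a half-sinusoid during the light period and is
#' zero otherwise. The graded profile is flux-matched to constant light: its
#' peak is `Imax = 24*A*pi/(2*TL)` so the photon dose over a 24 h day equals
#' `24*A`.
#'
#' Time-of-day convention: dawn corresponds to time of day 12, the convention
#' used throughout the package (see [time_of_day()]). `dawn_offset` gives the
#' experiment time of the first dawn; the default of 12 h reproduces the
#' standard half-sine insolation profile gated on `mod(texp - 12, 24) <= TL`.
#'
#' @param mode `"constant"` or `"graded_LD"`.
#' @param A Mean irradiance over the day (uE m^-2 s^-1). The constant light
#'   level, or the flux-matched daily mean in graded mode.
#' @param TL Duration of the light period in hours (graded mode only),
#'   `0 < TL <= 24`.
#' @param dawn_offset Experiment time (h) at which the first dawn occurs.
#' @return An object of class `"light_profile"`.
#' @seealso [irradiance()], [peak_irradiance()], [time_of_day()]
#' @examples
#' lp <- light_profile("graded_LD", A = 15, TL = 12)
#' lp$Imax # ~47 uE m^-2 s^-1
#' @export
light_profile <- function(mode = c("constant", "graded_LD"), A = 15,
                          TL = 12, dawn_offset = 12) {
  mode <- match.arg(mode)
  if (!is.finite(A) || A < 0)
    stop("invalid light profile: A must be a finite non-negative irradiance")
  obj <- list(mode = mode, A = A, dawn_offset = dawn_offset)
  if (mode == "graded_LD") {
    obj$TL <- TL
    obj$Imax <- peak_irradiance(A, TL)
  }
  structure(obj, class = "light_profile")
}

#' @export
print.light_profile <- function(x, ...) {
  if (x$mode == "constant") {
    cat(sprintf("Constant light, A = %.3g uE/m^2/s\n", x$A))
  } else {
    cat(sprintf(
      "Graded %g:%g LD, mean A = %.3g, peak Imax = %.3g uE/m^2/s, dawn at texp = %g h\n",
      x$TL, 24 - x$TL, x$A, x$Imax, x$dawn_offset))
  }
  invisible(x)
}

#' Peak irradiance of a flux-matched graded LD cycle
#'
#' The half-sine insolation profile with light period `TL` that delivers the
#' same daily photon flux as constant light at irradiance `A` peaks at
#' `Imax = 24*A*pi/(2*TL)`.
#'
#' @param A Constant-light reference irradiance (uE m^-2 s^-1).
#' @param TL Light period duration (h), in (0, 24].
#' @return Peak irradiance (uE m^-2 s^-1).
#' @examples
#' peak_irradiance(15, 12) # ~47
#' @export
peak_irradiance <- function(A, TL) {
  if (!is.finite(TL) || TL <= 0 || TL > 24)
    stop("invalid light profile: TL must satisfy 0 < TL <= 24")
  if (any(!is.finite(A)) || any(A < 0))
    stop("invalid light profile: A must be non-negative")
  24 * A * pi / (2 * TL)
}

#' Ambient irradiance at experiment time
#'
#' Evaluates the light profile at experiment times `texp`. Constant mode
#' returns `A`; graded mode returns `Imax * sin(pi * s / TL)` where
#' `s = mod(texp - dawn_offset, 24)` during the light window `s <= TL`,
#' and 0 in the dark. Periodic with 24 h.
#'
#' @param texp Experiment time(s) in hours.
#' @param profile A [light_profile()].
#' @return Irradiance(s), same length as `texp`.
#' @export
irradiance <- function(texp, profile) {
  stopifnot(inherits(profile, "light_profile"))
  if (profile$mode == "constant") return(rep(profile$A, length(texp)))
  s <- (texp - profile$dawn_offset) %% 24
  ifelse(s <= profile$TL, profile$Imax * sin(pi * s / profile$TL), 0)
}

#' Time of day under the dawn = 12 convention
#'
#' Maps experiment time to circadian time of day in `[0, 24)` with dawn (end
#' of the last dark period of entrainment) at time of day 12, i.e.
#' `tau = mod(texp - dawn_offset + 12, 24)`.
#'
#' @param texp Experiment time(s) in hours.
#' @param dawn_offset Experiment time of the first dawn (h); a
#'   [light_profile()] may be given instead.
#' @return Time(s) of day in `[0, 24)`.
#' @export
time_of_day <- function(texp, dawn_offset = 12) {
  if (inherits(dawn_offset, "light_profile")) dawn_offset <- dawn_offset$dawn_offset
  (texp - dawn_offset + 12) %% 24
}

#' Mean elongation-rate model
#'
#' Describes the mean instantaneous exponential elongation rate alpha(t) of
#' the population. Under constant light the rate oscillates with a circadian
#' period around `alpha_bar`:
#' `alpha(t) = alpha_bar * (1 + epsilon * cos(2*pi*(tau - phase)/24))`.
#' Under LD cycles rates track ambient light linearly: `alpha(t) = c * I(t)`,
#' so growth stops in the dark.
#'
#' @param mode `"constant_light_oscillatory"` or `"light_tracking"`.
#' @param alpha_bar Mean exponential elongation rate (1/h).
#' @param epsilon Relative oscillation amplitude, `0 <= epsilon < 1`.
#' @param phase Time of day (h) at which the oscillation peaks.
#' @param c Conversion slope from irradiance to rate ((1/h) per uE m^-2 s^-1).
#' @return An object of class `"elongation_model"`.
#' @export
elongation_model <- function(mode = c("constant_light_oscillatory", "light_tracking"),
                             alpha_bar = 0.035, epsilon = 0, phase = 18,
                             c = alpha_bar / 15) {
  mode <- match.arg(mode)
  if (alpha_bar < 0) stop("invalid elongation model: alpha_bar must be >= 0")
  if (epsilon < 0 || epsilon >= 1)
    stop("invalid elongation model: epsilon must lie in [0, 1) so alpha(t) >= 0")
  if (c < 0) stop("invalid elongation model: c must be >= 0")
  structure(list(mode = mode, alpha_bar = alpha_bar, epsilon = epsilon,
                 phase = phase, c = c),
            class = "elongation_model")
}

#' Mean exponential elongation rate at experiment time
#'
#' @param texp Experiment time(s) in hours.
#' @param model An [elongation_model()].
#' @param profile A [light_profile()] (supplies the time-of-day convention and,
#'   in light-tracking mode, the irradiance).
#' @return Rate(s) in 1/h; non-negative, periodic with 24 h.
#' @export
mean_elongation_rate <- function(texp, model, profile) {
  stopifnot(inherits(model, "elongation_model"))
  if (model$mode == "constant_light_oscillatory") {
    tau <- time_of_day(texp, profile)
    model$alpha_bar * (1 + model$epsilon * cos(2 * pi * (tau - model$phase) / 24))
  } else {
    model$c * irradiance(texp, profile)
  }
}

#' Upper bound on the elongation rate
#'
#' Supremum of alpha(t) over the day, used as `alpha_max` by the thinning
#' simulator's rate bound.
#'
#' @inheritParams mean_elongation_rate
#' @return A single non-negative rate (1/h).
#' @export
elongation_rate_max <- function(model, profile) {
  if (model$mode == "constant_light_oscillatory") {
    model$alpha_bar * (1 + model$epsilon)
  } else if (profile$mode == "constant") {
    model$c * profile$A
  } else {
    model$c * profile$Imax
  }
}

# Closed-form integral of alpha(t) over [t1, t2] (vectorized over t2).
# Oscillatory mode integrates the cosine analytically; light-tracking mode
# integrates the half-sine insolation piecewise per day.
elongation_integral <- function(t1, t2, model, profile) {
  stopifnot(length(t1) == 1L, all(t2 >= t1 - 1e-12))
  if (model$mode == "constant_light_oscillatory") {
    d <- profile$dawn_offset
    ph <- 2 * pi * (12 - d - model$phase) / 24
    w <- 2 * pi / 24
    model$alpha_bar * ((t2 - t1) +
      model$epsilon / w * (sin(w * t2 + ph) - sin(w * t1 + ph)))
  } else if (profile$mode == "constant") {
    model$c * profile$A * (t2 - t1)
  } else {
    model$c * (cum_insolation(t2, profile) - cum_insolation(t1, profile))
  }
}

# Cumulative insolation from the dawn epoch to experiment time t (vectorized).
cum_insolation <- function(t, profile) {
  u <- t - profile$dawn_offset
  day <- floor(u / 24)
  s <- u - 24 * day
  within_day <- ifelse(
    s <= profile$TL,
    profile$Imax * profile$TL / pi * (1 - cos(pi * s / profile$TL)),
    24 * profile$A)
  24 * profile$A * day + within_day
}
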