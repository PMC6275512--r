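#' Size-control parameters
#'
#' Parameters of the clock-independent cell size control. Added length over a
#' cycle decomposes linearly as `Delta = a * L0 + Delta0`: `a` quantifies the
#' dependence on birth length (`a = 0` adder, `a < 0` sizer-like, `a > 0`
#' timer-like) and the stochastic, birth-length-independent part `Delta0` is
#' governed by a hazard per unit added length
#' `S(d0) = (k/lam) * (d0/lam)^(k-1)` for `d0 > 0` (Weibull form; `k = 1`
#' gives a constant hazard, `k > 1` a hazard increasing with added length).
#' `sigma_zeta` is the cell-to-cell SD of the growth amplitude `zeta`,
#' resampled at each division from Normal(1, sigma_zeta) truncated to
#' positive values.
#'
#' @param a Birth-length coupling (dimensionless).
#' @param k Hazard shape, `k >= 1` (monotone non-decreasing hazard).
#' @param lam Hazard scale in micrometres, `> 0`.
#' @param sigma_zeta SD of the growth amplitude, `>= 0`.
#' @return An object of class `"size_control_params"`.
#' @export
size_control_params <- function(a = -0.1, k = 3, lam = 3.7, sigma_zeta = 0.08) {
  if (!is.finite(k) || k < 1)
    stop("unsupported hazard: shape k must be >= 1 (monotone hazard)")
  if (!is.finite(lam) || lam <= 0) stop("invalid params: lam must be > 0")
  if (sigma_zeta < 0) stop("invalid params: sigma_zeta must be >= 0")
  structure(list(a = a, k = k, lam = lam, sigma_zeta = sigma_zeta),
            class = "size_control_params")
}

#' @export
print.size_control_params <- function(x, ...) {
  cat(sprintf("Size control: a = %.3g, k = %.3g, lam = %.3g um, sigma_zeta = %.3g\n",
              x$a, x$k, x$lam, x$sigma_zeta))
  invisible(x)
}

#' Birth-length-independent part of added length
#'
#' `Delta0 = L - (1 + a) * L0`. May be negative early in the cycle (the
#' hazard is then zero).
#'
#' @param L Current length(s) (um).
#' @param L0 Birth length(s) (um), `> 0`.
#' @param a Birth-length coupling.
#' @return `Delta0` value(s) in um.
#' @export
delta0 <- function(L, L0, a) {
  if (any(!is.finite(L0)) || any(L0 <= 0))
    stop("invalid state: birth length L0 must be positive")
  L - (1 + a) * L0
}

#' Size-control hazard per unit added length
#'
#' `S(d0) = (k/lam) * (d0/lam)^(k-1)` for `d0 > 0`, and 0 for `d0 <= 0`;
#' non-decreasing for `k >= 1`.
#'
#' @param d0 Birth-length-independent added length(s) (um).
#' @param params A [size_control_params()].
#' @return Hazard value(s), per um.
#' @export
size_hazard <- function(d0, params) {
  ifelse(d0 > 0, (params$k / params$lam) * (pmax(d0, 0) / params$lam)^(params$k - 1), 0)
}

# Cumulative size hazard H(d0) = integral of S from 0 to d0 = (d0/lam)^k.
cum_size_hazard <- function(d0, params) {
  (pmax(d0, 0) / params$lam)^params$k
}

#' Cell state
#'
#' Instantaneous state of a growing cell: current length, birth length, growth
#' amplitude and experiment time.
#'
#' @param L Current length (um).
#' @param L0 Birth length (um).
#' @param zeta Growth amplitude (dimensionless, positive).
#' @param t Experiment time (h).
#' @return An object of class `"cell_state"`.
#' @export
cell_state <- function(L, L0, zeta = 1, t = 0) {
  if (!is.finite(L0) || L0 <= 0) stop("invalid state: L0 must be positive")
  if (!is.finite(L) || L <= 0) stop("invalid state: L must be positive")
  if (!is.finite(zeta) || zeta <= 0) stop("invalid state: zeta must be positive")
  structure(list(L = L, L0 = L0, zeta = zeta, t = t), class = "cell_state")
}

#' Instantaneous division rate
#'
#' The model's division rate
#' `Gamma = S(Delta0(L, L0)) * G(tau(t)) * zeta * alpha * L`,
#' the product of the size-control hazard, the circadian coupling at the time
#' of day of `state$t`, and the elongation rate `dL/dt = zeta * alpha * L`.
#' Zero whenever `alpha = 0` (dark) or `Delta0 <= 0`.
#'
#' @param state A [cell_state()].
#' @param G A [coupling_function()].
#' @param alpha Mean exponential elongation rate at `state$t` (1/h), `>= 0`.
#' @param params A [size_control_params()].
#' @param dawn_offset Experiment time of dawn (h) fixing the time-of-day
#'   convention; a [light_profile()] may be given.
#' @return Division rate in 1/h.
#' @export
division_rate <- function(state, G, alpha, params, dawn_offset = 12) {
  stopifnot(inherits(state, "cell_state"), alpha >= 0)
  d0 <- delta0(state$L, state$L0, params$a)
  size_hazard(d0, params) *
    coupling_eval(time_of_day(state$t, dawn_offset), G) *
    state$zeta * alpha * state$L
}

#' Effective coupling function
#'
#' The time-dependent part of the division rate, `G(tau(texp)) * alpha(texp)`,
#' combining circadian modulation with light-driven growth-rate modulation.
#' Zero in the dark; reduces to `alpha(texp)` for the clock-deletion model
#' `G == 1`.
#'
#' @param texp Experiment time(s) in hours.
#' @param G A [coupling_function()].
#' @param model An [elongation_model()].
#' @param profile A [light_profile()].
#' @return Effective coupling value(s) in 1/h.
#' @export
effective_coupling <- function(texp, G, model, profile) {
  coupling_eval(time_of_day(texp, profile), G) *
    mean_elongation_rate(texp, model, profile)
}
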