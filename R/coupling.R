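#' Circadian coupling function G(t)
#'
#' The coupling function is a strictly positive, smooth, 24 h-periodic
#' multiplier on the division rate that encodes circadian modulation of cell
#' division. It is parametrized by its log-values at a set of knot times of
#' day and evaluated by periodic cubic-spline interpolation of the log-values,
#' exponentiated -- positivity and periodicity hold by construction.
#' `G == 1` everywhere models clock-deletion cells.
#'
#' `Gmax` is an upper bound on G required by the thinning simulator; by
#' default it is 1.5 times the maximum of G over a dense grid.
#'
#' @param log_values Log-coupling values at the knots.
#' @param knot_times Knot times of day in `[0, 24)`, at least 4, strictly
#'   increasing. Default: 8 equispaced knots.
#' @param Gmax Optional upper bound; computed from the spline if omitted.
#' @return An object of class `"coupling_function"`.
#' @examples
#' G1 <- constant_coupling(1)
#' coupling_eval(c(0, 6, 12), G1)
#' @export
coupling_function <- function(log_values, knot_times = seq(0, 21, by = 3),
                              Gmax = NULL) {
  if (length(knot_times) < 4)
    stop("invalid coupling: need at least 4 knots covering [0, 24)")
  if (length(log_values) != length(knot_times))
    stop("invalid coupling: log_values and knot_times lengths differ")
  if (is.unsorted(knot_times, strictly = TRUE) ||
      any(knot_times < 0) || any(knot_times >= 24))
    stop("invalid coupling: knot_times must be strictly increasing in [0, 24)")
  if (any(!is.finite(log_values)))
    stop("invalid coupling: non-finite log_values")
  fn <- stats::splinefun(c(knot_times, knot_times[1] + 24),
                         c(log_values, log_values[1]),
                         method = "periodic")
  if (is.null(Gmax)) {
    grid <- seq(0, 24, by = 0.05)
    Gmax <- 1.5 * max(exp(fn(grid)))
  }
  structure(list(knot_times = knot_times, log_values = log_values,
                 Gmax = Gmax, spline = fn),
            class = "coupling_function")
}

#' Evaluate a coupling function at times of day
#'
#' Periodic cubic interpolation of the knot log-values, exponentiated; exact
#' at the knots and satisfying `G(tau) = G(tau + 24)`.
#'
#' @param tau Time(s) of day in hours (any real; reduced modulo 24).
#' @param G A [coupling_function()].
#' @return Positive coupling value(s).
#' @export
coupling_eval <- function(tau, G) {
  UseMethod("coupling_eval", G)
}

#' @export
coupling_eval.coupling_function <- function(tau, G) {
  exp(G$spline(tau %% 24))
}

#' @export
print.coupling_function <- function(x, ...) {
  cat(sprintf("Periodic coupling function: %d knots, range [%.3g, %.3g], Gmax = %.3g\n",
              length(x$knot_times), min(exp(x$log_values)),
              max(exp(x$log_values)), x$Gmax))
  invisible(x)
}

#' Constant coupling (clock-deletion model)
#'
#' @param value The constant value, default 1 (the clock-deletion reference).
#' @param knot_times Knot grid on which the constant is represented.
#' @return A [coupling_function()] equal to `value` everywhere.
#' @export
constant_coupling <- function(value = 1, knot_times = seq(0, 21, by = 3)) {
  coupling_function(rep(log(value), length(knot_times)), knot_times,
                    Gmax = 1.5 * value)
}

#' Smooth single-peaked coupling function
#'
#' A circular-Gaussian bump on the coupling scale,
#' `G(tau) = basal + (height - basal) * exp(-d(tau)^2 / (2 * width^2))` with
#' `d` the circular distance to `peak_time`, sampled at the knots and
#' represented as a periodic spline. The default emulates wild-type
#' modulation: low basal coupling through subjective night and early day and
#' a peak a few hours before subjective dusk, about threefold above the
#' clock-deletion reference level of 1.
#'
#' @param peak_time Time of day of the peak (h); default 22.
#' @param height Peak coupling value; default 3.
#' @param basal Basal coupling value; default 0.5.
#' @param width Gaussian width of the bump (h); default 2.5.
#' @param knot_times Knot grid.
#' @return A [coupling_function()].
#' @export
coupling_bump <- function(peak_time = 22, height = 3, basal = 0.25,
                          width = 3, knot_times = seq(0, 21, by = 3)) {
  stopifnot(height > 0, basal > 0, width > 0)
  d <- circ_dist(knot_times, peak_time)
  g <- basal + (height - basal) * exp(-d^2 / (2 * width^2))
  coupling_function(log(g), knot_times)
}

#' On-off gate coupling shapes (benchmark alternatives)
#'
#' Classical gating models restrict division to a permissive window instead of
#' modulating it continuously. These fixed shapes are provided as benchmark
#' couplings for simulation-based comparison; they are not inferred.
#' `smooth = 0` gives a piecewise square gate; `smooth > 0` applies
#' logistic shoulders of that width (h).
#'
#' @param open_start,open_end Times of day (h) delimiting the open window
#'   (wrapping across midnight allowed).
#' @param high,low Coupling values inside/outside the window.
#' @param smooth Shoulder width in hours; 0 for a hard square gate.
#' @return An object of classes `"coupling_gate"`, `"coupling_function"`.
#' @export
coupling_gate <- function(open_start = 16, open_end = 24, high = 2,
                          low = 0.1, smooth = 0) {
  stopifnot(high > 0, low > 0, smooth >= 0)
  structure(list(open_start = open_start %% 24, open_end = open_end %% 24,
                 high = high, low = low, smooth = smooth,
                 Gmax = 1.5 * high),
            class = c("coupling_gate", "coupling_function"))
}

#' @export
coupling_eval.coupling_gate <- function(tau, G) {
  tau <- tau %% 24
  inside <- if (G$open_start <= G$open_end) {
    tau >= G$open_start & tau < G$open_end
  } else {
    tau >= G$open_start | tau < G$open_end
  }
  if (G$smooth == 0) return(ifelse(inside, G$high, G$low))
  # logistic shoulders via circular distances to the two edges
  rise <- stats::plogis(signed_circ_dist(tau, G$open_start) / G$smooth)
  fall <- stats::plogis(-signed_circ_dist(tau, G$open_end) / G$smooth)
  w <- if (G$open_start <= G$open_end) pmin(rise, fall) else pmax(rise, fall)
  G$low + (G$high - G$low) * w
}

#' Shift a coupling function in time of day
#'
#' Returns the coupling `G(tau - shift)`. The package anchors the clock state
#' so that dawn maps to time of day 12 in every light regime (dawn reset);
#' under long photoperiods an entrained clock may instead track midday, which
#' corresponds to a positive shift of the coupling. This helper exposes that
#' phase offset without changing the default convention.
#'
#' @param G A [coupling_function()] (spline-based).
#' @param shift Hours by which the coupling is delayed.
#' @return A [coupling_function()].
#' @export
shift_coupling <- function(G, shift) {
  stopifnot(inherits(G, "coupling_function"))
  knots <- G$knot_times
  fn <- G$spline
  coupling_function(fn((knots - shift) %% 24), knots, Gmax = G$Gmax)
}

# circular distance in hours on the 24 h circle
circ_dist <- function(x, y) {
  d <- abs((x - y) %% 24)
  pmin(d, 24 - d)
}

# signed circular offset of x past y, in (-12, 12]
signed_circ_dist <- function(x, y) {
  d <- (x - y) %% 24
  ifelse(d > 12, d - 24, d)
}

# Design matrix mapping knot log-values to interpolated log G at query times:
# column k is the periodic spline through the k-th unit vector. Interpolation
# is linear in the knot values, so log G(tau) = M %*% log_values exactly.
coupling_design_matrix <- function(tau, knot_times = seq(0, 21, by = 3)) {
  K <- length(knot_times)
  tau <- tau %% 24
  M <- matrix(0, length(tau), K)
  for (k in seq_len(K)) {
    e <- rep(0, K); e[k] <- 1
    fn <- stats::splinefun(c(knot_times, knot_times[1] + 24), c(e, e[1]),
                           method = "periodic")
    M[, k] <- fn(tau)
  }
  M
}
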