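#' Modal division phase of a population
#'
#' Circular mean time of day of divisions, the phase around which divisions
#' concentrate in a gated (or light-driven) population. Serves as the natural
#' origin of the division cycle for phase-aligned analyses.
#'
#' @param cells Cell table.
#' @param dawn_offset Dawn convention (h) or a [light_profile()].
#' @return Time of day (h) in `[0, 24)`.
#' @export
division_phase <- function(cells, dawn_offset = 12) {
  taud <- time_of_day(cells$division_time_h[cells$censored == 0 &
                                              !is.na(cells$division_time_h)],
                      dawn_offset)
  if (!length(taud)) stop("no divisions in cell table")
  ang <- atan2(mean(sin(2 * pi * taud / 24)), mean(cos(2 * pi * taud / 24)))
  (ang * 24 / (2 * pi)) %% 24
}

circular_mean_tau <- function(tau) {
  (atan2(mean(sin(2 * pi * tau / 24)),
         mean(cos(2 * pi * tau / 24))) * 24 / (2 * pi)) %% 24
}

#' Cluster cells into fast and slow subpopulations
#'
#' Detects the fast/slow subpopulation structure that circadian gating
#' imprints on time of day at birth and cell cycle duration. Both features
#' are combined into the phase-aligned duration residual
#' `r = duration - ((T_peak - tau_birth) mod 24)`, the cycle duration in
#' excess of the time from birth to the population's modal division phase
#' `T_peak` (see [division_phase()]): cells dividing at the first reachable
#' peak have `r ~ 0`, cells waiting a further day `r ~ 24`. Gaussian mixtures
#' with 1 and 2 components are fitted to `r`; two subpopulations are declared
#' when the 2-component model improves BIC by more than `bic_margin` (default
#' 10, conventional strong evidence). The component with the smaller mean
#' cycle duration is labelled `"fast"`.
#'
#' @param cells Cell table with at least 100 uncensored cells.
#' @param dawn_offset Dawn convention (h) or a [light_profile()].
#' @param seed Integer seed (mixture initialisation).
#' @param bic_margin Required BIC improvement of the 2-component model.
#' @return A list of class `"cg_clustering"`: `labels` (data.frame `cell_id`,
#'   `label`, `posterior_prob`), `n_components`, `bic` (named BIC values; in
#'   mclust convention, larger is better), `means` (per-component circular
#'   mean birth time of day and mean duration), `division_peak_tau`, and the
#'   fitted `model`.
#' @importFrom mclust Mclust mclustBIC priorControl
#' @export
cluster_subpopulations <- function(cells, dawn_offset = 12, seed = 1,
                                   bic_margin = 10) {
  cc <- cells[cells$censored == 0 & !is.na(cells$division_time_h), ]
  dur <- cc$division_time_h - cc$birth_time_h
  cc <- cc[dur > 0, ]
  dur <- dur[dur > 0]
  if (nrow(cc) < 100)
    stop("clustering error: need at least 100 uncensored cells")
  tau_b <- time_of_day(cc$birth_time_h, dawn_offset)
  t_peak <- division_phase(cc, dawn_offset)
  r <- matrix(dur - ((t_peak - tau_b) %% 24), ncol = 1)
  set.seed(seed)
  fit <- tryCatch(
    mclust::Mclust(r, G = 1:2, verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("degenerate fit; refitting with a regularizing prior")
    fit <- mclust::Mclust(r, G = 1:2, verbose = FALSE,
                          prior = mclust::priorControl())
  }
  bic_tab <- apply(fit$BIC, 1, max, na.rm = TRUE)
  ncomp <- if (bic_tab["2"] - bic_tab["1"] > bic_margin) 2L else 1L
  if (ncomp == 2) {
    fit2 <- if (fit$G == 2) fit else mclust::Mclust(r, G = 2, verbose = FALSE)
    mean_dur <- tapply(dur, fit2$classification, mean)
    fast_comp <- as.integer(names(which.min(mean_dur)))
    label <- ifelse(fit2$classification == fast_comp, "fast", "slow")
    pp <- fit2$z[cbind(seq_len(nrow(r)), fit2$classification)]
    fit <- fit2
  } else {
    label <- rep("fast", nrow(r))
    pp <- rep(1, nrow(r))
  }
  comp_means <- do.call(rbind, lapply(split(seq_along(label), label), function(i)
    data.frame(mean_birth_tau = circular_mean_tau(tau_b[i]),
               mean_duration_h = mean(dur[i]), n = length(i))))
  structure(list(labels = data.frame(cell_id = cc$cell_id, label = label,
                                     posterior_prob = pp),
                 n_components = ncomp, bic = bic_tab, means = comp_means,
                 division_peak_tau = t_peak, model = fit),
            class = "cg_clustering")
}

#' @export
print.cg_clustering <- function(x, ...) {
  cat(sprintf("Subpopulation clustering: %d component(s) selected by BIC\n",
              x$n_components))
  print(x$means)
  invisible(x)
}

#' Classify a size-control slope
#'
#' Labels a regression of added length on birth length: adder-like if the
#' confidence interval contains 0; otherwise sizer-like for negative slopes
#' (toward -1) and timer-like for positive slopes (toward +1).
#'
#' @param slope Estimated slope, or a `"cg_regression"`.
#' @param ci Length-2 confidence interval for the slope.
#' @return A list of class `"size_control_classification"`: `slope`, `ci`,
#'   `label`.
#' @export
classify_size_control <- function(slope, ci = NULL) {
  if (inherits(slope, "cg_regression")) {
    ci <- slope$ci
    slope <- slope$slope
  }
  if (!is.finite(slope) || any(!is.finite(ci)))
    stop("classification error: non-finite slope or interval")
  label <- if (ci[1] <= 0 && 0 <= ci[2]) "adder-like"
           else if (slope < 0) "sizer-like" else "timer-like"
  structure(list(slope = slope, ci = ci, label = label),
            class = "size_control_classification")
}

#' @export
print.size_control_classification <- function(x, ...) {
  cat(sprintf("%s (slope %.3f [%.3f, %.3f])\n", x$label, x$slope,
              x$ci[1], x$ci[2]))
  invisible(x)
}

#' Central division-time window after dawn
#'
#' The central interval of division times, measured in hours after the most
#' recent dawn, covering a given fraction of divisions (e.g. the window
#' within which 90% of cells divide).
#'
#' @param cells Cell table (uncensored cells are used).
#' @param coverage Fraction of divisions to cover, in (0, 1).
#' @param dawn_offset Dawn convention (h) or a [light_profile()].
#' @return Named numeric `c(t_lo, t_hi)` in hours after dawn.
#' @export
division_time_window <- function(cells, coverage = 0.9, dawn_offset = 12) {
  if (coverage <= 0 || coverage >= 1) stop("coverage must be in (0, 1)")
  if (inherits(dawn_offset, "light_profile")) dawn_offset <- dawn_offset$dawn_offset
  td <- cells$division_time_h[cells$censored == 0 & !is.na(cells$division_time_h)]
  if (!length(td)) stop("no divisions in cell table")
  after_dawn <- (td - dawn_offset) %% 24
  q <- stats::quantile(after_dawn, c((1 - coverage) / 2, 1 - (1 - coverage) / 2))
  c(t_lo = unname(q[1]), t_hi = unname(q[2]))
}

#' Regression of added length on birth time of day
#'
#' OLS of added length on the time of birth within the day, optionally
#' restricted to a subpopulation. A negative slope means cells born later in
#' the day add less length before dividing. Time of birth is a circular
#' quantity; to regress on it linearly the day must be cut somewhere. With
#' `origin = "division_peak"` (default) it is cut at the population's modal
#' division phase -- the natural start of the division cycle in a gated
#' population, placing the discontinuity where the fewest fast-subpopulation
#' births occur; `origin = "dawn"` cuts at dawn instead.
#'
#' @param cells Cell table.
#' @param subset_ids Optional cell ids (e.g. one label group from
#'   [cluster_subpopulations()]).
#' @param dawn_offset Dawn convention (h) or a [light_profile()].
#' @param origin Where the circular birth-time axis is cut.
#' @param conf Confidence level.
#' @return A list of class `"cg_regression"`: `slope` (um/h), `intercept`,
#'   `ci`, `n`, `fit`.
#' @export
added_vs_time_regression <- function(cells, subset_ids = NULL,
                                     dawn_offset = 12,
                                     origin = c("division_peak", "dawn"),
                                     conf = 0.95) {
  origin <- match.arg(origin)
  cc <- cells[cells$censored == 0 & !is.na(cells$division_length_um), ]
  cut_at <- if (origin == "division_peak") division_phase(cc, dawn_offset) else 12
  if (!is.null(subset_ids)) cc <- cc[cc$cell_id %in% subset_ids, ]
  if (nrow(cc) < 10) stop("regression error: need at least 10 cells in subset")
  x <- (time_of_day(cc$birth_time_h, dawn_offset) - cut_at) %% 24
  if (stats::sd(x) < 1e-12) stop("regression error: degenerate birth-time variance")
  y <- cc$division_length_um - cc$birth_length_um
  fit <- stats::lm(y ~ x)
  ci <- stats::confint(fit, "x", level = conf)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 ci = c(ci[1], ci[2]), n = nrow(cc), fit = fit),
            class = "cg_regression")
}

#' Cell cycle duration histogram and same-day/next-day split
#'
#' Histogram of cell cycle durations. Cells are additionally labelled
#' same-day or next-day dividers according to whether birth and division fall
#' in the same dawn-to-dawn day, and summarised per subpopulation label if
#' one is supplied.
#'
#' @param cells Cell table.
#' @param bin_h Histogram bin width (h).
#' @param dawn_offset Dawn convention (h) or a [light_profile()].
#' @param labels Optional label data.frame from [cluster_subpopulations()].
#' @return A list of class `"cg_duration_histogram"`: `histogram` (data.frame
#'   `mid`, `count`), `cells` (per-cell `duration_h`, `day_label`), and
#'   `summary` (per group: n, mean and median duration).
#' @export
cycle_duration_histogram <- function(cells, bin_h = 1, dawn_offset = 12,
                                     labels = NULL) {
  if (inherits(dawn_offset, "light_profile")) dawn_offset <- dawn_offset$dawn_offset
  cc <- cells[cells$censored == 0 & !is.na(cells$division_time_h), ]
  if (!nrow(cc)) stop("no uncensored cells")
  dur <- cc$division_time_h - cc$birth_time_h
  day_b <- floor((cc$birth_time_h - dawn_offset) / 24)
  day_d <- floor((cc$division_time_h - dawn_offset) / 24)
  day_label <- ifelse(day_b == day_d, "same_day", "next_day")
  breaks <- seq(0, max(dur) + bin_h, by = bin_h)
  h <- graphics::hist(dur, breaks = breaks, plot = FALSE)
  per_cell <- data.frame(cell_id = cc$cell_id, duration_h = dur,
                         day_label = day_label)
  grp <- day_label
  if (!is.null(labels)) {
    lab <- labels$label[match(cc$cell_id, labels$cell_id)]
    per_cell$label <- lab
    grp <- lab
  }
  summ <- do.call(rbind, lapply(split(dur, grp), function(d)
    data.frame(n = length(d), mean_h = mean(d), median_h = stats::median(d))))
  summ$group <- rownames(summ)
  structure(list(histogram = data.frame(mid = h$mids, count = h$counts),
                 cells = per_cell, summary = summ),
            class = "cg_duration_histogram")
}

#' @export
print.cg_duration_histogram <- function(x, ...) {
  print(x$summary[, c("group", "n", "mean_h", "median_h")], row.names = FALSE)
  invisible(x)
}
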