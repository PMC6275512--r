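#' Ordinary regression of added length on birth length
#'
#' The classical size-control diagnostic: OLS of `L_div - L_birth` on
#' `L_birth` over uncensored cells. A slope of 0 indicates an adder, -1 a
#' sizer, +1 a timer.
#'
#' @param cells A cell table (see [read_cell_table()] for the schema).
#' @param conf Confidence level for the slope interval.
#' @return A list of class `"cg_regression"`: `slope`, `intercept`, `ci`
#'   (slope confidence interval), `n`, and the underlying `lm` fit.
#' @export
regress_added_vs_birth <- function(cells, conf = 0.95) {
  cc <- cells[cells$censored == 0 & !is.na(cells$division_length_um), ]
  if (nrow(cc) < 10) stop("regression error: need at least 10 uncensored cells")
  x <- cc$birth_length_um
  if (stats::sd(x) < 1e-12) stop("regression error: degenerate birth-length variance")
  y <- cc$division_length_um - x
  fit <- stats::lm(y ~ x)
  ci <- stats::confint(fit, "x", level = conf)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 ci = c(ci[1], ci[2]), n = nrow(cc), fit = fit),
            class = "cg_regression")
}

#' @export
print.cg_regression <- function(x, ...) {
  cat(sprintf("Added vs birth length: slope = %.3f [%.3f, %.3f], intercept = %.3f um, n = %d\n",
              x$slope, x$ci[1], x$ci[2], x$intercept, x$n))
  invisible(x)
}

# Discrete life-table hazard with delayed entry: entry/exit coordinates and an
# event indicator; hazard in bin [b_j, b_{j+1}) is d_j / (dx * n_j) with n_j
# the number at risk at b_j (entered, not yet exited).
lifetable_hazard <- function(entry, exit, event, breaks) {
  dx <- diff(breaks)
  lo <- breaks[-length(breaks)]
  n_at_risk <- vapply(lo, function(b) sum(entry <= b & exit > b), 0L)
  bin <- findInterval(exit[event], breaks, rightmost.closed = FALSE)
  d <- tabulate(bin[bin >= 1 & bin <= length(lo)], nbins = length(lo))
  hazard <- ifelse(n_at_risk > 0, d / (dx * n_at_risk), NA_real_)
  list(hazard = hazard, n_at_risk = n_at_risk, d = d)
}

#' Empirical size-control hazard by birth-length stratum
#'
#' Life-table estimate of the division hazard per unit added length within
#' birth-length strata, with cell-level bootstrap confidence intervals.
#' On the added-length scale (`x_scale = "added"`) cells enter at 0 and exit
#' at their added length; on the `"delta0"` scale the coordinate is
#' `Delta0 = L - (1 + a) * L0`, cells enter at `-a * L0` (delayed entry when
#' `a < 0`) and per-stratum curves collapse onto the single function
#' `S(Delta0)` when size control depends on `Delta0` only.
#'
#' @param cells A cell table.
#' @param birth_bins Birth-length stratum boundaries (um).
#' @param dx Bin width on the hazard coordinate (um).
#' @param x_scale `"added"` or `"delta0"`.
#' @param a Birth-length coupling used for the `"delta0"` scale.
#' @param n_boot Bootstrap resamples (over cells) for percentile intervals.
#' @param conf Confidence level.
#' @param x_max Upper end of the hazard grid; defaults to the 99th percentile
#'   of exit values.
#' @return A list of class `"cg_hazard"`, one element per non-empty stratum:
#'   a data.frame with `grid` (bin centres), `hazard`, `ci_low`, `ci_high`,
#'   `n_at_risk`; bins never at risk are `NA` (undefined). The stratum
#'   interval is in attribute `"birth_bin"`.
#' @export
empirical_hazard <- function(cells, birth_bins = c(2.4, 2.8, 3.2, 3.6, 4.0),
                             dx = 0.2, x_scale = c("added", "delta0"), a = 0,
                             n_boot = 1000, conf = 0.95, x_max = NULL) {
  x_scale <- match.arg(x_scale)
  if (dx <= 0) stop("invalid dx")
  use <- !is.na(cells$birth_length_um)
  if (sum(cells$censored == 0, na.rm = TRUE) < 50)
    stop("estimation error: need at least 50 uncensored cells")
  cc <- cells[use, ]
  Lb <- cc$birth_length_um
  Lx <- ifelse(cc$censored == 0, cc$division_length_um, NA)
  # censored cells exit (without event) at their last observed length if known
  event <- cc$censored == 0
  Lx[!event] <- cc$birth_length_um[!event]  # conservative: no trace info here
  if (x_scale == "added") {
    entry <- rep(0, nrow(cc))
    exit <- Lx - Lb
  } else {
    entry <- -a * Lb
    exit <- Lx - (1 + a) * Lb
  }
  ok <- is.finite(exit) & exit > entry
  entry <- entry[ok]; exit <- exit[ok]; event <- event[ok]; Lb <- Lb[ok]
  if (is.null(x_max)) x_max <- stats::quantile(exit, 0.99)
  breaks <- seq(min(0, min(entry)), x_max + dx, by = dx)
  strata <- cut(Lb, birth_bins, include.lowest = TRUE)
  out <- list()
  alpha <- (1 - conf) / 2
  for (s in levels(strata)) {
    idx <- which(strata == s)
    if (length(idx) == 0) {
      warning("empty birth-length stratum ", s, "; skipped")
      next
    }
    est <- lifetable_hazard(entry[idx], exit[idx], event[idx], breaks)
    boot <- matrix(NA_real_, n_boot, length(est$hazard))
    for (b in seq_len(n_boot)) {
      rs <- sample(idx, length(idx), replace = TRUE)
      boot[b, ] <- lifetable_hazard(entry[rs], exit[rs], event[rs], breaks)$hazard
    }
    df <- data.frame(
      grid = breaks[-length(breaks)] + dx / 2,
      hazard = est$hazard,
      ci_low = apply(boot, 2, stats::quantile, alpha, na.rm = TRUE),
      ci_high = apply(boot, 2, stats::quantile, 1 - alpha, na.rm = TRUE),
      n_at_risk = est$n_at_risk)
    attr(df, "birth_bin") <- s
    out[[s]] <- df
  }
  structure(out, class = "cg_hazard", x_scale = x_scale)
}

# Half-frame growth correction: extrapolate exponential growth half an
# acquisition interval beyond the recorded division frame and back before the
# recorded birth frame, using the cell's own average rate.
half_frame_correct <- function(Lb, Ld, tb, td, dt_acq) {
  r <- log(Ld / Lb) / pmax(td - tb, dt_acq)
  list(Lb = Lb * exp(-r * dt_acq / 2), Ld = Ld * exp(r * dt_acq / 2))
}

#' Maximum-likelihood estimation of size-control parameters
#'
#' Fits `(a, k, lam)` of the linear size-control model by maximising the
#' likelihood of the birth-length-independent added length. For a divided
#' cell the log-likelihood is `log S(d0_div) - [H(d0_div) - H(d0_birth)]`
#' where `H` is the cumulative hazard `(d0/lam)^k` (zero for negative
#' arguments) and `d0_birth = -a * L_birth` accounts for hazard accrued from
#' birth (relevant for sizer-like control, `a < 0`). Censored cells
#' contribute survival terms. The `half_frame` correction compensates the
#' discrete observation convention -- division lengths recorded one frame
#' before division, birth lengths one frame after -- by extrapolating
#' exponential growth half an acquisition interval outward on both ends;
#' without it the estimated `a` is biased towards the sizer direction.
#'
#' When the measurement-noise SD of frame lengths is known (as in simulation
#' studies, or from repeated segmentation of the same frames), supplying
#' `noise_sd > 0` replaces the sharp likelihood by its convolution with the
#' induced Gaussian error on `d0` (Gauss-Hermite quadrature), removing the
#' attenuation bias on `a` that noisy birth lengths otherwise cause.
#'
#' @param cells A cell table (at least 100 uncensored cells).
#' @param correction `"half_frame"` (default) or `"none"`.
#' @param dt_acq Acquisition interval (h); inferred from the recorded time
#'   grid if omitted.
#' @param noise_sd Known measurement-noise SD on lengths (um); 0 disables the
#'   noise convolution.
#' @param conf Confidence level of the profile-likelihood intervals.
#' @param a_starts Multi-start grid for `a`.
#' @return A list of class `"size_control_fit"`: `params` (a
#'   [size_control_params()] with the MLEs), `estimates`, `ci` (profile
#'   likelihood), `logLik`, `n`, `correction`.
#' @export
fit_size_control <- function(cells, correction = c("half_frame", "none"),
                             dt_acq = NULL, noise_sd = 0, conf = 0.95,
                             a_starts = seq(-0.8, 0.4, by = 0.2)) {
  correction <- match.arg(correction)
  cc <- cells[cells$censored == 0 & !is.na(cells$division_length_um), ]
  if (nrow(cc) < 100)
    stop("estimation error: need at least 100 uncensored cells")
  cens <- cells[cells$censored == 1, ]
  if (is.null(dt_acq)) {
    tt <- sort(unique(c(cells$birth_time_h, cells$division_time_h)))
    dt_acq <- min(diff(tt)[diff(tt) > 1e-9])
  }
  Lb <- cc$birth_length_um; Ld <- cc$division_length_um
  if (correction == "half_frame") {
    adj <- half_frame_correct(Lb, Ld, cc$birth_time_h, cc$division_time_h, dt_acq)
    Lb <- adj$Lb; Ld <- adj$Ld
  }
  LbC <- cens$birth_length_um
  # censored exit length: last observed length is not in the table; use birth
  # length (their survival contribution from birth onward is then zero).
  gh <- gauss_hermite(21)
  nll <- function(par) {
    a <- par[1]; k <- exp(par[2]); lam <- exp(par[3])
    if (k > 50) return(1e10)
    d0b <- pmax(-a * Lb, 0)
    d0d <- Ld - (1 + a) * Lb
    H <- function(x) (pmax(x, 0) / lam)^k
    if (noise_sd > 0) {
      # Convolve the division density in d0 with the Gaussian error induced
      # by frame-length noise. The density g(x) = S(x) exp(-(H(x) - H(d0b)))
      # is truncated at the entry boundary b = max(d0b, 0); evaluating the
      # Gauss-Hermite sum with the argument clamped at b and subtracting the
      # exact boundary mass g(b) * Phi((b - y)/su) keeps the integrand (and
      # hence the likelihood) continuous in the parameters.
      su <- noise_sd * sqrt(1 + (1 + a)^2)
      g <- function(x) (k / lam) * (pmax(x, 1e-12) / lam)^(k - 1) *
        exp(-(H(x) - H(d0b)))
      f <- 0
      for (i in seq_along(gh$x)) {
        xi <- d0d - sqrt(2) * su * gh$x[i]
        f <- f + gh$w[i] * g(pmax(xi, d0b))
      }
      f <- f / sqrt(pi) - g(d0b) * stats::pnorm((d0b - d0d) / su)
      ll <- sum(log(pmax(f, 1e-300)))
    } else {
      if (any(d0d <= 0)) return(1e10)
      ll <- sum(log(k) - k * log(lam) + (k - 1) * log(d0d)) -
        sum(H(d0d) - H(d0b))
    }
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  best <- NULL
  for (a0 in a_starts) {
    d0 <- cc$division_length_um - (1 + a0) * cc$birth_length_um
    d0 <- d0[d0 > 0]
    if (length(d0) < 10) next
    lam0 <- mean(d0); k0 <- max(1, (mean(d0) / stats::sd(d0))^1.086)
    fit <- tryCatch(
      stats::optim(c(a0, log(k0), log(lam0)), nll, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best) || best$value >= 1e9)
    stop("estimation error: size-control likelihood failed to converge")
  mle <- best$par
  est <- c(a = mle[1], k = exp(mle[2]), lam = exp(mle[3]))
  ci <- rbind(a = profile_ci(nll, mle, 1, conf, identity),
              k = profile_ci(nll, mle, 2, conf, exp),
              lam = profile_ci(nll, mle, 3, conf, exp))
  colnames(ci) <- c("lower", "upper")
  structure(list(params = size_control_params(est["a"], max(est["k"], 1),
                                              est["lam"], sigma_zeta = 0),
                 estimates = est, ci = ci, logLik = -best$value,
                 n = nrow(cc), n_censored = nrow(cens),
                 correction = correction, dt_acq = dt_acq),
            class = "size_control_fit")
}

# Gauss-Hermite nodes/weights (weight exp(-x^2)) via the Golub-Welsch
# eigendecomposition of the Jacobi matrix.
gauss_hermite <- function(n) {
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1) / 2)
  J[cbind(1:(n - 1), 2:n)] <- off
  J[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

# Profile-likelihood interval for parameter j on the internal scale, mapped
# through `trans`. Brackets are scaled by the Wald SE from a numerical
# Hessian; inner optimisations are warm-started along the profile. Falls back
# to the Wald interval if the root search fails.
profile_ci <- function(nll, mle, j, conf, trans) {
  target <- stats::qchisq(conf, 1) / 2
  l0 <- nll(mle)
  se <- wald_se(nll, mle)[j]
  if (!is.finite(se) || se <= 0) se <- 0.1
  warm <- mle[-j]
  f_prof <- function(v) {
    fixed <- function(free) {
      p <- numeric(length(mle)); p[j] <- v; p[-j] <- free
      nll(p)
    }
    o <- stats::optim(warm, fixed, method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-10))
    warm <<- o$par
    max(o$value - l0, 0)
  }
  bound <- function(dir) {
    warm <<- mle[-j]
    v1 <- mle[j]
    for (mult in c(1, 2, 4, 8, 16)) {
      v2 <- mle[j] + dir * mult * 1.959964 * se
      if (f_prof(v2) > target) {
        return(tryCatch(
          stats::uniroot(function(x) f_prof(x) - target, sort(c(v1, v2)),
                         tol = se / 50)$root,
          error = function(e) NA_real_))
      }
      v1 <- v2
    }
    NA_real_
  }
  lo <- bound(-1); hi <- bound(1)
  if (is.na(lo)) lo <- mle[j] - 1.959964 * se
  if (is.na(hi)) hi <- mle[j] + 1.959964 * se
  sort(trans(c(lo, hi)))
}

# Wald standard errors from a central-difference Hessian.
wald_se <- function(nll, mle, h = 1e-3) {
  p <- length(mle)
  H <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) for (k in seq_len(i)) {
    ei <- ek <- numeric(p); ei[i] <- h; ek[k] <- h
    H[i, k] <- H[k, i] <-
      (nll(mle + ei + ek) - nll(mle + ei - ek) -
         nll(mle - ei + ek) + nll(mle - ei - ek)) / (4 * h^2)
  }
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p, p))
  sqrt(pmax(diag(V), 0))
}

#' @export
print.size_control_fit <- function(x, ...) {
  cat(sprintf("Size-control MLE (%s correction), n = %d (+%d censored):\n",
              x$correction, x$n, x$n_censored))
  for (p in c("a", "k", "lam"))
    cat(sprintf("  %-4s = %7.3f  [%7.3f, %7.3f]\n", p, x$estimates[p],
                x$ci[p, 1], x$ci[p, 2]))
  invisible(x)
}
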