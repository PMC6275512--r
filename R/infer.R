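# ---- likelihood machinery for coupling inference -------------------------

# Piecewise-exponential reconstruction of a cell's length history and the
# discretization of its division-rate integral. Using the change of variables
# dL = zeta * alpha * L dt, the cumulative division rate over the cycle is
#   int Gamma dt = int S(Delta0(L)) G(tau(t(L))) dL,
# which depends on the trace only through (time, length) pairs: no elongation
# model is needed. Each inter-frame interval is split into `nsub` pieces and
# contributes weights w = S(Delta0(L_mid)) * (L_hi - L_lo) at times of day
# tau_mid, so that int Gamma dt ~ sum w * G(tau).
#
# With edge_correction, exposure is extended half an acquisition interval
# before the recorded birth frame and after the recorded division frame
# (growth extrapolated at the cell's mean rate), compensating the discrete
# observation convention; the division point is placed half a frame past the
# recorded division frame.
build_coupling_terms <- function(cells, traces, params, dawn_offset = 12,
                                 nsub = 2, edge_correction = TRUE,
                                 dt_acq = NULL) {
  if (inherits(dawn_offset, "light_profile")) dawn_offset <- dawn_offset$dawn_offset
  if (is.null(dt_acq)) {
    tt <- sort(unique(traces$time_h))
    dt_acq <- min(diff(tt)[diff(tt) > 1e-9])
  }
  tr_by_cell <- split(traces[, c("time_h", "length_um")], traces$cell_id)
  tau_div <- numeric(0)
  const_div <- numeric(0)
  q_tau <- vector("list", nrow(cells))
  q_w <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    tr <- tr_by_cell[[as.character(cell$cell_id)]]
    if (is.null(tr) || nrow(tr) < 2) next
    tt <- tr$time_h
    ll <- pmax(tr$length_um, 1e-6)
    divided <- cell$censored == 0 && !is.na(cell$division_time_h)
    rbar <- log(ll[length(ll)] / ll[1]) / max(tt[length(tt)] - tt[1], dt_acq)
    if (edge_correction) {
      tt <- c(tt[1] - dt_acq / 2, tt)
      ll <- c(ll[1] * exp(-max(rbar, 0) * dt_acq / 2), ll)
      if (divided) {
        tt <- c(tt, tt[length(tt)] + dt_acq / 2)
        ll <- c(ll, ll[length(ll)] * exp(max(rbar, 0) * dt_acq / 2))
      }
    }
    L0 <- ll[1]
    # subdivide each interval; geometric (exponential-growth) interpolation
    m <- length(tt) - 1
    fr <- rep(seq_len(m), each = nsub)
    u0 <- rep((seq_len(nsub) - 1) / nsub, m)
    u1 <- u0 + 1 / nsub
    Llo <- ll[fr] * (ll[fr + 1] / ll[fr])^u0
    Lhi <- ll[fr] * (ll[fr + 1] / ll[fr])^u1
    tmid <- tt[fr] + (u0 + u1) / 2 * (tt[fr + 1] - tt[fr])
    w <- size_hazard(delta0(sqrt(Llo * Lhi), L0, params$a), params) * (Lhi - Llo)
    keep <- w != 0
    q_tau[[i]] <- time_of_day(tmid[keep], dawn_offset)
    q_w[[i]] <- w[keep]
    if (divided) {
      t_div <- cell$division_time_h + if (edge_correction) dt_acq / 2 else 0
      L_div <- ll[length(ll)]
      tau_div <- c(tau_div, time_of_day(t_div, dawn_offset))
      # G-independent factor of Gamma at division: S(Delta0) * dL/dt
      s_div <- size_hazard(delta0(L_div, L0, params$a), params)
      const_div <- c(const_div, log(pmax(s_div * max(rbar, 1e-12) * L_div, 1e-300)))
    }
  }
  list(tau_div = tau_div, const_div = const_div,
       q_tau = unlist(q_tau), q_w = unlist(q_w), dt_acq = dt_acq)
}

#' Log-likelihood of one observed cell cycle
#'
#' For a divided cell, `log Gamma(t_div) - int Gamma dt` over the observed
#' cycle; for a censored cell, `-int Gamma dt`. The integral uses the change
#' of variables `int Gamma dt = int S(Delta0(L)) G(tau(L)) dL` along the
#' piecewise-exponential reconstruction of the length history, so no
#' elongation model is required; the rate factor at the division point uses
#' the cell's mean growth rate.
#'
#' @param trace Data frame `time_h`, `length_um` for one cell.
#' @param record One-row cell table for the same cell.
#' @param G A [coupling_function()].
#' @param params A [size_control_params()].
#' @param dawn_offset Dawn convention (h) or a [light_profile()].
#' @param nsub Subdivisions per frame interval for the integral.
#' @param edge_correction Extend exposure half a frame beyond the recorded
#'   birth/division frames.
#' @return The log-likelihood (finite).
#' @export
cycle_log_likelihood <- function(trace, record, G, params, dawn_offset = 12,
                                 nsub = 4, edge_correction = FALSE) {
  if (nrow(record) != 1 || !all(trace$cell_id == record$cell_id))
    stop("input error: trace and record do not match a single cell")
  terms <- build_coupling_terms(record, trace, params, dawn_offset,
                                nsub = nsub, edge_correction = edge_correction)
  ll <- -sum(terms$q_w * coupling_eval(terms$q_tau, G))
  if (length(terms$tau_div))
    ll <- ll + terms$const_div + log(coupling_eval(terms$tau_div, G))
  as.numeric(ll)
}

# Periodic second-difference penalty matrix for K knots.
second_diff_penalty <- function(K) {
  D <- matrix(0, K, K)
  for (i in seq_len(K)) {
    D[i, i] <- -2
    D[i, ifelse(i == 1, K, i - 1)] <- 1
    D[i, ifelse(i == K, 1, i + 1)] <- 1
  }
  crossprod(D)
}

# Effective sample size from the autocorrelation function (initial positive
# sequence, truncated at the first small lag).
ess_one <- function(x) {
  n <- length(x)
  if (stats::sd(x) < 1e-12) return(n)
  r <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (rr in r) {
    if (is.na(rr) || rr < 0.05) break
    s <- s + rr
  }
  n / (1 + 2 * s)
}

# Adaptive random-walk Metropolis with a fixed preconditioning Cholesky
# factor; the global scale adapts towards ~25% acceptance during burn-in.
rwm_chains <- function(lp, theta0, chol_prop, n_iter, n_chains, burn_frac,
                       seed) {
  set.seed(seed)
  K <- length(theta0)
  n_keep <- n_iter - floor(n_iter * burn_frac)
  samples <- vector("list", n_chains)
  acc_rates <- numeric(n_chains)
  for (ch in seq_len(n_chains)) {
    theta <- theta0 + 0.1 * drop(crossprod(chol_prop, stats::rnorm(K)))
    l_cur <- lp(theta)
    scale <- 2.38 / sqrt(K)
    keep <- matrix(NA_real_, n_keep, K)
    n_acc <- 0L; n_acc_win <- 0L
    burn_n <- n_iter - n_keep
    for (it in seq_len(n_iter)) {
      prop <- theta + scale * drop(crossprod(chol_prop, stats::rnorm(K)))
      l_prop <- lp(prop)
      if (is.finite(l_prop) && log(stats::runif(1)) < l_prop - l_cur) {
        theta <- prop; l_cur <- l_prop
        n_acc_win <- n_acc_win + 1L
        if (it > burn_n) n_acc <- n_acc + 1L
      } else if (it > burn_n) {
        # no-op; rejection
      }
      if (it <= burn_n && it %% 50 == 0) {
        scale <- scale * exp((n_acc_win / 50 - 0.25) * 0.5)
        n_acc_win <- 0L
      }
      if (it > burn_n) keep[it - burn_n, ] <- theta
    }
    samples[[ch]] <- keep
    acc_rates[ch] <- n_acc / n_keep
  }
  list(samples = samples, acc_rates = acc_rates)
}

make_posterior <- function(samples_list, acc_rates, knot_times, map_par,
                           lp_map, ess_threshold, extra = NULL) {
  K <- length(knot_times)
  pooled <- do.call(rbind, lapply(samples_list, function(s) s[, seq_len(K), drop = FALSE]))
  ess <- apply(pooled, 2, ess_one)
  # split-chain potential scale reduction
  rhat <- vapply(seq_len(K), function(k) {
    ch <- lapply(samples_list, function(s) s[, k])
    halves <- unlist(lapply(ch, function(x) {
      h <- floor(length(x) / 2)
      list(x[1:h], x[(h + 1):(2 * h)])
    }), recursive = FALSE)
    m <- lengths(halves)[1]
    mu <- vapply(halves, mean, 0); v <- vapply(halves, stats::var, 0)
    W <- mean(v); B <- m * stats::var(mu)
    if (W < 1e-12) return(1)
    sqrt(((m - 1) / m * W + B / m) / W)
  }, 0)
  if (min(ess) < ess_threshold)
    warning(sprintf("sampler diagnostics: min knot ESS %.0f below threshold %g",
                    min(ess), ess_threshold))
  gs <- exp(pooled)
  structure(list(
    samples = pooled,
    knot_times = knot_times,
    mean = colMeans(gs),
    ci_low = apply(gs, 2, stats::quantile, 0.025),
    ci_high = apply(gs, 2, stats::quantile, 0.975),
    map_estimate = coupling_function(map_par[seq_len(K)], knot_times),
    map_log_posterior = lp_map,
    diagnostics = list(acceptance = acc_rates, ess = ess, rhat = rhat),
    extra = extra),
    class = "coupling_posterior")
}

#' @export
print.coupling_posterior <- function(x, ...) {
  cat("Posterior coupling function at knots (mean [95% CrI]):\n")
  for (k in seq_along(x$knot_times))
    cat(sprintf("  tau = %4.1f h: %5.2f [%5.2f, %5.2f]\n", x$knot_times[k],
                x$mean[k], x$ci_low[k], x$ci_high[k]))
  cat(sprintf("min ESS %.0f, max Rhat %.3f, acceptance %s\n",
              min(x$diagnostics$ess), max(x$diagnostics$rhat),
              paste(sprintf("%.2f", x$diagnostics$acceptance), collapse = "/")))
  invisible(x)
}

#' Bayesian inference of the circadian coupling function from length traces
#'
#' Samples the posterior of the knot log-values of the periodic coupling
#' function G given single-cell length traces, with the size-control
#' parameters fixed beforehand (measured directly in clock-deletion cells,
#' which anchors the scale of G). The log-likelihood sums
#' [cycle_log_likelihood()] over cells; the prior is a zero-mean Gaussian on
#' periodic second differences of the knot log-values (SD `prior_sd`) plus a
#' weak Gaussian on their mean level (SD `level_sd`), expressing only
#' smoothness, positivity and periodicity.
#'
#' @param cells Cell table.
#' @param traces Trace table covering the cells.
#' @param params_fixed A [size_control_params()] estimated from clock-deletion
#'   data.
#' @param dawn_offset Dawn convention (h) or a [light_profile()].
#' @param knot_times Knot grid over the 24 h day (default 8 equispaced).
#' @param prior_sd Smoothness prior SD on periodic second differences.
#' @param level_sd Prior SD on the mean knot log-value.
#' @param n_iter,n_chains,burn_frac Sampler settings (adaptive random-walk
#'   Metropolis preconditioned by the curvature at the posterior mode; the
#'   first `burn_frac` of each chain is discarded).
#' @param seed Integer seed.
#' @param nsub Subdivisions per frame interval in the likelihood integral.
#' @param edge_correction See [cycle_log_likelihood()].
#' @param ess_threshold Minimum effective sample size before a diagnostic
#'   warning is raised.
#' @return A `"coupling_posterior"`: pooled `samples` of knot log-values,
#'   posterior `mean`, `ci_low`/`ci_high` (95% credible bounds on the G
#'   scale), `map_estimate` (a [coupling_function()]), and
#'   `diagnostics` (acceptance rates, per-knot ESS and split-Rhat).
#' @export
infer_coupling <- function(cells, traces, params_fixed, dawn_offset = 12,
                           knot_times = seq(0, 21, by = 3), prior_sd = 1,
                           level_sd = 2, n_iter = 10000, n_chains = 4,
                           burn_frac = 0.5, seed = 1, nsub = 2,
                           edge_correction = TRUE, ess_threshold = 100) {
  K <- length(knot_times)
  terms <- build_coupling_terms(cells, traces, params_fixed, dawn_offset,
                                nsub = nsub, edge_correction = edge_correction)
  M_div <- coupling_design_matrix(terms$tau_div, knot_times)
  M_int <- coupling_design_matrix(terms$q_tau, knot_times)
  w <- terms$q_w
  P <- second_diff_penalty(K)
  A <- colSums(M_div)
  lp <- function(theta) {
    g <- exp(M_int %*% theta)
    sum(M_div %*% theta) - sum(w * g) -
      drop(theta %*% P %*% theta) / (2 * prior_sd^2) -
      mean(theta)^2 / (2 * level_sd^2)
  }
  gr <- function(theta) {
    g <- drop(exp(M_int %*% theta))
    A - drop(crossprod(M_int, w * g)) -
      drop(P %*% theta) / prior_sd^2 -
      rep(mean(theta) / (K * level_sd^2), K)
  }
  opt <- stats::optim(rep(0, K), function(th) -lp(th), function(th) -gr(th),
                      method = "BFGS", control = list(maxit = 500))
  map <- opt$par
  g_map <- drop(exp(M_int %*% map))
  H <- crossprod(M_int * sqrt(pmax(w * g_map, 0))) + P / prior_sd^2 +
    matrix(1 / (K^2 * level_sd^2), K, K) + diag(1e-8, K)
  chol_prop <- chol(solve(H))
  res <- rwm_chains(lp, map, chol_prop, n_iter, n_chains, burn_frac, seed)
  post <- make_posterior(res$samples, res$acc_rates, knot_times, map,
                         lp(map), ess_threshold,
                         extra = list(n_cells = nrow(cells),
                                      n_divisions = length(terms$tau_div),
                                      const_loglik = sum(terms$const_div)))
  post
}

#' Coupling inference from birth and division times only
#'
#' A simpler variant that ignores cell lengths: the division rate is modelled
#' as `h(age) * G(tau)` with a Weibull age hazard
#' `h(age) = (k/lam) * (age/lam)^(k-1)` fitted jointly with the knot
#' log-values of G. Uses the same smoothness prior and sampler as
#' [infer_coupling()], with weak normal priors on the log age-hazard
#' parameters.
#'
#' @param cells Cell table (lengths not used).
#' @param base_hazard Named vector `c(shape =, scale =)` initialising the age
#'   hazard (scale in hours).
#' @param fix_coupling If `TRUE`, G is held at 1 and only the age hazard is
#'   inferred (useful as a marginal model of cycle durations).
#' @param da Age step (h) of the integral discretization.
#' @inheritParams infer_coupling
#' @return A `"coupling_posterior"`; the joint draws of
#'   `log(shape), log(scale)` are in `extra$age_samples` and their posterior
#'   medians in `extra$age_hazard`.
#' @export
infer_coupling_division_time <- function(cells, base_hazard = c(shape = 2, scale = 15),
                                         dawn_offset = 12,
                                         knot_times = seq(0, 21, by = 3),
                                         prior_sd = 1, level_sd = 2,
                                         n_iter = 10000, n_chains = 4,
                                         burn_frac = 0.5, seed = 1, da = 0.5,
                                         fix_coupling = FALSE,
                                         ess_threshold = 100) {
  if (inherits(dawn_offset, "light_profile")) dawn_offset <- dawn_offset$dawn_offset
  K <- length(knot_times)
  cc <- cells[!is.na(cells$birth_time_h), ]
  divided <- cc$censored == 0 & !is.na(cc$division_time_h)
  end_t <- ifelse(divided, cc$division_time_h,
                  max(c(cc$birth_time_h, cc$division_time_h), na.rm = TRUE))
  dur <- pmax(end_t - cc$birth_time_h, da)
  # age-integral grid per cell (midpoint rule)
  n_steps <- pmax(1L, ceiling(dur / da))
  idx <- rep(seq_len(nrow(cc)), n_steps)
  step <- sequence(n_steps)
  dai <- (dur / n_steps)[idx]
  age_mid <- (step - 0.5) * dai
  tau_mid <- time_of_day(cc$birth_time_h[idx] + age_mid, dawn_offset)
  M_int <- coupling_design_matrix(tau_mid, knot_times)
  age_div <- dur[divided]
  tau_div <- time_of_day(end_t[divided], dawn_offset)
  M_div <- coupling_design_matrix(tau_div, knot_times)
  P <- second_diff_penalty(K)
  hz <- function(x, ka, la) (ka / la) * (x / la)^(ka - 1)
  lp_full <- function(par) {
    theta <- par[seq_len(K)]
    ka <- exp(par[K + 1]); la <- exp(par[K + 2])
    if (ka <= 0 || ka > 50 || la <= 0) return(-Inf)
    g <- drop(exp(M_int %*% theta))
    ll <- sum(log(hz(age_div, ka, la))) + sum(M_div %*% theta) -
      sum(dai * hz(age_mid, ka, la) * g)
    ll - drop(theta %*% P %*% theta) / (2 * prior_sd^2) -
      mean(theta)^2 / (2 * level_sd^2) -
      (par[K + 1] - log(base_hazard["shape"]))^2 / 8 -
      (par[K + 2] - log(base_hazard["scale"]))^2 / 8
  }
  if (fix_coupling) {
    lp <- function(p2) lp_full(c(rep(0, K), p2))
    opt <- stats::optim(log(base_hazard), function(p) -lp(p),
                        method = "Nelder-Mead")
    H <- num_hessian(function(p) -lp(p), opt$par)
    chol_prop <- chol(solve(H + diag(1e-8, 2)))
    res <- rwm_chains(lp, opt$par, chol_prop, n_iter, n_chains, burn_frac, seed)
    pooled <- do.call(rbind, res$samples)
    theta0 <- matrix(0, nrow(pooled), K)
    return(make_posterior(lapply(res$samples, function(s)
      cbind(matrix(0, nrow(s), K), s)[, seq_len(K), drop = FALSE]),
      res$acc_rates, knot_times, rep(0, K), lp(opt$par), 0,
      extra = list(age_samples = pooled,
                   age_hazard = exp(apply(pooled, 2, stats::median)))))
  }
  start <- c(rep(0, K), log(base_hazard))
  opt <- stats::optim(start, function(p) -lp_full(p), method = "BFGS",
                      control = list(maxit = 500))
  H <- num_hessian(function(p) -lp_full(p), opt$par)
  chol_prop <- tryCatch(chol(solve(H + diag(1e-8, K + 2))),
                        error = function(e) diag(0.05, K + 2))
  res <- rwm_chains(lp_full, opt$par, chol_prop, n_iter, n_chains, burn_frac,
                    seed)
  age_pooled <- do.call(rbind, lapply(res$samples,
                                      function(s) s[, K + (1:2), drop = FALSE]))
  make_posterior(res$samples, res$acc_rates, knot_times, opt$par,
                 lp_full(opt$par), ess_threshold,
                 extra = list(age_samples = age_pooled,
                              age_hazard = exp(apply(age_pooled, 2, stats::median)),
                              n_divisions = length(age_div)))
}

#' Posterior mean coupling curve and peak location
#'
#' Evaluates the posterior mean of G on a dense time-of-day grid (by
#' averaging `exp` of interpolated knot log-values over thinned draws).
#'
#' @param post A `"coupling_posterior"`.
#' @param grid Times of day (h).
#' @param thin Keep every `thin`-th draw.
#' @return A data.frame `tau`, `mean_G`.
#' @export
posterior_coupling_curve <- function(post, grid = seq(0, 24, by = 0.1),
                                     thin = 10) {
  M <- coupling_design_matrix(grid, post$knot_times)
  draws <- post$samples[seq(1, nrow(post$samples), by = thin), , drop = FALSE]
  data.frame(tau = grid, mean_G = rowMeans(exp(M %*% t(draws))))
}

#' Time of day at which a coupling function peaks
#'
#' @param G A [coupling_function()] or a `"coupling_posterior"` (posterior
#'   mean curve).
#' @param grid Search grid of times of day (h).
#' @return Peak time of day (h).
#' @export
coupling_peak_time <- function(G, grid = seq(0, 24 - 0.05, by = 0.05)) {
  if (inherits(G, "coupling_posterior")) {
    cur <- posterior_coupling_curve(G, grid)
    return(cur$tau[which.max(cur$mean_G)])
  }
  grid[which.max(coupling_eval(grid, G))]
}

# Central-difference Hessian of f at x.
num_hessian <- function(f, x, h = 1e-3) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) for (k in seq_len(i)) {
    ei <- ek <- numeric(p); ei[i] <- h; ek[k] <- h
    H[i, k] <- H[k, i] <- (f(x + ei + ek) - f(x + ei - ek) -
                             f(x - ei + ek) + f(x - ei - ek)) / (4 * h^2)
  }
  (H + t(H)) / 2
}
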