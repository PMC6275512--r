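# noiseless synthetic trace of one exponentially growing cell
one_cell <- function(L0 = 2, rate = 0.04, t0 = 12, t1 = 36, dt = 0.75,
                     divided = TRUE) {
  tt <- seq(t0, t1, by = dt)
  trace <- data.frame(cell_id = 1L, time_h = tt,
                      length_um = L0 * exp(rate * (tt - t0)))
  record <- data.frame(cell_id = 1L, lineage_id = 1L, parent_id = NA_integer_,
                       condition = "synthetic", birth_time_h = t0,
                       division_time_h = if (divided) t1 else NA_real_,
                       birth_length_um = L0,
                       division_length_um = if (divided) max(trace$length_um) else NA_real_,
                       censored = as.integer(!divided))
  list(trace = trace, record = record)
}

test_that("cycle log-likelihood matches closed forms", {
  oc <- one_cell(divided = FALSE)
  # k = 1, G == 1, a = 0: int Gamma dt = (L_end - L0) / lam exactly
  params <- size_control_params(a = 0, k = 1, lam = 2.3, sigma_zeta = 0)
  ll <- cycle_log_likelihood(oc$trace, oc$record, constant_coupling(1),
                             params, nsub = 4)
  L_end <- max(oc$trace$length_um)
  expect_equal(ll, -(L_end - 2) / 2.3, tolerance = 1e-6)
  # linearity in G: censored contribution scales with a constant coupling
  ll2 <- cycle_log_likelihood(oc$trace, oc$record, constant_coupling(2),
                              params, nsub = 4)
  expect_equal(ll2, 2 * ll, tolerance = 1e-9)
  # divided cell: doubling G adds log 2 minus the extra integral
  ocd <- one_cell(divided = TRUE)
  lld1 <- cycle_log_likelihood(ocd$trace, ocd$record, constant_coupling(1), params)
  lld2 <- cycle_log_likelihood(ocd$trace, ocd$record, constant_coupling(2), params)
  expect_equal(lld2 - lld1, log(2) - (-ll), tolerance = 1e-9)
  # a censored interval with zero division rate contributes nothing
  dark <- one_cell(divided = FALSE)
  dark$trace$length_um <- rep(2, nrow(dark$trace))  # no growth: dL = 0
  expect_equal(cycle_log_likelihood(dark$trace, dark$record,
                                    coupling_bump(), params), 0)
  expect_error(cycle_log_likelihood(oc$trace, oc$record[c(1, 1), ],
                                    constant_coupling(1), params),
               "input error")
})

test_that("one-cell division-time density agrees with brute-force simulation", {
  params <- size_control_params(a = 0, k = 2, lam = 2.5, sigma_zeta = 0)
  G <- coupling_bump(peak_time = 22, height = 3, basal = 0.25, width = 3)
  alpha <- 0.05; L0 <- 2.5; t0 <- 12
  # model density over a grid, from the package likelihood
  dens_model <- function(t_div) {
    tt <- seq(t0, t_div, length.out = 400)
    trace <- data.frame(cell_id = 1L, time_h = tt,
                        length_um = L0 * exp(alpha * (tt - t0)))
    record <- data.frame(cell_id = 1L, lineage_id = 1L, parent_id = NA_integer_,
                         condition = "s", birth_time_h = t0,
                         division_time_h = t_div,
                         birth_length_um = L0,
                         division_length_um = max(trace$length_um),
                         censored = 0L)
    exp(cycle_log_likelihood(trace, record, G, params, nsub = 2))
  }
  # brute-force: fine-step Bernoulli division times for the same single cell
  set.seed(42)
  h <- 5e-4; n_sim <- 20000
  tt <- t0 + h * seq_len(80000)
  L <- L0 * exp(alpha * (tt - t0))
  p <- size_hazard(L - L0, params) * coupling_eval(time_of_day(tt), G) *
    alpha * L * h
  lsurv <- cumsum(log1p(-p))
  u <- stats::runif(n_sim)
  idx <- findInterval(log(u), rev(lsurv))
  t_div_sim <- ifelse(idx >= 1, tt[length(tt) + 1 - idx], NA) # inverse CDF
  t_div_sim <- t_div_sim[!is.na(t_div_sim)]
  breaks <- seq(16, 44, by = 2)
  inside <- t_div_sim > 16 & t_div_sim < 44
  sim_p <- graphics::hist(t_div_sim[inside], breaks = breaks,
                          plot = FALSE)$density * mean(inside) * 2
  # bin probabilities of the model density (5-point average per bin)
  mod_p <- vapply(seq_len(length(breaks) - 1), function(i) {
    pts <- seq(breaks[i] + 0.2, breaks[i + 1] - 0.2, length.out = 5)
    mean(vapply(pts, dens_model, 0)) * 2
  }, 0)
  keep <- mod_p > 0.005
  expect_lt(max(abs(sim_p[keep] - mod_p[keep])), 0.02)
})

test_that("coupling inference recovers the truth and its own scale", {
  d <- generate_dataset("WT_constant", seed = 19,
                        config = default_sim_config("WT_constant", seed = 19,
                                                    n_lineages = 10,
                                                    max_cells = 420))
  post <- suppressWarnings(
    infer_coupling(d$cells, d$traces, d$params, dawn_offset = d$profile,
                   n_iter = 2500, n_chains = 2, seed = 3))
  g_true <- coupling_eval(post$knot_times, d$G)
  expect_gte(sum(post$ci_low <= g_true & g_true <= post$ci_high), 6)
  expect_true(all(post$ci_low <= post$ci_high))
  expect_true(all(is.finite(post$diagnostics$ess)))
  # periodicity by construction
  gm <- post$map_estimate
  expect_equal(coupling_eval(0, gm), coupling_eval(24, gm))
  # scale is anchored: the posterior log-density has curvature along a
  # global rescaling of G
  terms <- cyanogate:::build_coupling_terms(d$cells, d$traces, d$params,
                                            d$profile)
  M <- coupling_design_matrix(terms$q_tau, gm$knot_times)
  Md <- coupling_design_matrix(terms$tau_div, gm$knot_times)
  ll <- function(theta) sum(Md %*% theta) - sum(terms$q_w * exp(M %*% theta))
  th <- gm$log_values
  curv <- ll(th + 0.05) + ll(th - 0.05) - 2 * ll(th)
  expect_lt(curv, 0)
})

test_that("clock-deletion data analysed as wild type recovers G near 1", {
  d <- generate_dataset("clockdel_constant", seed = 23,
                        config = default_sim_config("clockdel_constant",
                                                    seed = 23, n_lineages = 10,
                                                    max_cells = 420))
  post <- suppressWarnings(
    infer_coupling(d$cells, d$traces, d$params, dawn_offset = d$profile,
                   n_iter = 2500, n_chains = 2, seed = 4))
  expect_gte(sum(post$ci_low <= 1 & 1 <= post$ci_high), 7)
})

test_that("division-time model recovers the marginal age hazard and is wider", {
  # data drawn from the time-only generative model itself
  set.seed(5)
  n <- 800
  tb <- 12 + runif(n, 0, 72)
  dur <- rweibull(n, shape = 2.4, scale = 18)
  cells_w <- data.frame(cell_id = seq_len(n), lineage_id = 1L,
                        parent_id = NA_integer_, condition = "s",
                        birth_time_h = tb, division_time_h = tb + dur,
                        birth_length_um = 3, division_length_um = 6,
                        censored = 0L)
  # G fixed at 1: the fitted Weibull age hazard matches the marginal
  # cycle-duration distribution
  fit0 <- infer_coupling_division_time(cells_w, n_iter = 1500, n_chains = 2,
                                       seed = 5, fix_coupling = TRUE)
  ks <- suppressWarnings(stats::ks.test(
    dur, stats::pweibull, shape = fit0$extra$age_hazard[1],
    scale = fit0$extra$age_hazard[2]))
  expect_lt(unname(ks$statistic), 0.05)
  # joint fit on gated data: credible band at the peak is wider than the
  # trace-based one, which uses the additional length information
  d <- generate_dataset("WT_constant", seed = 29,
                        config = default_sim_config("WT_constant", seed = 29,
                                                    n_lineages = 12,
                                                    max_cells = 700))
  post_t <- suppressWarnings(
    infer_coupling_division_time(d$cells, dawn_offset = d$profile,
                                 n_iter = 2500, n_chains = 2, seed = 6))
  post_l <- suppressWarnings(
    infer_coupling(d$cells, d$traces, d$params, dawn_offset = d$profile,
                   n_iter = 2500, n_chains = 2, seed = 6))
  peak_knot <- which.max(post_l$mean)
  rel_width <- function(p, k) (p$ci_high[k] - p$ci_low[k]) / p$mean[k]
  expect_gt(rel_width(post_t, peak_knot), rel_width(post_l, peak_knot))
})

test_that("with no data the coupling posterior reproduces the prior", {
  cells0 <- data.frame(cell_id = integer(0), lineage_id = integer(0),
                       parent_id = integer(0), condition = character(0),
                       birth_time_h = numeric(0), division_time_h = numeric(0),
                       birth_length_um = numeric(0),
                       division_length_um = numeric(0), censored = integer(0))
  traces0 <- data.frame(cell_id = integer(0), time_h = numeric(0),
                        length_um = numeric(0))
  post <- suppressWarnings(
    infer_coupling(cells0, traces0, size_control_params(), n_iter = 4000,
                   n_chains = 2, seed = 7))
  # prior is centred on log G = 0 with level SD 2: mean of knot log-values
  # is approximately Normal(0, 2)
  lev <- rowMeans(post$samples)
  expect_lt(abs(mean(lev)), 0.6)
  expect_gt(stats::sd(lev), 1.0)
  expect_lt(stats::sd(lev), 3.5)
})
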