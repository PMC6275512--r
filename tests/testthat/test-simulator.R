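test_that("thinning bound dominates the division rate over the horizon", {
  params <- size_control_params(a = -0.1, k = 2, lam = 2, sigma_zeta = 0)
  G <- coupling_bump()
  # no division possible while the window-end Delta0 is non-positive
  expect_equal(thinning_bound(1.05, 1.0, 1,
                              G, size_control_params(a = 0.2, k = 2, lam = 2),
                              alpha_max = 0.05), 0)
  # tight case: constant coupling at its own bound, alpha at its maximum
  Gc <- coupling_function(rep(log(2), 8), Gmax = 2)
  prof <- light_profile("constant", A = 15)
  model <- elongation_model("constant_light_oscillatory", alpha_bar = 0.05,
                            epsilon = 0)
  st <- cell_state(L = 3, L0 = 2, zeta = 1.2, t = 7)
  expect_equal(thinning_bound(3, 2, 1.2, Gc, params,
                              elongation_rate_max(model, prof)),
               division_rate(st, Gc, 0.05, params))
  # random draws: B >= Gamma(t) on a time grid within the window
  set.seed(21)
  model_o <- elongation_model("constant_light_oscillatory", alpha_bar = 0.05,
                              epsilon = 0.2, phase = 18)
  amax <- elongation_rate_max(model_o, prof)
  for (i in 1:200) {
    p <- size_control_params(a = runif(1, -0.4, 0.3), k = runif(1, 1, 4),
                             lam = runif(1, 0.8, 4), sigma_zeta = 0)
    L0 <- runif(1, 1, 4); zeta <- runif(1, 0.7, 1.4)
    t0 <- runif(1, 0, 24); dt <- runif(1, 0.3, 2)
    tt <- seq(t0, t0 + dt, length.out = 100)
    L <- L0 * exp(zeta * vapply(tt, function(t2)
      elongation_integral(t0, t2, model_o, prof), 0))
    B <- thinning_bound(L[100], L0, zeta, G, p, amax)
    gam <- size_hazard(L - (1 + p$a) * L0, p) *
      coupling_eval(time_of_day(tt, prof), G) * zeta *
      mean_elongation_rate(tt, model_o, prof) * L
    expect_true(all(gam <= B + 1e-12))
  }
  expect_error(thinning_bound(3, 2, 1, G, structure(
    list(a = 0, k = 0.5, lam = 1, sigma_zeta = 0),
    class = "size_control_params"), 0.05), "unsupported hazard")
})

test_that("a lineage without division grows deterministically", {
  # S ~ 0: pure exponential growth to within 1e-8 relative error
  params <- size_control_params(a = 0, k = 2, lam = 1e9, sigma_zeta = 0)
  prof <- light_profile("constant", A = 15)
  model <- elongation_model("constant_light_oscillatory", alpha_bar = 0.03,
                            epsilon = 0.3, phase = 20)
  cfg <- sim_config(t0 = 0, t_end = 50, dt_horizon = 1, n_lineages = 1)
  set.seed(5)
  res <- simulate_lineage(cfg, constant_coupling(1), model, prof, params,
                          L_init = 2, zeta_init = 1.1)
  expect_equal(nrow(res$cells), 1)
  expect_true(is.na(res$cells$div_t))
  L_expect <- 2 * exp(1.1 * elongation_integral(0, 50, model, prof))
  expect_lt(abs(res$cells$L_div - L_expect) / L_expect, 1e-8)
})

test_that("simulated added lengths match the closed-form distribution", {
  # adder (a = 0), G == 1, constant alpha: Delta0 = added length is
  # exactly Weibull(k, lam); KS against the closed-form CDF
  params <- size_control_params(a = 0, k = 2, lam = 3.4, sigma_zeta = 0.1)
  prof <- light_profile("constant", A = 15)
  model <- elongation_model("constant_light_oscillatory", alpha_bar = 0.04,
                            epsilon = 0)
  cfg <- sim_config(t0 = 12, t_end = 12 + 24 * 9, n_lineages = 40,
                    max_cells = 3000, L0_meanlog = log(3), seed = 3)
  set.seed(cfg$seed)
  truth <- cyanogate:::simulate_colony(cfg, constant_coupling(1), model, prof,
                                       params)
  cyc <- truth_cycles(truth)
  d0 <- cyc$L_div - cyc$L_birth
  expect_gt(length(d0), 2000)
  ks <- suppressWarnings(stats::ks.test(d0, stats::pweibull, shape = 2,
                                        scale = 3.4))
  expect_lt(unname(ks$statistic), 0.03)
  # constant hazard case: exponential added lengths with mean lam
  params1 <- size_control_params(a = 0, k = 1, lam = 3, sigma_zeta = 0)
  set.seed(9)
  truth1 <- cyanogate:::simulate_colony(
    sim_config(t0 = 12, t_end = 12 + 24 * 9, n_lineages = 40,
               max_cells = 3000, L0_meanlog = log(3), seed = 9),
    constant_coupling(1), model, prof, params1)
  d1 <- with(truth_cycles(truth1), L_div - L_birth)
  ks1 <- suppressWarnings(stats::ks.test(d1, stats::pexp, rate = 1 / 3))
  expect_lt(unname(ks1$statistic), 0.03)
})

test_that("thinning agrees with a fine-step brute-force oracle under gating", {
  # peaked coupling, constant alpha; compare Delta0 and division time-of-day
  # distributions between the exact simulator and a Bernoulli(Gamma * h)
  # simulator at h = 1e-3
  params <- size_control_params(a = -0.1, k = 3, lam = 3.7, sigma_zeta = 0)
  G <- coupling_bump()
  prof <- light_profile("constant", A = 15)
  model <- elongation_model("constant_light_oscillatory", alpha_bar = 0.035,
                            epsilon = 0)
  set.seed(31)
  cfg <- sim_config(t0 = 12, t_end = 12 + 24 * 60, dt_horizon = 1,
                    n_lineages = 1, L0_meanlog = log(3))
  thin <- do.call(rbind, lapply(1:25, function(i)
    simulate_lineage(cfg, G, model, prof, params)$cells))
  thin <- thin[!thin$first_cycle & !is.na(thin$div_t), ]
  bf <- do.call(rbind, lapply(1:25, function(i)
    oracle_bruteforce(60, a = -0.1, k = 3, lam = 3.7, alpha = 0.035,
                      G_fun = function(tau) coupling_eval(tau, G))))
  bf <- bf[bf$t_birth > 36, ]  # discard transients as for the lineage founders
  d_thin <- thin$L_div - 0.9 * thin$L_birth
  d_bf <- bf$L_div - 0.9 * bf$L_birth
  expect_gt(nrow(thin), 800)
  expect_lt(ks_dist(d_thin, d_bf), 0.06)
  tod_thin <- time_of_day(thin$div_t)
  tod_bf <- time_of_day(bf$t_div)
  expect_lt(ks_dist(tod_thin, tod_bf), 0.06)
})

test_that("no growth or division in the dark; daughters are exact halves", {
  params <- size_control_params()
  prof <- light_profile("graded_LD", A = 15, TL = 12)
  model <- elongation_model("light_tracking", c = 0.035 / 15)
  cfg <- sim_config(t0 = 12, t_end = 12 + 24 * 4, dt_acq = 1,
                    n_lineages = 10, max_cells = 300, seed = 2)
  set.seed(2)
  truth <- cyanogate:::simulate_colony(cfg, coupling_bump(), model, prof,
                                       params)
  ev <- truth[!is.na(truth$div_t), ]
  # divisions only during the light window
  s <- (ev$div_t - prof$dawn_offset) %% 24
  expect_true(all(s <= prof$TL + 1e-9))
  # daughters start at exactly half the parent division length
  kids <- truth[!is.na(truth$parent_id), ]
  expect_equal(kids$L_birth,
               truth$L_div[match(kids$parent_id, truth$cell_id)] / 2)
  # lengths constant across the dark interval of a surviving cell
  cell <- truth[is.na(truth$div_t), ][1, ]
  dusk <- cell$birth_t + (prof$TL - (cell$birth_t - prof$dawn_offset) %% 24)
  if (dusk > cell$birth_t && dusk + 11 < cfg$t_end) {
    L1 <- true_length(cell, dusk + 0.5, model, prof)
    L2 <- true_length(cell, dusk + 11, model, prof)
    expect_equal(L1, L2)
  }
})

test_that("observation model follows the previous/next frame convention", {
  params <- size_control_params(sigma_zeta = 0)
  prof <- light_profile("constant", A = 15)
  model <- elongation_model("constant_light_oscillatory", alpha_bar = 0.04,
                            epsilon = 0)
  cfg <- sim_config(t0 = 12, t_end = 12 + 24 * 3, dt_acq = 0.75,
                    n_lineages = 12, max_cells = 250, noise_sd = 0, seed = 8)
  set.seed(8)
  truth <- cyanogate:::simulate_colony(cfg, constant_coupling(1), model, prof,
                                       params)
  obs <- observe_cells(truth, cfg, model, prof, condition = "test")
  frames <- seq(cfg$t0, cfg$t_end, by = cfg$dt_acq)
  expect_equal(length(frames), floor((cfg$t_end - cfg$t0) / cfg$dt_acq) + 1)
  tr <- truth[match(obs$cells$cell_id, truth$cell_id), ]
  div <- obs$cells$censored == 0
  # division frame is the last frame at or before the true division time;
  # recorded division length is the true (pre-division) length there
  expect_true(all(obs$cells$division_time_h[div] <= tr$div_t[div] + 1e-9))
  expect_true(all(tr$div_t[div] - obs$cells$division_time_h[div] < cfg$dt_acq))
  idx_div <- which(div)
  expect_equal(obs$cells$division_length_um[div],
               vapply(idx_div, function(i)
                 true_length(tr[i, ], obs$cells$division_time_h[i], model, prof),
                 0))
  # birth frame follows the true birth; recorded length exceeds true birth
  # length by less than one frame of maximal growth
  expect_true(all(obs$cells$birth_time_h >= tr$birth_t - 1e-9))
  excess <- obs$cells$birth_length_um - tr$L_birth
  bound <- obs$cells$birth_length_um *
    (exp(tr$zeta * elongation_rate_max(model, prof) * cfg$dt_acq) - 1)
  expect_true(all(excess >= -1e-9))
  expect_true(all(excess <= bound + 1e-9))
})

test_that("dataset generation is reproducible and scenario-aware", {
  cfg <- default_sim_config("clockdel_constant", seed = 77, n_lineages = 8,
                            max_cells = 150, t_end = 12 + 24 * 3)
  d1 <- generate_dataset("clockdel_constant", config = cfg)
  d2 <- generate_dataset("clockdel_constant", config = cfg)
  expect_identical(d1$cells, d2$cells)
  expect_identical(d1$traces, d2$traces)
  expect_error(generate_dataset("no_such_scenario"), "unknown scenario")
  expect_error(scenario_settings("custom"), "requires")
  # added-vs-birth regression on clock-deletion data recovers the configured a
  pars <- size_control_params(a = -0.35, k = 3, lam = 3.7 * 1.35 / 1.1,
                              sigma_zeta = 0.08)
  d <- generate_dataset("clockdel_constant", seed = 13, params = pars)
  expect_gt(nrow(d$cells), 1000)
  reg <- regress_added_vs_birth(d$cells)
  expect_lt(abs(reg$slope - (-0.35)), 0.1)
})
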