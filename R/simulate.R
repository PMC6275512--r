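#' Simulation configuration
#'
#' Settings of a lineage/colony simulation and of its discrete observation
#' model. Times are hours of experiment time, lengths micrometres.
#'
#' @param t0,t_end Simulation window (h), `t0 < t_end`.
#' @param dt_horizon Thinning time horizon over which the division rate is
#'   bounded (h).
#' @param dt_acq Acquisition (frame) interval of the observation model (h);
#'   45 min in constant light, hourly in LD experiments.
#' @param n_lineages Number of founder cells.
#' @param L0_meanlog,L0_sdlog Lognormal parameters of founder initial lengths.
#' @param noise_sd SD of additive Gaussian measurement noise on frame
#'   lengths (um).
#' @param seed Integer seed making dataset generation reproducible.
#' @param mode `"colony"` follows both daughters at each division (up to
#'   `max_cells`); `"lineage"` follows a single daughter, matching the
#'   single-lineage structure of the exact simulation algorithm.
#' @param max_cells Cap on the number of cell cycles simulated in colony mode.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(t0 = 12, t_end = 12 + 24 * 6, dt_horizon = 1,
                       dt_acq = 0.75, n_lineages = 24,
                       L0_meanlog = log(3), L0_sdlog = 0.2,
                       noise_sd = 0.05, seed = 1,
                       mode = c("colony", "lineage"), max_cells = 1600) {
  mode <- match.arg(mode)
  if (!(t0 < t_end)) stop("invalid config: t0 must be < t_end")
  if (dt_horizon <= 0 || dt_acq <= 0) stop("invalid config: time steps must be > 0")
  if (n_lineages < 1) stop("invalid config: n_lineages must be >= 1")
  structure(list(t0 = t0, t_end = t_end, dt_horizon = dt_horizon,
                 dt_acq = dt_acq, n_lineages = n_lineages,
                 L0_meanlog = L0_meanlog, L0_sdlog = L0_sdlog,
                 noise_sd = noise_sd, seed = as.integer(seed), mode = mode,
                 max_cells = max_cells),
            class = "sim_config")
}

#' Thinning rate bound over a horizon window
#'
#' Constant bound on the division rate over a thinning window, evaluated at
#' the window-end length `L_end`:
#' `B = S(L_end - (1 + a) * L0) * Gmax * zeta * alpha_max * L_end`.
#' Because the hazard is monotone (`k >= 1`) and length is non-decreasing,
#' `B >= Gamma(t)` throughout the window.
#'
#' @param L_end Length at the end of the window (um).
#' @param L0 Birth length (um).
#' @param zeta Growth amplitude.
#' @param G A [coupling_function()] (supplies `Gmax`).
#' @param params A [size_control_params()].
#' @param alpha_max Upper bound on the elongation rate (1/h); see
#'   [elongation_rate_max()].
#' @return The bound `B` in 1/h.
#' @export
thinning_bound <- function(L_end, L0, zeta, G, params, alpha_max) {
  if (params$k < 1) stop("unsupported hazard: k < 1 invalidates the monotone bound")
  size_hazard(L_end - (1 + params$a) * L0, params) *
    G$Gmax * zeta * alpha_max * L_end
}

# Truncated-positive Normal(1, sigma) growth amplitudes.
rzeta <- function(n, sigma) {
  if (sigma == 0) return(rep(1, n))
  x <- stats::rnorm(n, 1, sigma)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), 1, sigma)
  x
}

# Exact thinning simulation of one cell cycle from birth (t, L0) to division
# or t_end. Growth within a horizon is integrated in closed form; the
# division rate at a candidate time is evaluated at the exact length there.
sim_one_cycle <- function(t, L0, zeta, t_end, G, model, profile, params,
                          dt, alpha_max) {
  L <- L0
  a <- params$a
  repeat {
    if (t >= t_end - 1e-12) {
      if (!is.finite(L)) stop("numerical failure: non-finite length")
      return(list(divided = FALSE, t = t_end, L = L))
    }
    t2 <- min(t + dt, t_end)
    Lend <- L * exp(zeta * elongation_integral(t, t2, model, profile))
    if (!is.finite(Lend)) stop("numerical failure: non-finite length")
    B <- thinning_bound(Lend, L0, zeta, G, params, alpha_max)
    if (B <= 0) { t <- t2; L <- Lend; next }
    tau <- stats::rexp(1, B)
    if (tau > t2 - t) { t <- t2; L <- Lend; next }
    tc <- t + tau
    Lc <- L * exp(zeta * elongation_integral(t, tc, model, profile))
    Gam <- size_hazard(Lc - (1 + a) * L0, params) *
      coupling_eval(time_of_day(tc, profile), G) *
      zeta * mean_elongation_rate(tc, model, profile) * Lc
    t <- tc
    L <- Lc
    if (Gam >= B * stats::runif(1)) return(list(divided = TRUE, t = t, L = L))
  }
}

#' Simulate a single growing and dividing lineage
#'
#' Exact stochastic simulation by thinning: within each horizon window the
#' cell grows deterministically by `dL/dt = zeta * alpha(t) * L`; candidate
#' division times are drawn from an exponential clock at the window's rate
#' bound (see [thinning_bound()]) and accepted with probability `Gamma / B`.
#' At a division the length halves exactly, the birth length is reset and
#' `zeta` is resampled from Normal(1, sigma_zeta) truncated to positive
#' values. One daughter is followed after each division.
#'
#' The continuous trajectory is fully determined by the per-cycle rows
#' returned (birth time, true birth length, `zeta`): within a cycle
#' `L(t) = L_birth * exp(zeta * int alpha)`; see [true_length()].
#'
#' @param config A [sim_config()] (`t0`, `t_end`, `dt_horizon` are used).
#' @param G A [coupling_function()].
#' @param model An [elongation_model()].
#' @param profile A [light_profile()].
#' @param params A [size_control_params()].
#' @param L_init,zeta_init Optional founder length (um) and amplitude;
#'   drawn from the config's lognormal / Normal(1, sigma) if omitted.
#' @return A list with `cells` (one row per cell cycle: `cell_id`,
#'   `parent_id`, `lineage_id`, `birth_t`, `div_t` (`NA` if censored),
#'   `L_birth`, `L_div`, `zeta`, `first_cycle`) and `events` (completed
#'   divisions: `t_div`, `L_div`, `lineage_id`, `parent_id`).
#' @export
simulate_lineage <- function(config, G, model, profile, params,
                             L_init = NULL, zeta_init = NULL) {
  alpha_max <- elongation_rate_max(model, profile)
  if (is.null(L_init)) L_init <- stats::rlnorm(1, config$L0_meanlog, config$L0_sdlog)
  if (is.null(zeta_init)) zeta_init <- rzeta(1, params$sigma_zeta)
  t <- config$t0
  L0 <- L_init
  zeta <- zeta_init
  rows <- list()
  id <- 0L
  first <- TRUE
  while (t < config$t_end) {
    res <- sim_one_cycle(t, L0, zeta, config$t_end, G, model, profile, params,
                         config$dt_horizon, alpha_max)
    id <- id + 1L
    rows[[id]] <- data.frame(
      cell_id = id, parent_id = id - 1L, lineage_id = 1L,
      birth_t = t, div_t = if (res$divided) res$t else NA_real_,
      L_birth = L0, L_div = res$L, zeta = zeta, first_cycle = first)
    first <- FALSE
    if (!res$divided) break
    t <- res$t
    L0 <- res$L / 2
    zeta <- rzeta(1, params$sigma_zeta)
  }
  cells <- do.call(rbind, rows)
  cells$parent_id[1] <- NA_integer_
  ev <- cells[!is.na(cells$div_t), c("div_t", "L_div", "lineage_id", "parent_id")]
  names(ev)[1:2] <- c("t_div", "L_div")
  list(cells = cells, events = ev)
}

# Breadth-first colony simulation: both daughters are enqueued at each
# division until max_cells cycles have been simulated.
simulate_colony <- function(config, G, model, profile, params) {
  alpha_max <- elongation_rate_max(model, profile)
  n0 <- config$n_lineages
  # Founders stagger uniformly over the 24 h preceding the movie start: cells
  # placed on the pad are at arbitrary points of their division cycle, so
  # their (unobserved) births fall anywhere in the previous day. This
  # desynchronises colony generations; founder cycles (birth before t0) are
  # flagged and excluded by the observation model.
  birth <- config$t0 - stats::runif(n0, 0, 24)
  L0 <- stats::rlnorm(n0, config$L0_meanlog, config$L0_sdlog)
  zeta <- rzeta(n0, params$sigma_zeta)
  queue_b <- birth; queue_L <- L0; queue_z <- zeta
  queue_parent <- rep(NA_integer_, n0)
  queue_lin <- seq_len(n0)
  out <- vector("list", config$max_cells)
  n_done <- 0L
  head <- 1L
  while (head <= length(queue_b) && n_done < config$max_cells) {
    b <- queue_b[head]; l0 <- queue_L[head]; z <- queue_z[head]
    res <- sim_one_cycle(b, l0, z, config$t_end, G, model, profile, params,
                         config$dt_horizon, alpha_max)
    n_done <- n_done + 1L
    out[[n_done]] <- data.frame(
      cell_id = n_done, parent_id = queue_parent[head],
      lineage_id = queue_lin[head], birth_t = b,
      div_t = if (res$divided) res$t else NA_real_,
      L_birth = l0, L_div = res$L, zeta = z,
      first_cycle = b < config$t0 || is.na(queue_parent[head]))
    if (res$divided) {
      zd <- rzeta(2, params$sigma_zeta)
      queue_b <- c(queue_b, res$t, res$t)
      queue_L <- c(queue_L, res$L / 2, res$L / 2)
      queue_z <- c(queue_z, zd)
      queue_parent <- c(queue_parent, n_done, n_done)
      queue_lin <- c(queue_lin, queue_lin[head], queue_lin[head])
    }
    head <- head + 1L
  }
  do.call(rbind, out[seq_len(n_done)])
}

#' True length of a simulated cell at arbitrary times
#'
#' Deterministic within-cycle growth `L(t) = L_birth * exp(zeta * int alpha)`
#' reconstructing the continuous trajectory of a simulated cell.
#'
#' @param cell One row of a simulated true-cell table.
#' @param t Times (h), within the cell's cycle.
#' @param model,profile Elongation model and light profile used in the
#'   simulation.
#' @return Length(s) in um.
#' @export
true_length <- function(cell, t, model, profile) {
  cell$L_birth * exp(cell$zeta * elongation_integral(cell$birth_t, t, model, profile))
}

#' Discrete observation of simulated cells
#'
#' Applies the experimental observation model: lengths are sampled on the
#' acquisition grid with additive Gaussian noise. For a division falling
#' between frames f and f+1, the parent's recorded division length (and time)
#' is taken at frame f -- the last frame before division -- while each
#' daughter's recorded birth length (and time) is taken at frame f+1, the
#' next step. Cells alive at the end of the movie are emitted as censored
#' records with empty division fields. Founder cells (first, partially
#' observed cycles) are excluded; cycles too short to span a frame are
#' dropped.
#'
#' @param true_cells True-cell table from [simulate_lineage()] or colony
#'   simulation.
#' @param config A [sim_config()] (acquisition grid and noise SD).
#' @param model,profile Elongation model and light profile of the simulation.
#' @param condition Condition label stored in the output.
#' @return A list with `cells` (the cell-table schema: `cell_id`,
#'   `lineage_id`, `parent_id`, `condition`, `birth_time_h`,
#'   `division_time_h`, `birth_length_um`, `division_length_um`, `censored`)
#'   and `traces` (`cell_id`, `time_h`, `length_um`).
#' @export
observe_cells <- function(true_cells, config, model, profile,
                          condition = "custom") {
  frames <- seq(config$t0, config$t_end, by = config$dt_acq)
  keep <- !true_cells$first_cycle
  cells_out <- vector("list", sum(keep))
  traces_out <- vector("list", sum(keep))
  j <- 0L
  for (i in which(keep)) {
    cc <- true_cells[i, ]
    ib <- match(TRUE, frames >= cc$birth_t - 1e-9)
    censored <- is.na(cc$div_t)
    id <- if (censored) length(frames) else {
      w <- which(frames <= cc$div_t + 1e-9)
      if (length(w)) max(w) else 0L
    }
    if (is.na(ib) || id < ib) next  # cycle never observed on the grid
    tt <- frames[ib:id]
    len <- true_length(cc, tt, model, profile) +
      stats::rnorm(length(tt), 0, config$noise_sd)
    len <- pmax(len, 1e-6)
    j <- j + 1L
    cells_out[[j]] <- data.frame(
      cell_id = cc$cell_id, lineage_id = cc$lineage_id,
      parent_id = cc$parent_id, condition = condition,
      birth_time_h = tt[1],
      division_time_h = if (censored) NA_real_ else tt[length(tt)],
      birth_length_um = len[1],
      division_length_um = if (censored) NA_real_ else len[length(len)],
      censored = as.integer(censored))
    traces_out[[j]] <- data.frame(cell_id = cc$cell_id, time_h = tt,
                                  length_um = len)
  }
  list(cells = do.call(rbind, cells_out[seq_len(j)]),
       traces = do.call(rbind, traces_out[seq_len(j)]))
}

#' Scenario presets
#'
#' Resolves a named scenario to its coupling function, elongation model,
#' light profile and size-control parameters. Wild-type (WT) scenarios use
#' the default single-peaked coupling ([coupling_bump()]); clock-deletion
#' scenarios use `G == 1` and, in constant light, a non-oscillatory
#' elongation rate. LD scenarios use light-tracking elongation under a graded
#' profile (12:12 by default; set `TL = 16` for 16:8).
#'
#' @param scenario One of `"WT_constant"`, `"clockdel_constant"`, `"WT_LD"`,
#'   `"clockdel_LD"`, `"custom"`.
#' @param TL Light period (h) for LD scenarios.
#' @param params Optional [size_control_params()] override.
#' @param G,model,profile Optional overrides; required for `"custom"`.
#' @return A list with components `G`, `model`, `profile`, `params`.
#' @export
scenario_settings <- function(scenario = c("WT_constant", "clockdel_constant",
                                           "WT_LD", "clockdel_LD", "custom"),
                              TL = 12, params = NULL, G = NULL, model = NULL,
                              profile = NULL) {
  scenario <- tryCatch(match.arg(scenario),
                       error = function(e) stop("unknown scenario: ", scenario[1]))
  if (is.null(params)) params <- size_control_params()
  if (scenario == "custom") {
    if (is.null(G) || is.null(model) || is.null(profile))
      stop("custom scenario requires G, model and profile")
    return(list(G = G, model = model, profile = profile, params = params))
  }
  wt <- scenario %in% c("WT_constant", "WT_LD")
  constant <- scenario %in% c("WT_constant", "clockdel_constant")
  if (is.null(G)) G <- if (wt) coupling_bump() else constant_coupling(1)
  if (is.null(profile)) {
    profile <- if (constant) light_profile("constant", A = 15)
               else light_profile("graded_LD", A = 15, TL = TL)
  }
  if (is.null(model)) {
    model <- if (constant) {
      elongation_model("constant_light_oscillatory", alpha_bar = 0.035,
                       epsilon = if (wt) 0.15 else 0, phase = 18)
    } else {
      elongation_model("light_tracking", alpha_bar = 0.035, c = 0.035 / 15)
    }
  }
  list(G = G, model = model, profile = profile, params = params)
}

#' Default simulation configuration for a scenario
#'
#' Constant-light scenarios are observed every 45 min, LD scenarios hourly,
#' matching the acquisition used in the corresponding experiments; six days
#' of simulated time starting at the first dawn, 24 founders, capped at 1,600
#' cell cycles (the experimental scale of 1,000-1,500 analysed cells per
#' condition).
#'
#' @inheritParams scenario_settings
#' @param seed Integer seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A [sim_config()].
#' @export
default_sim_config <- function(scenario = "WT_constant", seed = 1, ...) {
  constant <- scenario %in% c("WT_constant", "clockdel_constant", "custom")
  args <- list(t0 = 12, t_end = 12 + 24 * 6,
               dt_acq = if (constant) 0.75 else 1,
               n_lineages = 24, max_cells = 1600, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

#' Generate a synthetic single-cell dataset
#'
#' Runs the exact simulator under a named scenario and applies the discrete
#' observation model, producing a cell table and per-frame trace table in the
#' pipeline's exchange schema. Reproducible: the same configuration and seed
#' give identical tables.
#'
#' @param scenario See [scenario_settings()].
#' @param config A [sim_config()]; a scenario-appropriate default is used if
#'   omitted.
#' @param ... Passed to [scenario_settings()] (e.g. `TL`, `params`, `G`).
#' @param seed Convenience override of `config$seed`.
#' @return An object of class `"cg_dataset"`: a list with `cells`, `traces`,
#'   `truth` (the noiseless true-cell table), and the generating `G`,
#'   `model`, `profile`, `params`, `config`, `scenario`.
#' @export
generate_dataset <- function(scenario = "WT_constant", config = NULL,
                             seed = NULL, ...) {
  set <- scenario_settings(scenario, ...)
  if (is.null(config)) config <- default_sim_config(scenario,
                                                    seed = if (is.null(seed)) 1L else seed)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  set.seed(config$seed)
  truth <- if (config$mode == "colony") {
    simulate_colony(config, set$G, set$model, set$profile, set$params)
  } else {
    do.call(rbind, lapply(seq_len(config$n_lineages), function(i) {
      res <- simulate_lineage(config, set$G, set$model, set$profile, set$params)
      res$cells$lineage_id <- i
      res$cells$cell_id <- res$cells$cell_id + i * 100000L
      res$cells$parent_id <- res$cells$parent_id + i * 100000L
      res$cells
    }))
  }
  obs <- observe_cells(truth, config, set$model, set$profile,
                       condition = scenario)
  structure(list(cells = obs$cells, traces = obs$traces, truth = truth,
                 G = set$G, model = set$model, profile = set$profile,
                 params = set$params, config = config, scenario = scenario),
            class = "cg_dataset")
}

#' @export
print.cg_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset '%s': %d cells (%d censored), %d trace points\n",
              x$scenario, nrow(x$cells), sum(x$cells$censored),
              nrow(x$traces)))
  invisible(x)
}
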