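# Independent oracles used by the tests; deliberately simple implementations
# that do not share code with the package's simulator or estimators.

# Inverse-CDF sampler of the birth-length-independent added length under the
# Weibull-form hazard: Delta0 | entry d0b has survival
# exp(-(H(d0) - H(d0b))), H(x) = (x/lam)^k.
oracle_rdelta0 <- function(n, k, lam, d0b = 0) {
  u <- stats::runif(n)
  lam * ((pmax(d0b, 0) / lam)^k - log(u))^(1 / k)
}

# Brute-force fine-step simulator: chains of growing/dividing cells under
# constant mean elongation rate, Bernoulli division with probability
# Gamma * h per step. Returns completed cycles (birth/division times and
# lengths). G_fun maps time of day (dawn at tau = 12, dawn_offset = 12) to
# the coupling value.
oracle_bruteforce <- function(n_div, a, k, lam, alpha, G_fun, sigma_zeta = 0,
                              L_init = 3, h = 1e-3, t0 = 12, chunk = 30000) {
  out_t <- numeric(n_div); out_Lb <- numeric(n_div); out_Ld <- numeric(n_div)
  out_tb <- numeric(n_div)
  got <- 0L
  t <- t0; L0 <- L_init
  zeta <- if (sigma_zeta > 0) {
    z <- stats::rnorm(1, 1, sigma_zeta); while (z <= 0) z <- stats::rnorm(1, 1, sigma_zeta); z
  } else 1
  tb <- t
  while (got < n_div) {
    tt <- t + h * seq_len(chunk)
    L <- L0 * exp(zeta * alpha * (tt - tb))
    d0 <- L - (1 + a) * L0
    S <- ifelse(d0 > 0, (k / lam) * (pmax(d0, 0) / lam)^(k - 1), 0)
    tau <- (tt - 12 + 12) %% 24
    p <- S * G_fun(tau) * zeta * alpha * L * h
    hit <- which(stats::runif(chunk) < p)
    if (length(hit)) {
      i <- hit[1]
      got <- got + 1L
      out_t[got] <- tt[i]; out_Lb[got] <- L0; out_Ld[got] <- L[i]
      out_tb[got] <- tb
      t <- tt[i]; tb <- t; L0 <- L[i] / 2
      zeta <- if (sigma_zeta > 0) {
        z <- stats::rnorm(1, 1, sigma_zeta)
        while (z <= 0) z <- stats::rnorm(1, 1, sigma_zeta)
        z
      } else 1
    } else {
      t <- tt[chunk]
    }
  }
  data.frame(t_birth = out_tb, t_div = out_t, L_birth = out_Lb, L_div = out_Ld)
}

# Two-sample Kolmogorov-Smirnov distance.
ks_dist <- function(x, y) {
  unname(suppressWarnings(stats::ks.test(x, y)$statistic))
}

# Extract completed non-founder cycles from a simulation truth table.
truth_cycles <- function(truth) {
  truth[!truth$first_cycle & !is.na(truth$div_t), ]
}
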