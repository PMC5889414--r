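# Independent numerical oracles used to validate closed-form implementations.

# Bhattacharyya coefficient by adaptive quadrature of the defining integral
omega_quadrature <- function(mu_a, sd_a, mu_b, sd_b) {
  integrate(function(x) sqrt(dnorm(x, mu_a, sd_a) * dnorm(x, mu_b, sd_b)),
            -Inf, Inf, rel.tol = 1e-10)$value
}

# Wu-Kofke overlap by dense-grid (trapezoid) integration
kab_grid <- function(mu_a, sd_a, mu_b, sd_b, n_grid = 200001) {
  lo <- min(mu_a - 10 * sd_a, mu_b - 10 * sd_b)
  hi <- max(mu_a + 10 * sd_a, mu_b + 10 * sd_b)
  x <- seq(lo, hi, length.out = n_grid)
  pa <- dnorm(x, mu_a, sd_a)
  pb <- dnorm(x, mu_b, sd_b)
  y <- ifelse(pa + pb > 0, 2 * pa * pb / (pa + pb), 0)
  sum((y[-1] + y[-n_grid]) / 2 * diff(x))
}

# two-state harmonic fixture: forward/reverse works from exact Boltzmann
# samples of u_k(x) = K_k x^2 / 2
harmonic_pair <- function(k0 = 1, k1 = 4, n = 2000, seed = 1) {
  leg <- generate_harmonic_leg(
    harmonic_leg_spec(k0 = k0, k1 = k1, schedule = c(0, 1),
                      n_per_state = n), seed = seed)
  u <- leg$u
  list(u = u,
       w_fwd = u$u[2, u$origin == 1] - u$u[1, u$origin == 1],
       w_rev = u$u[1, u$origin == 2] - u$u[2, u$origin == 2],
       exact_df = leg$exact_df)
}

# printed benchmark quality rows, variant order RH/SP, RH/LP, BA/SP, BA/LP,
# BH/SP, BH/LP, Consensus
published_quality <- function() {
  list(
    variants = c("RH/SP", "RH/LP", "BA/SP", "BA/LP", "BH/SP", "BH/LP",
                 "Consensus"),
    mad = c(1.8, 2.8, 2.3, 2.2, 2.6, 2.5, 2.1),
    rmsd = c(2.3, 3.4, 3.4, 2.7, 3.5, 3.3, 2.7),
    msd = c(0.4, 1.1, -0.1, 0.7, 0.0, 0.0, 0.4),
    max = c(4.3, 6.6, 6.4, 4.8, 6.7, 6.4, 4.7),
    r2 = c(0.79, 0.54, 0.61, 0.71, 0.55, 0.60, 0.71),
    tau_r = c(1, 2 / 3, 1 / 3, 1, 1 / 3, 1, 1),
    tau_r90 = c(1, 0.6, 1 / 3, 1, 0.6, 1, 1))
}

quality_value <- function(q, variant_, metric_) {
  df <- as.data.frame(q)
  df$value[df$variant == variant_ & df$metric == metric_]
}
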