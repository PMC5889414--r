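test_that("MBAR satisfies its degenerate and covariance identities", {
  set.seed(1)
  # identical states carry zero free-energy difference
  row <- rnorm(40)
  u <- rbind(row, row)
  fit <- mbar(u, origin = rep(1:2, each = 20))
  expect_equal(coef(fit), c(0, 0), tolerance = 1e-9,
               ignore_attr = TRUE)
  # adding a constant to row k shifts f_k by exactly that constant
  leg <- generate_harmonic_leg(
    harmonic_leg_spec(schedule = c(0, 0.5, 1), n_per_state = 200),
    seed = 3)
  base <- coef(mbar(leg$u))
  u2 <- leg$u$u
  u2[3, ] <- u2[3, ] + 1.7
  shifted <- coef(mbar(u2, origin = leg$u$origin))
  expect_equal(shifted - base, c(0, 0, 1.7), tolerance = 1e-8,
               ignore_attr = TRUE)
  # anchoring: f[1] is exactly zero
  expect_identical(base[1], 0)
})

test_that("MBAR recovers the analytic harmonic free energy", {
  leg <- generate_harmonic_leg(harmonic_leg_spec(n_per_state = 500),
                               seed = 11)
  fit <- mbar(leg$u, n_boot = 40, seed = 5)
  K <- length(coef(fit))
  se <- sd(fit$boot_f[, K] - fit$boot_f[, 1])
  expect_lt(abs(coef(fit)[K] - leg$exact_df), 3 * se)
  # per-state analytic profile tracks too
  expect_equal(coef(fit), leg$exact_f, tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("reversing the lambda order negates the end-to-end estimate", {
  leg <- generate_harmonic_leg(
    harmonic_leg_spec(schedule = c(0, 0.3, 1), n_per_state = 300),
    seed = 7)
  f_fwd <- coef(mbar(leg$u))
  f_rev <- coef(mbar(reverse_states(leg$u)))
  expect_lt(abs(f_fwd[3] + f_rev[3]), 1e-9)
})

test_that("MBAR refuses unusable input", {
  u <- matrix(rnorm(20), nrow = 2)
  expect_error(mbar(u), "'origin' is required")
  expect_error(mbar(matrix(rnorm(10), 1), origin = rep(1, 10)),
               "at least two states")
  expect_error(mbar(u, origin = rep(1:2, each = 5), n_boot = 1),
               "at least 2")
  expect_error(mbar(u, origin = rep(1:2, each = 5), max_iter = 1),
               "failed to converge")
})

test_that("stratified bootstrap errors vanish for identical states and
           match regeneration spread on the harmonic toy", {
  row <- rnorm(50)
  fit <- mbar(rbind(row, row), origin = rep(1:2, each = 25), n_boot = 30,
              seed = 2)
  expect_lt(fit$se[2], 1e-6)
  # bootstrap SE within a factor 2 of the spread over regenerations
  spec <- harmonic_leg_spec(schedule = c(0, 0.5, 1), n_per_state = 250)
  regen <- vapply(1:30, function(s) {
    leg <- generate_harmonic_leg(spec, seed = 100 + s)
    f <- coef(mbar(leg$u))
    f[3] - f[1]
  }, numeric(1))
  leg <- generate_harmonic_leg(spec, seed = 100 + 1)
  fit <- mbar(leg$u, n_boot = 100, seed = 9)
  se_boot <- sd(fit$boot_f[, 3] - fit$boot_f[, 1])
  expect_gt(se_boot, sd(regen) / 2)
  expect_lt(se_boot, sd(regen) * 2)
  # fixed seed makes the bootstrap bit-reproducible
  fit2 <- mbar(leg$u, n_boot = 100, seed = 9)
  expect_identical(fit$boot_f, fit2$boot_f)
})

test_that("fast and log-domain solver kernels agree; extreme potentials
           fall back gracefully", {
  leg <- generate_harmonic_leg(
    harmonic_leg_spec(schedule = c(0, 0.5, 1), n_per_state = 100),
    seed = 19)
  fast <- relfep:::.mbar_scf_fast(leg$u$u, leg$u$n_k, numeric(3), 1e-12,
                                  500L)
  safe <- relfep:::.mbar_scf(leg$u$u, leg$u$n_k, numeric(3), 1e-12, 500L)
  expect_true(fast$stable && fast$converged && safe$converged)
  expect_equal(fast$f, safe$f, tolerance = 1e-12)
  # a zero-sample perturbation state with an extreme potential row breaks
  # the multiply-add path; mbar() must still solve it via the log domain
  u <- rbind(leg$u$u, leg$u$u[3, ] - 2000)
  fit <- mbar(u, origin = leg$u$origin)
  expect_false(relfep:::.mbar_scf_fast(u, c(leg$u$n_k, 0L), numeric(4),
                                       1e-10, 100L)$stable)
  expect_equal(coef(fit)[4], coef(fit)[3] - 2000, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("exponential averaging matches its closed forms", {
  expect_equal(exponential_average(rep(2.5, 10)), 2.5)
  # two-term brute force: dominated by the small work
  expect_equal(exponential_average(c(0, 50)),
               -log((exp(0) + exp(-50)) / 2))
  expect_equal(exponential_average(c(0, 50)), log(2), tolerance = 1e-10)
  # overflow safety for very large works
  expect_true(is.finite(exponential_average(c(1000, 1001))))
  # Gaussian closed form mu - sigma^2/2
  set.seed(31)
  w <- rnorm(1e5, 2, sqrt(2))
  expect_equal(exponential_average(w), 1, tolerance = 0.05)
  expect_error(exponential_average(numeric()), "no work values")
})

test_that("BAR agrees with MBAR at K = 2 and with symmetry", {
  hp <- harmonic_pair(n = 2000, seed = 13)
  dg_bar <- bar(hp$w_fwd, hp$w_rev)
  dg_mbar <- coef(mbar(hp$u))[2]
  expect_lt(abs(dg_bar - dg_mbar), 1e-6)
  # symmetric construction: same work multiset in both directions -> 0
  set.seed(4)
  w <- rnorm(500, 0, 1)
  expect_lt(abs(bar(w, w)), 1e-9)
  # high-overlap Gaussian works: BAR between the two exponential averages
  gw <- generate_gaussian_work(1, 0.5, 5e4, seed = 6)
  dg <- bar(gw$w_fwd, gw$w_rev)
  expect_equal(dg, 1, tolerance = 0.02)
  expect_error(bar(numeric(), 1), "both work directions")
})

test_that("estimator family is consistent on well-overlapping Gaussians", {
  gw <- generate_gaussian_work(0.8, 1, 5e4, seed = 21)
  fwd <- exponential_average(gw$w_fwd)
  rev <- -exponential_average(gw$w_rev)
  dg <- bar(gw$w_fwd, gw$w_rev)
  expect_equal(fwd, 0.8, tolerance = 0.05)
  expect_equal(rev, 0.8, tolerance = 0.05)
  expect_equal(dg, 0.8, tolerance = 0.05)
})

test_that("analytic harmonic free energy lies within 3 SE across seeds", {
  spec <- harmonic_leg_spec(schedule = c(0, 0.25, 0.5, 0.75, 1),
                            n_per_state = 200)
  hits <- vapply(1:20, function(s) {
    leg <- generate_harmonic_leg(spec, seed = 400 + s)
    fit <- mbar(leg$u, n_boot = 30, seed = s)
    K <- length(coef(fit))
    se <- sd(fit$boot_f[, K] - fit$boot_f[, 1])
    abs(coef(fit)[K] - leg$exact_df) <= 3 * se
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("leg estimates convert to kJ/mol and combine through the cycle", {
  # quadrature rule: 3-4-5
  expect_equal(se_quadrature(c(0.3, 0.4)), 0.5)
  leg <- generate_harmonic_leg(harmonic_leg_spec(n_per_state = 200),
                               seed = 17)
  est <- leg_free_energy(leg$u, "protein", "A->B", n_boot = 30, seed = 1)
  expect_equal(est$value, 0.6931472 * kT_kJmol(300), tolerance = 0.15)
  expect_equal(est$value / kT_kJmol(300), leg$exact_df, tolerance = 0.1)
  p <- free_energy_estimate(5.0, 0.2, "protein", "A->B")
  w <- free_energy_estimate(3.0, 0.2, "water", "A->B")
  dd <- combine_cycle(p, w)
  expect_equal(dd$value, 2.0)
  expect_equal(dd$se, sqrt(0.08))
  expect_identical(dd$phase, "binding")
  # equal legs cancel
  expect_equal(combine_cycle(p, free_energy_estimate(5, 0.2, "water",
                                                     "A->B"))$value, 0)
  w2 <- free_energy_estimate(3.0, 0.2, "water", "C->D")
  expect_error(combine_cycle(p, w2), "different transformations")
  expect_error(combine_cycle(w, w), "protein leg and a water leg")
})
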