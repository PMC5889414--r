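gal_calc <- function(variant) {
  res <- galectin3_calculated()
  res[res$variant == variant, ]
}

test_that("deviation statistics reproduce the published RH/SP row", {
  calc <- gal_calc("RH/SP")
  exp <- galectin3_experimental()
  d <- deviation_stats(calc$ddG, exp$ddG[match(calc$transformation,
                                               exp$transformation)])
  expect_equal(d[["mad"]], 1.8, tolerance = 0.05)
  expect_equal(d[["msd"]], 0.4, tolerance = 0.05)
  expect_equal(deviation_stats(1:5, 1:5),
               c(mad = 0, msd = 0, rmsd = 0, max = 0))
  expect_error(deviation_stats(1:3, 1:4), "differ in length")
})

test_that("deviation statistics obey their order relations on random tables", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(2:10, 1)
    calc <- rnorm(n, 0, 5)
    exp <- rnorm(n, 0, 5)
    d <- deviation_stats(calc, exp)
    expect_lte(d[["mad"]], d[["rmsd"]] + 1e-12)
    expect_lte(d[["rmsd"]], d[["max"]] + 1e-12)
    expect_lte(abs(d[["msd"]]), d[["mad"]] + 1e-12)
  }
})

test_that("bidirectional R2 is direction-symmetric and scale-invariant", {
  calc <- gal_calc("RH/SP")
  exp <- galectin3_experimental()
  y <- exp$ddG[match(calc$transformation, exp$transformation)]
  r2 <- bidirectional_r2(calc$ddG, y)
  expect_equal(r2, 0.79, tolerance = 0.02)
  # equals ordinary squared Pearson correlation on the doubled point set
  expect_equal(r2, cor(c(calc$ddG, -calc$ddG), c(y, -y))^2)
  # flipping any single transformation on both axes changes nothing
  for (i in seq_along(y)) {
    x2 <- calc$ddG; y2 <- y
    x2[i] <- -x2[i]; y2[i] <- -y2[i]
    expect_equal(bidirectional_r2(x2, y2), r2)
  }
  expect_equal(bidirectional_r2(2 * calc$ddG, y), r2)
  expect_equal(bidirectional_r2(calc$ddG, 3 * y), r2)
  expect_equal(bidirectional_r2(y * 2, y), 1)
  expect_error(bidirectional_r2(rep(0, 3), 1:3), "identically zero")
})

test_that("sign-concordance tau follows the tie rule on published columns", {
  exp <- galectin3_experimental()
  rh <- gal_calc("RH/SP")
  y <- exp$ddG[match(rh$transformation, exp$transformation)]
  t_rh <- tau_r(rh$ddG, y)
  expect_equal(as.numeric(t_rh), 1)          # 6 concordant + 1 tie
  expect_equal(attr(t_rh, "n_used"), 6L)
  ba <- gal_calc("BA/SP")
  t_ba <- tau_r(ba$ddG, y)
  expect_equal(as.numeric(t_ba), 1 / 3)      # 4 concordant, 2 discordant
  expect_equal(attr(t_ba, "concordant"), 4L)
  expect_equal(attr(t_ba, "discordant"), 2L)
  # antisymmetry
  expect_equal(as.numeric(tau_r(-ba$ddG, y)), -1 / 3)
  # positive rescaling changes nothing
  expect_equal(as.numeric(tau_r(ba$ddG * 10, y)), 1 / 3)
  expect_error(tau_r(c(0, 0), c(1, 2)), "ties")
})

test_that("tau_r90 filters insignificant values, published BH/SP drops one", {
  exp <- galectin3_experimental()
  bh <- gal_calc("BH/SP")
  y <- exp$ddG[match(bh$transformation, exp$transformation)]
  yse <- exp$se[match(bh$transformation, exp$transformation)]
  t90 <- tau_r90(bh$ddG, bh$se, y, yse)
  # OMe->OH drops (|-0.6| < 1.645 * 0.4), NHMe->OMe insignificant on the
  # experimental side; 4 concordant + 1 discordant remain
  expect_equal(as.numeric(t90), 0.6)
  expect_equal(attr(t90, "n_used"), 5L)
  # unreported experimental SE always passes the experimental filter
  expect_true("Pyr->F" %in% bh$transformation[abs(bh$ddG) >=
                                                1.645 * bh$se])
  # vacuous filter reduces to tau_r
  expect_equal(as.numeric(tau_r90(bh$ddG, rep(0, 7), y,
                                  rep(0, 7))),
               as.numeric(tau_r(bh$ddG, y)))
  expect_error(tau_r90(bh$ddG, bh$se, y, yse, z90 = 1e6),
               "no transformation")
})

test_that("parametric-simulation uncertainty matches degenerate and
           Monte-Carlo oracles", {
  # all SEs zero: every metric is exactly reproduced in every replicate
  for (m in c("mad", "rmsd", "r2", "tau_r")) {
    expect_equal(metric_uncertainty(c(1, -2, 3), rep(0, 3),
                                    c(1.5, -1, 2), rep(0, 3), m,
                                    n_rep = 50, seed = 1), 0)
  }
  # single transformation, folded-normal MAD: compare with direct MC
  sd_sim <- metric_uncertainty(5, 0.5, 0, NA_real_, "mad",
                               n_rep = 20000, seed = 2)
  set.seed(3)
  oracle <- sd(abs(rnorm(1e5, 5, 0.5)))
  expect_equal(sd_sim, oracle, tolerance = 0.05 * oracle)
  # seeded runs are bit-reproducible; doubling n_rep only jitters
  a <- metric_uncertainty(c(2, -3), c(0.5, 0.5), c(1, -2), c(0.2, 0.2),
                          "rmsd", n_rep = 2000, seed = 7)
  b <- metric_uncertainty(c(2, -3), c(0.5, 0.5), c(1, -2), c(0.2, 0.2),
                          "rmsd", n_rep = 2000, seed = 7)
  expect_identical(a, b)
  c2 <- metric_uncertainty(c(2, -3), c(0.5, 0.5), c(1, -2), c(0.2, 0.2),
                           "rmsd", n_rep = 4000, seed = 8)
  expect_equal(a, c2, tolerance = 0.1)
  expect_error(metric_uncertainty(1, 1, 0, 0, "mad", n_rep = 1),
               "at least 2")
  # a metric failing in most replicates is an error, not a silent NA
  expect_error(
    metric_uncertainty(0.1, 10, 0.1, 10, "tau_r90", n_rep = 200,
                       seed = 4),
    "more than 10%")
})

test_that("consensus averages variants with SE from their spread", {
  res <- galectin3_calculated()
  cons <- consensus(res)
  pub <- galectin3_consensus()
  i <- match(pub$transformation, cons$transformation)
  expect_equal(cons$ddG[i], pub$ddG, tolerance = 0.06)
  expect_equal(cons$se[i], pub$se, tolerance = 0.06)
  # NHMe->OMe: -4.7 +/- 0.9 as published
  j <- cons$transformation == "NHMe->OMe"
  expect_equal(cons$ddG[j], -4.7, tolerance = 0.05)
  expect_equal(cons$se[j], 0.9, tolerance = 0.05)
  # identical variants collapse to zero SE
  flat <- fep_results(rep(c("A->B", "B->C"), each = 2),
                      rep(c("X", "Y"), 2), c(1, 1, 2, 2), 0.1)
  expect_equal(consensus(flat)$se, c(0, 0))
  expect_error(consensus(fep_results("A->B", "X", 1, 0.1)),
               "not rectangular|at least two")
})

test_that("variant difference z-test", {
  t1 <- variant_difference_test(1.0, 0.5, 3.0, 0.5)
  expect_equal(t1$z, 2 / sqrt(0.5), tolerance = 1e-6)
  expect_true(t1$significant)
  t2 <- variant_difference_test(2, 0.4, 2, 0.4)
  expect_equal(t2$z, 0)
  expect_false(t2$significant)
  expect_equal(variant_difference_test(1, 1, 2, 1, level = 0.9)$z_crit,
               qnorm(0.95))
  expect_error(variant_difference_test(1, 0, 2, 0), "both standard errors")
})

test_that("evaluation handles exclusions and mismatched keys", {
  res <- galectin3_calculated()
  exp <- galectin3_experimental()
  q_all <- evaluate_affinities(res, exp, n_rep = 50, seed = 1)
  expect_setequal(unique(q_all$variant), c(method_variants(), "Consensus"))
  # empty exclusion equals the default
  q_none <- evaluate_affinities(res, exp, exclude = character(),
                                n_rep = 50, seed = 1)
  expect_equal(as.data.frame(q_all), as.data.frame(q_none))
  # excluding the largest transformation collapses R2 into the 0.12-0.38
  # band
  q_ex <- evaluate_affinities(res, exp, exclude = "Pyr->F", n_rep = 50,
                              seed = 1)
  r2 <- q_ex$value[q_ex$metric == "r2" & q_ex$variant != "Consensus"]
  expect_true(all(r2 > 0.1 & r2 < 0.4))
  expect_error(evaluate_affinities(res, exp, exclude = "bogus"),
               "unknown transformation")
  exp_short <- fep_experimental("A->B", 1, 0.1)
  expect_error(evaluate_affinities(res, exp_short, n_rep = 50),
               "not shared")
})
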