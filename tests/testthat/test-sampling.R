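# Ensemble sampling, stability classification, correlations, PSW sweeps.

test_that("leading eigenvalue: ties, convention, and dense-solver agreement", {
  expect_equal(leading_eigenvalue(matrix(-1.5)), -1.5 + 0i)
  # rotation matrix: real parts tie at zero, Im >= 0 representative returned
  expect_equal(leading_eigenvalue(matrix(c(0, 1, -1, 0), 2, 2)), 0 + 1i)
  set.seed(5)
  for (rep in 1:20) {
    J <- matrix(stats::rnorm(25), 5, 5)
    lead <- leading_eigenvalue(J)
    ev <- eigen(J, only.values = TRUE)$values
    expect_equal(Re(lead), max(Re(ev)), tolerance = 1e-10)
  }
  expect_error(leading_eigenvalue(matrix(1, 2, 3)), "square")
  expect_error(leading_eigenvalue(matrix(c(1, NA, 0, 1), 2, 2)), "finite")
})

test_that("stability indicator is strict at the boundary", {
  expect_equal(stability_indicator(-1.5), 1L)
  expect_equal(stability_indicator(0.3 + 2i), 0L)
  expect_equal(stability_indicator(0 + 0i), 0L)
  expect_equal(stability_indicator(0 + 5i), 0L)
})

test_that("ensembles are deterministic under a seed and bounded by their ranges", {
  j <- pp_jacobian()
  e1 <- gm_sample_ensemble(j, M = 300, seed = 99)
  e2 <- gm_sample_ensemble(j, M = 300, seed = 99)
  expect_identical(e1, e2)
  e3 <- gm_sample_ensemble(j, M = 300, seed = 100)
  expect_false(identical(e1$lambda_re, e3$lambda_re))
  rng <- gm_ranges(j, f_x = c(0.25, 0.75))
  e4 <- gm_sample_ensemble(j, M = 200, seed = 1, ranges = rng)
  expect_true(all(e4$f_x >= 0.25 & e4$f_x <= 0.75))
  expect_true(all(e4$sigma_f_x >= 0 & e4$sigma_f_x <= 1))
  expect_true(all(e4$stable %in% c(0L, 1L)))
})

test_that("1-D classification agrees exactly with the closed form g_x < l_x", {
  j <- gm_jacobian(gm_fixture("one_d_gain_loss"))
  ens <- gm_sample_ensemble(j, M = 5000, seed = 21)
  expect_identical(ens$stable, as.integer(ens$g_x < ens$l_x))
  # lambda equals alpha * (g_x - l_x) on every sample
  expect_equal(ens$lambda_re, ens$alpha_x * (ens$g_x - ens$l_x), tolerance = 1e-12)
})

test_that("stable fraction matches analytic probabilities of the sampling ranges", {
  j <- gm_jacobian(gm_fixture("one_d_gain_loss"))
  M <- 20000
  # g_x, l_x ~ U(0,2): P(g_x < l_x) = 1/2
  ens <- gm_sample_ensemble(j, M = M, seed = 4)
  se <- sqrt(0.25 / M)
  expect_lt(abs(mean(ens$stable) - 0.5), 3 * se)
  # g_x ~ U(0,1), l_x ~ U(0,2): P = 3/4 (area integration)
  rng <- gm_ranges(j, g_x = c(0, 1))
  ens2 <- gm_sample_ensemble(j, M = M, seed = 4, ranges = rng)
  expect_lt(abs(mean(ens2$stable) - 0.75), 3 * sqrt(0.75 * 0.25 / M))
})

test_that("degenerate ranges give a deterministic single evaluation", {
  j <- gm_jacobian(gm_fixture("one_d_gain_loss"))
  rng <- gm_ranges(j, g_x = c(0.5, 0.5), l_x = c(2, 2), alpha_x = c(1, 1))
  ens <- gm_sample_ensemble(j, M = 1, seed = 123, ranges = rng)
  expect_equal(ens$lambda_re, -1.5)
  expect_equal(ens$stable, 1L)
})

test_that("uncovered symbols and bad ranges are configuration errors", {
  j <- pp_jacobian()
  expect_error(gm_ranges(j, nope = c(0, 1)), "not a free parameter")
  expect_error(gm_ranges(j, sigma_f_x = c(0, 1)), "simplex")
  expect_error(gm_ranges(j, alpha_y = c(-1, 1)), "strictly positive")
  expect_error(gm_ranges(j, f_x = c(2, 1)), "lo <= hi")
})

test_that("stability correlation calibrates to +/-1 and the point-biserial value", {
  j <- gm_jacobian(gm_fixture("one_d_gain_loss"))
  # stability fully determined by g_x (others held constant):
  # s = 1{g_x < 1}, g_x ~ U(0,2); the point-biserial correlation of a
  # threshold at the median is -sqrt(3)/2 (cov = -1/8, sd = (2/sqrt(12))*(1/2))
  rng <- gm_ranges(j, l_x = c(1, 1), alpha_x = c(1, 1))
  ens <- gm_sample_ensemble(j, M = 40000, seed = 8, ranges = rng)
  sc <- gm_stability_correlation(ens)
  expect_equal(sc$score[sc$symbol == "g_x"], -sqrt(3) / 2, tolerance = 0.02)
  expect_true(all(is.na(sc$score[sc$symbol %in% c("l_x", "alpha_x")])))
  expect_true(all(abs(sc$score) <= 1, na.rm = TRUE))
  # perfect stabilizer / destabilizer via synthetic parameter columns
  ens$copy <- as.numeric(ens$stable)
  ens$anti <- 1 - as.numeric(ens$stable)
  sc2 <- gm_stability_correlation(ens)
  expect_equal(sc2$score[sc2$symbol == "copy"], 1)
  expect_equal(sc2$score[sc2$symbol == "anti"], -1)
  # covariance option drops the normalization
  sc3 <- gm_stability_correlation(ens, normalize = FALSE)
  expect_equal(sc3$score[sc3$symbol == "copy"],
               stats::var(as.numeric(ens$stable)))
})

test_that("constant stability indicator yields NA scores with a warning", {
  j <- gm_jacobian(gm_fixture("one_d_gain_loss"))
  rng <- gm_ranges(j, g_x = c(0, 0.4), l_x = c(1, 2))
  ens <- gm_sample_ensemble(j, M = 50, seed = 2, ranges = rng)
  expect_warning(sc <- gm_stability_correlation(ens), "constant")
  expect_true(all(is.na(sc$score)))
})

test_that("PSW sweep matches the analytic P(g_x < l_x) = l_x / 2 per cell", {
  j <- gm_jacobian(gm_fixture("one_d_gain_loss"))
  grid <- c(0.5, 1, 1.5, 2)
  sw <- gm_psw_sweep(j, list(l_x = grid), M = 4000, seed = 31)
  expect_equal(sw$l_x, grid)
  expect_true(all(sw$psw >= 0 & sw$psw <= 1))
  for (i in seq_along(grid)) {
    p <- grid[i] / 2
    expect_lt(abs(sw$psw[i] - p), 3 * sqrt(p * (1 - p) / 4000) + 1e-9)
  }
})

test_that("a sweep cell equals an independent clamped ensemble within sampling error", {
  j <- pp_jacobian()
  sw <- gm_psw_sweep(j, list(f_x = c(0.5, 1.5)), M = 3000, seed = 17)
  for (i in 1:2) {
    rng <- gm_ranges(j, f_x = rep(sw$f_x[i], 2))
    ens <- gm_sample_ensemble(j, M = 3000, seed = 1000 + i, ranges = rng)
    expect_lt(abs(sw$psw[i] - mean(ens$stable)), 4 * sqrt(0.25 / 3000) * 2)
  }
})

test_that("two-parameter sweeps cover the grid and stay in [0, 1]", {
  j <- pp_jacobian()
  sw <- gm_psw_sweep(j, list(alpha_y = c(0.5, 1, 2), f_x = c(0.5, 1.5)),
                     M = 400, seed = 9)
  expect_equal(nrow(sw), 6)
  expect_true(all(sw$psw >= 0 & sw$psw <= 1))
  expect_error(gm_psw_sweep(j, list(nope = 1:3), M = 10, seed = 1),
               "not in the Jacobian")
  expect_error(gm_psw_sweep(j, list(), M = 10, seed = 1), "named list")
})

test_that("tidiers and autoplot methods return the documented shapes", {
  j <- gm_jacobian(gm_fixture("one_d_gain_loss"))
  ens <- gm_sample_ensemble(j, M = 500, seed = 12)
  td <- tidy(ens)
  expect_named(td, c("symbol", "score"))
  gl <- glance(ens)
  expect_equal(gl$n_samples, 500)
  expect_equal(gl$seed, 12)
  sw <- gm_psw_sweep(j, list(l_x = c(0.5, 1.5)), M = 100, seed = 3)
  expect_s3_class(autoplot(sw), "ggplot")
  sc <- gm_stability_correlation(ens)
  expect_s3_class(autoplot(sc), "ggplot")
})
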