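# Saddle-node-type and Hopf detection, grids, and the bialternate cross-check.

# a model whose Jacobian is [[a, -1], [1, 0]] for alpha_x = alpha_y = 1,
# g1_y = -1, g2_x = 1, with a = g1_x free
oscillator_jacobian <- function() {
  m <- gm_model("oscillator") |>
    gm_add_variable("X") |> gm_add_variable("Y") |>
    gm_add_process("G1", gain = "X", dependencies = c("X", "Y")) |>
    gm_add_process("L1", loss = "X") |>
    gm_add_process("G2", gain = "Y", dependencies = "X") |>
    gm_add_process("L2", loss = "Y")
  gm_jacobian(m)
}

osc_base <- list(alpha_x = 1, alpha_y = 1, g1_y = -1, g2_x = 1)

test_that("1-D zero-eigenvalue hit sits exactly at the stability boundary g_x = l_x", {
  j <- gm_jacobian(gm_fixture("one_d_gain_loss"))
  path <- gm_path(base = list(alpha_x = 1, l_x = 1), param = "g_x", from = 0, to = 2)
  hits <- scan_zero_eigenvalue(j, path, tol = 1e-8)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$type, "zero_eigenvalue")
  expect_equal(hits$location, 1, tolerance = 1e-8)
  expect_lt(hits$residual, 1e-8)
  expect_lt(abs(hits$eigen_re), 1e-7)
})

test_that("a path inside the stable region yields no hits", {
  j <- gm_jacobian(gm_fixture("one_d_gain_loss"))
  path <- gm_path(base = list(alpha_x = 1, l_x = 2), param = "g_x", from = 0, to = 1.5)
  expect_equal(nrow(scan_zero_eigenvalue(j, path)), 0)
})

test_that("predator-prey determinant root matches a fine-grid scan oracle", {
  j <- pp_jacobian()
  base <- stable_pp_params()
  path <- gm_path(base = base, param = "f_x", from = 0, to = 2)
  hits <- scan_zero_eigenvalue(j, path, tol = 1e-8)
  # oracle: brute-force dense determinant scan
  ts <- seq(0, 2, length.out = 20001)
  dets <- vapply(ts, function(v) {
    q <- base; q$f_x <- v
    det(gm_eval_jacobian(j, q))
  }, numeric(1))
  flips <- which(diff(sign(dets)) != 0)
  expect_equal(nrow(hits), length(flips))
  for (k in seq_along(flips)) {
    expect_equal(hits$location[k], ts[flips[k]], tolerance = 1e-3)
  }
})

test_that("Hopf detection on the rotation family finds a = 0 with pair +/- i", {
  j <- oscillator_jacobian()
  path <- gm_path(base = osc_base, param = "g1_x", from = -1, to = 1)
  hits <- scan_hopf(j, path, tol = 1e-8)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$type, "hopf")
  expect_equal(hits$location, 0, tolerance = 1e-8)
  expect_equal(hits$eigen_im, 1, tolerance = 1e-6)
  expect_lt(hits$residual, 1e-8)
})

test_that("Hopf scanning is a structural error in one dimension", {
  j <- gm_jacobian(gm_fixture("one_d_gain_loss"))
  path <- gm_path(base = list(alpha_x = 1, l_x = 1), param = "g_x", from = 0, to = 2)
  expect_error(scan_hopf(j, path), "one-dimensional")
})

test_that("predator-prey Hopf coincides with the 2x2 trace-zero condition", {
  j <- pp_jacobian()
  # keep alpha (g_y - m_y) < 0 so det > 0 where the trace crosses zero
  base <- list(alpha_y = 1, sigma_f_x = 0.5, f_x = 1.5, f_y = 1,
               l_x = 1, g_x = 1, g_y = 0.5, m_y = 1, s_x = 0)
  path <- gm_path(base = base, param = "s_x", from = 0, to = 2)
  hits <- scan_hopf(j, path, tol = 1e-8)
  expect_equal(nrow(hits), 1)
  # closed form: trace = s_x - rho f_x - (1-rho) l_x + alpha (g_y - m_y) = 0
  s_star <- with(base, sigma_f_x * f_x + (1 - sigma_f_x) * l_x -
                   alpha_y * (g_y - m_y))
  expect_equal(hits$location, s_star, tolerance = 1e-7)
  J <- gm_eval_jacobian(j, modifyList(base, list(s_x = hits$location)))
  expect_gt(det(J), 1e-6)
})

test_that("hits respect the determinant/eigenvalue consistency invariants", {
  j <- pp_jacobian()
  base <- stable_pp_params()
  tol <- 1e-8
  zpath <- gm_path(base = base, param = "f_x", from = 0, to = 2)
  zh <- scan_zero_eigenvalue(j, zpath, tol = tol)
  for (k in seq_len(nrow(zh))) {
    expect_lt(zh$residual[k], tol)
    expect_lt(sqrt(zh$eigen_re[k]^2 + zh$eigen_im[k]^2), 10 * tol)
  }
  hpath <- gm_path(base = modifyList(base, list(g_y = 0.5)), param = "s_x",
                   from = 0, to = 2)
  hh <- scan_hopf(j, hpath, tol = tol)
  for (k in seq_len(nrow(hh))) {
    expect_lt(abs(hh$eigen_re[k]), tol)
    expect_gt(abs(hh$eigen_im[k]), tol)
    J <- gm_eval_jacobian(j, modifyList(modifyList(base, list(g_y = 0.5)),
                                        stats::setNames(list(hh$location[k]), "s_x")))
    expect_gt(abs(det(J)), tol)
  }
})

test_that("hits are invariant under path reparameterization and grid refinement", {
  j <- gm_jacobian(gm_fixture("one_d_gain_loss"))
  p1 <- gm_path(base = list(alpha_x = 1, l_x = 1), param = "g_x", from = 0, to = 2)
  p2 <- gm_path(base = list(alpha_x = 1, l_x = 1), param = "g_x", from = 2, to = 0)
  h1 <- scan_zero_eigenvalue(j, p1, n_grid = 200L)
  h2 <- scan_zero_eigenvalue(j, p2, n_grid = 200L)
  h3 <- scan_zero_eigenvalue(j, p1, n_grid = 997L)
  expect_equal(h1$location, h2$location, tolerance = 1e-7)
  expect_equal(h1$location, h3$location, tolerance = 1e-7)
  # waypoint form agrees with the segment form
  wp <- gm_path(waypoints = list(list(alpha_x = 1, l_x = 1, g_x = 0),
                                 list(alpha_x = 1, l_x = 1, g_x = 2)))
  h4 <- scan_zero_eigenvalue(j, wp)
  expect_equal(nrow(h4), 1)
})

test_that("bialternate product has pairwise eigenvalue sums; det vanishes at Hopf", {
  set.seed(41)
  for (rep in 1:5) {
    J <- matrix(stats::rnorm(16), 4, 4)
    B <- gm_bialternate(J)
    ev <- eigen(J, only.values = TRUE)$values
    sums <- c()
    for (i in 2:4) for (jdx in 1:(i - 1)) sums <- c(sums, ev[i] + ev[jdx])
    expect_equal(sort(Re(eigen(B, only.values = TRUE)$values)), sort(Re(sums)),
                 tolerance = 1e-8)
  }
  # cross-check the tracking detector: det(2J (.) I) = 0 at the located Hopf
  j <- oscillator_jacobian()
  path <- gm_path(base = osc_base, param = "g1_x", from = -1, to = 1)
  hit <- scan_hopf(j, path)
  Jh <- gm_eval_jacobian(j, modifyList(osc_base, list(g1_x = hit$location)))
  expect_lt(abs(det(gm_bialternate(Jh))), 1e-8)
})

test_that("grid classification recovers the 1-D stability region g_x < l_x exactly", {
  j <- gm_jacobian(gm_fixture("one_d_gain_loss"))
  g <- classify_grid(j, axes = list(g_x = seq(0.1, 1.9, by = 0.2),
                                    l_x = seq(0.1, 1.9, by = 0.2)),
                     fixed = list(alpha_x = 1))
  expect_setequal(unique(g$class[g$g_x < g$l_x]), "stable")
  expect_true(all(g$class[g$g_x >= g$l_x] == "unstable_real"))
})

test_that("predator-prey diagram: one connected stable region touching high l_x / low f_x", {
  j <- pp_jacobian()
  fixed <- list(alpha_y = 1, sigma_f_x = 0.5, f_y = 1, g_x = 1, g_y = 0.5,
                m_y = 1, s_x = 1)
  g <- classify_grid(j, axes = list(f_x = seq(0, 2, by = 0.25),
                                    l_x = seq(0, 2, by = 0.25)), fixed = fixed)
  corner <- g[g$f_x == 0 & g$l_x == 2, ]
  expect_equal(corner$class, "stable")
  # connectedness: along each l_x slice the stable cells form one contiguous run
  for (lv in unique(g$l_x)) {
    s <- g$class[g$l_x == lv][order(g$f_x[g$l_x == lv])] == "stable"
    expect_lte(sum(rle(s)$values), 1)
  }
  expect_error(classify_grid(j, axes = list()), "named list")
  expect_error(classify_grid(j, axes = list(zzz = 1:3)), "not free")
})

test_that("oscillatory versus real instabilities are distinguished", {
  j <- oscillator_jacobian()
  g <- classify_grid(j, axes = list(g1_x = c(-0.5, 0.5)),
                     fixed = osc_base[c("alpha_x", "alpha_y", "g1_y", "g2_x")])
  expect_equal(g$class, c("stable", "unstable_oscillatory"))
  g2 <- classify_grid(gm_jacobian(gm_fixture("one_d_gain_loss")),
                      axes = list(g_x = c(2)), fixed = list(alpha_x = 1, l_x = 1))
  expect_equal(g2$class, "unstable_real")
})
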