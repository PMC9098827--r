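# Normalization: scale parameters, elasticities, Jacobian assembly,
# timescale normalization and constraint substitution.

p_sym <- genmod:::p_sym
p_const <- genmod:::p_const
p_add <- genmod:::p_add
p_sub <- genmod:::p_sub
p_mul <- genmod:::p_mul
p_equal <- genmod:::p_equal

test_that("scale skeleton: turnovers, branching groups and sum-to-one", {
  sp1 <- gm_scale_parameters(gm_fixture("one_d_gain_loss"))
  expect_equal(unname(sp1$turnover), "alpha_x")
  expect_length(sp1$groups, 0)

  spp <- gm_scale_parameters(gm_fixture("predator_prey"))
  expect_equal(unname(spp$turnover), c("alpha_x", "alpha_y"))
  expect_length(spp$groups, 1)
  g <- spp$groups[[1]]
  expect_equal(g$variable, "X")
  expect_equal(g$sign, "loss")
  expect_equal(g$symbols, c("sigma_f_x", "sigma_l_x"))
  expect_equal(g$free, "sigma_f_x")
  expect_match(spp$constraints$constraint[1], "sigma_f_x \\+ sigma_l_x = 1")

  spz <- gm_scale_parameters(gm_fixture("z_branching"))
  kinds <- vapply(spz$groups, function(g) paste0(g$variable, ":", g$sign), character(1))
  expect_setequal(kinds, c("Z:gain", "Z:loss"))
  zg <- spz$groups[[which(kinds == "Z:gain")]]
  expect_equal(zg$symbols, c("beta_a_z", "beta_b_z", "beta_c_z"))
})

test_that("branching weights in every group sum to one symbolically", {
  for (fx in c("predator_prey", "z_branching")) {
    j <- gm_jacobian(gm_fixture(fx))
    for (v in j$variables) {
      for (sg in c("gain", "loss")) {
        ws <- j$scale$weights[[v]][[sg]]
        if (length(ws) == 0) next
        total <- Reduce(p_add, ws, genmod:::p_zero())
        expect_true(p_equal(total, p_const(1)),
                    info = sprintf("%s %s:%s", fx, v, sg))
      }
    }
  }
})

test_that("the one-variable gain/loss Jacobian is alpha * (g_x - l_x)", {
  j <- gm_jacobian(gm_fixture("one_d_gain_loss"))
  expected <- p_mul(p_sym("alpha_x"), p_sub(p_sym("g_x"), p_sym("l_x")))
  expect_true(p_equal(j$entries[[1, 1]], expected))
  # eigenvalue equals the single entry: closed form alpha * (g_x - l_x)
  expect_equal(gm_eval_jacobian(j, list(alpha_x = 1, g_x = 0.5, l_x = 2))[1, 1], -1.5)
})

test_that("predator-prey Jacobian matches the printed matrix symbolically", {
  j <- pp_jacobian()
  rho <- p_sym("sigma_f_x"); alpha <- p_sym("alpha_y")
  e11 <- p_sub(p_sub(p_sym("s_x"), p_mul(rho, p_sym("f_x"))),
               p_mul(p_sub(p_const(1), rho), p_sym("l_x")))
  e12 <- genmod:::p_neg(p_mul(rho, p_sym("f_y")))
  e21 <- p_mul(alpha, p_sym("g_x"))
  e22 <- p_mul(alpha, p_sub(p_sym("g_y"), p_sym("m_y")))
  expect_true(p_equal(j$entries[[1, 1]], e11))
  expect_true(p_equal(j$entries[[1, 2]], e12))
  expect_true(p_equal(j$entries[[2, 1]], e21))
  expect_true(p_equal(j$entries[[2, 2]], e22))
})

test_that("timescale normalization sets the reference turnover to one and is idempotent", {
  j <- gm_jacobian(gm_fixture("predator_prey"))
  jn <- gm_normalize_timescale(j, "X")
  expect_true(p_equal(jn$turnover_poly[["X"]], p_const(1)))
  expect_false("alpha_x" %in% gm_free_parameters(jn)$symbol)
  expect_identical(as.character(gm_normalize_timescale(jn, "X")), as.character(jn))
  expect_error(gm_normalize_timescale(jn, "Y"), "different reference")
  expect_error(gm_normalize_timescale(j, "W"), "unknown reference")
  # single-variable model: the only turnover becomes 1
  j1 <- gm_normalize_timescale(gm_jacobian(gm_fixture("one_d_gain_loss")), "X")
  expect_equal(genmod:::p_to_string(j1$entries[[1, 1]]), "g_x - l_x")
})

test_that("structural zeros: entry (i,j) is zero iff no contributing process depends on j", {
  j3 <- gm_jacobian(gm_food_chain(3))
  m <- as.character(j3)
  expect_equal(m[1, 3], "0")
  expect_equal(m[3, 1], "0")
  expect_true(all(m[cbind(c(1, 2, 3, 1, 2), c(1, 2, 3, 2, 3))] != "0"))
  # constraints never create entries without a dependency path
  jc <- gm_apply_constraints(j3)
  mc <- as.character(jc)
  expect_equal(mc[1, 3], "0")
  expect_equal(mc[3, 1], "0")
})

test_that("simple composition G = H(F): chain rule with h_f", {
  m <- gm_fixture("predator_prey") |>
    gm_add_constraint("function_composition", process = "G", outer = "H",
                      arguments = "F")
  j <- gm_apply_constraints(gm_normalize_timescale(gm_jacobian(m), "X"))
  hf <- p_sym("h_f"); alpha <- p_sym("alpha_y")
  expect_true(p_equal(j$entries[[2, 1]], p_mul(alpha, p_mul(hf, p_sym("f_x")))))
  expect_true(p_equal(j$entries[[2, 2]],
                      p_mul(alpha, p_sub(p_mul(hf, p_sym("f_y")), p_sym("m_y")))))
  # forcing H linear (h_f = 1) collapses g to f: identity composition
  m1 <- gm_fixture("predator_prey") |>
    gm_add_constraint("function_composition", process = "G", outer = "H",
                      arguments = "F", fixed = list(h_f = 1))
  j1 <- gm_apply_constraints(gm_normalize_timescale(gm_jacobian(m1), "X"))
  expect_true(p_equal(j1$entries[[2, 1]], p_mul(alpha, p_sym("f_x"))))
})

test_that("per-capita consumption constraint yields (1+h_c) f_x and f_y + h_c (f_y - 1)", {
  j <- pp_jacobian(conversion = TRUE)
  alpha <- p_sym("alpha_y"); hc <- p_sym("h_c")
  gx <- p_mul(p_add(p_const(1), hc), p_sym("f_x"))
  gy <- p_add(p_sym("f_y"), p_mul(hc, p_sub(p_sym("f_y"), p_const(1))))
  expect_true(p_equal(j$entries[[2, 1]], p_mul(alpha, gx)))
  expect_true(p_equal(j$entries[[2, 2]], p_mul(alpha, p_sub(gy, p_sym("m_y")))))
  # the redundant g_x, g_y symbols are gone; h_c takes their place
  syms <- gm_free_parameters(j)$symbol
  expect_false(any(c("g_x", "g_y") %in% syms))
  expect_true("h_c" %in% syms)
})

test_that("explicit inner elasticities come out exactly by log-differentiation", {
  cn <- list(expression = "F / Y", arguments = c("F", "Y"))
  e <- genmod:::inner_elasticities(cn)
  expect_equal(unname(e), c(1, -1))
  # power-law inner form a * X^p gives exactly p, independent of a
  cn2 <- list(expression = "3.7 * X^2.5", arguments = "X")
  expect_equal(unname(genmod:::inner_elasticities(cn2)), 2.5)
  # a non-log-differentiable (star-dependent) form is rejected
  cn3 <- list(expression = "F + Y", arguments = c("F", "Y"))
  expect_error(genmod:::inner_elasticities(cn3), "steady-state values")
})

test_that("derivative conditions pin the targeted elasticity to zero", {
  m <- gm_fixture("one_d_gain_loss") |>
    gm_add_constraint("derivative_condition", process = "G", variable = "X")
  j <- gm_apply_constraints(gm_jacobian(m))
  expected <- genmod:::p_neg(p_mul(p_sym("alpha_x"), p_sym("l_x")))
  expect_true(p_equal(j$entries[[1, 1]], expected))
})

test_that("composition cycles are rejected", {
  m <- gm_fixture("predator_prey") |>
    gm_add_constraint("function_composition", process = "G", outer = "H",
                      arguments = "F") |>
    gm_add_constraint("function_composition", process = "F", outer = "K",
                      arguments = "G")
  expect_error(gm_apply_constraints(gm_jacobian(m)), "cycle")
})

test_that("conservation laws emit flux-matching scale constraints, full-size Jacobian", {
  m <- gm_model("closed_pair") |>
    gm_add_variable("A") |> gm_add_variable("B") |>
    gm_add_process("T1", loss = "A", gain = "B", dependencies = "A") |>
    gm_add_process("T2", loss = "B", gain = "A", dependencies = "B") |>
    gm_add_constraint("conservation_law", coefficients = c(A = 1, B = 1))
  sp <- gm_scale_parameters(m)
  fm <- sp$constraints[sp$constraints$kind == "flux_matching", ]
  expect_equal(nrow(fm), 2)
  expect_true(any(grepl("q_a_b", fm$constraint)))
  # Jacobian keeps full size
  expect_equal(gm_jacobian(m)$n, 2)
})

test_that("elasticity of any power law is its exponent, at any positive point", {
  set.seed(3)
  for (rep in 1:10) {
    a <- stats::runif(1, 0.1, 5)
    p <- stats::runif(1, -2, 3)
    at <- stats::runif(1, 0.2, 4)
    f <- function(x) a * x^p
    expect_equal(gm_elasticity(f, at), p, tolerance = 1e-7)
    # the symbolic route recovers the printed exponent exactly
    expect_equal(gm_elasticity_expr(sprintf("%.10f * X^%.10f", a, p), "X", at),
                 round(p, 10), tolerance = 1e-13)
  }
  # linear, quadratic, square-root, reciprocal
  expect_equal(gm_elasticity(function(x) 3 * x, 2), 1, tolerance = 1e-8)
  expect_equal(gm_elasticity(function(x) 0.7 * x^2, 1.5), 2, tolerance = 1e-8)
  expect_equal(gm_elasticity(function(x) sqrt(x), 0.8), 0.5, tolerance = 1e-8)
  expect_equal(gm_elasticity(function(x) 2 / x, 1.3), -1, tolerance = 1e-8)
})

test_that("JSON export carries entries and the parameter table", {
  j <- pp_jacobian()
  path <- withr::local_tempfile(fileext = ".json")
  gm_jacobian_json(j, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$variables, c("X", "Y"))
  expect_equal(dim(obj$entries), c(2, 2))
  expect_true("sigma_f_x" %in% obj$parameters$symbol)
})
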