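#' Worked generalized models
#'
#' A small catalog of fully declared models used throughout the package's
#' examples and tests:
#'
#' * `one_d_gain_loss`: one variable `X` with a single gain `G` and a single
#'   loss `L`, both depending on `X`. Jacobian `[alpha_x * (g_x - l_x)]`; the
#'   steady state is stable iff `g_x < l_x`.
#' * `predator_prey`: prey `X` with reproduction `S`, predation loss `F(X,Y)`
#'   and other mortality `L`; predator `Y` with predation gain `G(X,Y)` and
#'   mortality `M`. The prey loss branching weight `sigma_f_x` is the share
#'   of prey loss due to predation.
#' * `predator_prey_conversion`: as above, plus the biomass-conversion
#'   constraints: per-capita consumption `C = F/Y` (explicit), and
#'   `G = H(F, C)` with the elasticity of gain w.r.t. total consumption
#'   pinned to 1 (`h_f = 1`), leaving the conversion-efficiency elasticity
#'   `h_c` free. After [gm_apply_constraints()] the predator-gain
#'   elasticities become `(1 + h_c) * f_x` and `f_y + h_c * (f_y - 1)`.
#' * `z_branching`: a three-variable model whose third equation has three
#'   gains (`A(X)`, `B(Y)`, `C(Z)`) and three losses (`Q(Z)`, `R(Z,Y)`,
#'   `S(Z,Y,X)`), exercising multi-way branching groups
#'   (`beta_a_z + beta_b_z + beta_c_z = 1`, `sigma_q_z + sigma_r_z +
#'   sigma_s_z = 1`).
#'
#' @param name One of `"one_d_gain_loss"`, `"predator_prey"`,
#'   `"predator_prey_conversion"`, `"z_branching"`.
#' @return A validated `gm_model`.
#' @examples
#' gm_jacobian(gm_fixture("one_d_gain_loss"))
#' @export
gm_fixture <- function(name) {
  switch(
    name,
    one_d_gain_loss = gm_model("one_d_gain_loss") |>
      gm_add_variable("X", "a positive stock subject to gain and loss") |>
      gm_add_process("G", gain = "X", dependencies = "X") |>
      gm_add_process("L", loss = "X", dependencies = "X"),
    predator_prey = predator_prey_model(),
    predator_prey_conversion = predator_prey_model("predator_prey_conversion") |>
      gm_add_constraint("explicit_inner", name = "C", expression = "F / Y",
                        arguments = c("F", "Y")) |>
      gm_add_constraint("function_composition", process = "G", outer = "H",
                        arguments = c("F", "C"), fixed = list(h_f = 1)),
    z_branching = gm_model("z_branching") |>
      gm_add_variable("X") |> gm_add_variable("Y") |> gm_add_variable("Z") |>
      gm_add_process("U", gain = "X", dependencies = "X") |>
      gm_add_process("V", loss = "X", dependencies = "X") |>
      gm_add_process("W", gain = "Y", dependencies = "Y") |>
      gm_add_process("N", loss = "Y", dependencies = "Y") |>
      gm_add_process("A", gain = "Z", dependencies = "X") |>
      gm_add_process("B", gain = "Z", dependencies = "Y") |>
      gm_add_process("C", gain = "Z", dependencies = "Z") |>
      gm_add_process("Q", loss = "Z", dependencies = "Z") |>
      gm_add_process("R", loss = "Z", dependencies = c("Z", "Y")) |>
      gm_add_process("S", loss = "Z", dependencies = c("Z", "Y", "X")),
    stop(sprintf("unknown fixture '%s'; available: %s", name,
                 "one_d_gain_loss, predator_prey, predator_prey_conversion, z_branching"),
         call. = FALSE)
  )
}

predator_prey_model <- function(name = "predator_prey") {
  gm_model(name) |>
    gm_add_variable("X", "prey") |>
    gm_add_variable("Y", "predator") |>
    gm_add_process("S", gain = "X", dependencies = "X") |>
    gm_add_process("F", loss = "X", dependencies = c("X", "Y")) |>
    gm_add_process("L", loss = "X", dependencies = "X") |>
    gm_add_process("G", gain = "Y", dependencies = c("X", "Y")) |>
    gm_add_process("M", loss = "Y", dependencies = "Y")
}

#' Generate a food chain of n trophic levels
#'
#' Level 1 has a primary-production gain; level k feeds on level k-1
#' (predation loss `F<k>` of the lower level, matching gain `G<k>` of the
#' upper, linked by a linear conversion constraint `G<k> = H<k>(F<k>)` with
#' outer elasticity pinned to 1); every level has an additional mortality
#' loss. The top level lacks a predation loss. The resulting Jacobian is
#' tridiagonal.
#'
#' @param n Chain length (number of trophic levels), `n >= 1`.
#' @return A validated `gm_model` with `n` variables and `3n - 1` processes.
#' @examples
#' gm_food_chain(3)
#' @export
gm_food_chain <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("chain length n must be an integer >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  vars <- paste0("X", seq_len(n))
  m <- gm_model(sprintf("food_chain_%d", n))
  for (v in vars) m <- gm_add_variable(m, v)
  m <- gm_add_process(m, "S", gain = "X1", dependencies = "X1")
  for (k in seq_len(n)) {
    m <- gm_add_process(m, paste0("M", k), loss = vars[k], dependencies = vars[k])
  }
  for (k in seq_len(n)[-1]) {
    fk <- paste0("F", k); gk <- paste0("G", k)
    deps <- c(vars[k - 1], vars[k])
    m <- gm_add_process(m, fk, loss = vars[k - 1], dependencies = deps)
    m <- gm_add_process(m, gk, gain = vars[k], dependencies = deps)
    m <- gm_add_constraint(m, "function_composition", process = gk,
                           outer = paste0("H", k), arguments = fk,
                           fixed = stats::setNames(list(1), fk))
  }
  m
}
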