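# Shared test helpers: admissible parameter draws and the finite-difference
# master oracle (symbolic Jacobian vs. Jacobian of a power-law realization).

`%||%` <- function(a, b) if (is.null(a)) b else a

param_columns <- function(ens) {
  setdiff(names(ens), c("lambda_re", "lambda_im", "stable"))
}

# admissible random parameter sets for a Jacobian (uniform scalars, simplex
# branching), as a tibble of draws
draw_admissible <- function(jac, n, seed) {
  ens <- gm_sample_ensemble(jac, M = n, seed = seed)
  ens[param_columns(ens)]
}

# worst scaled elementwise deviation between the symbolic Jacobian and the
# central finite-difference Jacobian of the power-law realization, over n
# random admissible parameter sets
master_oracle_worst_dev <- function(jac, n_sets, seed) {
  draws <- draw_admissible(jac, n_sets, seed)
  ones <- stats::setNames(rep(1, length(jac$variables)), jac$variables)
  worst <- 0
  for (m in seq_len(n_sets)) {
    params <- as.list(draws[m, ])
    J_sym <- gm_eval_jacobian(jac, params)
    realized <- gm_realize(jac, params)
    J_fd <- gm_fd_jacobian(realized$rhs, ones)
    dev <- max(abs(J_sym - J_fd) / pmax(1, abs(J_sym)))
    worst <- max(worst, dev)
  }
  worst
}

stable_pp_params <- function() {
  # a comfortably stable predator-prey parameter set (trace < 0, det > 0)
  list(alpha_y = 1, sigma_f_x = 0.5, s_x = 0.5, f_x = 1.5, f_y = 1,
       l_x = 1, g_x = 1, g_y = 0.5, m_y = 1)
}

pp_jacobian <- function(conversion = FALSE) {
  m <- gm_fixture(if (conversion) "predator_prey_conversion" else "predator_prey")
  j <- gm_normalize_timescale(gm_jacobian(m), "X")
  if (conversion) j <- gm_apply_constraints(j)
  j
}
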