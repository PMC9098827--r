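# Normalization of a generalized model into its generalized Jacobian.
#
# Every process P contributing to variable V enters V's normalized equation
# as  sign * alpha_V * w_{P,V} * p(x),  where alpha_V is V's turnover (total
# per-unit gain = loss rate at the steady state), w_{P,V} a branching weight
# (share of V's gain or loss carried by P; weights in a group sum to one),
# and p the normalized process with p(1) = 1. Differentiating at the all-ones
# point gives Jacobian entries  alpha_V * sum_P sign * w_{P,V} * theta_{P,j},
# with theta_{P,j} the elasticity (logarithmic derivative) of P w.r.t.
# variable j, a free parameter exactly for declared dependencies.

sym_turnover <- function(v) paste0("alpha_", tolower(v))
sym_weight <- function(p, v, sign) {
  paste0(if (sign == "gain") "beta_" else "sigma_", tolower(p), "_", tolower(v))
}
sym_elasticity <- function(p, v) paste0(tolower(p), "_", tolower(v))

# groups: for each variable and sign, the processes contributing (declaration
# order). Weight polynomials: k = 1 -> constant 1; k > 1 -> free symbols for
# the first k-1 processes and (1 - sum) for the last.
scale_skeleton <- function(model) {
  turnover <- stats::setNames(vapply(model$variables, sym_turnover, character(1)),
                              model$variables)
  weights <- list()
  groups <- list()
  for (v in model$variables) {
    weights[[v]] <- list(gain = list(), loss = list())
    for (sg in c("gain", "loss")) {
      procs <- vapply(Filter(function(p) v %in% p[[sg]], model$processes),
                      `[[`, character(1), "name")
      if (length(procs) == 0L) next
      if (length(procs) == 1L) {
        weights[[v]][[sg]][[procs]] <- p_const(1)
      } else {
        syms <- unname(vapply(procs, function(p) sym_weight(p, v, sg), character(1)))
        for (i in seq_along(procs)[-length(procs)]) {
          weights[[v]][[sg]][[procs[i]]] <- p_sym(syms[i])
        }
        last <- p_const(1)
        for (i in seq_along(procs)[-length(procs)]) last <- p_sub(last, p_sym(syms[i]))
        weights[[v]][[sg]][[procs[length(procs)]]] <- last
        groups[[length(groups) + 1L]] <- list(
          variable = v, sign = sg, processes = procs,
          symbols = syms, free = syms[-length(syms)]
        )
      }
    }
  }
  list(turnover = turnover, weights = weights, groups = groups)
}

#' Derive the scale-parameter skeleton of a model
#'
#' Introduces one turnover symbol `alpha_<v>` per variable (shared between the
#' gain and the loss side, so stationarity gains = losses is built in and
#' non-existent steady states are unrepresentable) and, for every gain/loss
#' group with more than one process, branching-weight symbols with a
#' sum-to-one constraint (`beta_*` for gains, `sigma_*` for losses; the
#' last-declared process's weight is eliminated as one minus the others).
#' Conservation laws add flux-matching constraints between the scale
#' parameters of shared processes, using abundance-ratio symbols
#' `q_<v1>_<v2>` for the unknown steady-state abundance ratios.
#'
#' @param model A validated `gm_model`.
#' @return A list with elements `turnover` (named symbols), `groups`
#'   (branching groups), and `constraints` (tibble of symbolic constraint
#'   equations, each understood as `expression = 0` or `= 1` as printed).
#' @export
gm_scale_parameters <- function(model) {
  assert_valid(model)
  sk <- scale_skeleton(model)
  rows <- list()
  for (g in sk$groups) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      kind = "branching_sum",
      constraint = paste(paste(g$symbols, collapse = " + "), "= 1"),
      variable = g$variable
    )
  }
  for (cn in model$constraints) {
    if (cn$kind != "conservation_law") next
    support <- names(cn$coefficients)
    for (p in model$processes) {
      touched <- intersect(union(p$gain, p$loss), support)
      if (length(touched) < 2L) next
      # shared flux: alpha_v * w_{P,v} * V* equal across touched equations
      ref <- touched[1]
      for (v2 in touched[-1]) {
        wref <- sk$weights[[ref]][[if (ref %in% p$gain) "gain" else "loss"]][[p$name]]
        w2 <- sk$weights[[v2]][[if (v2 %in% p$gain) "gain" else "loss"]][[p$name]]
        ratio <- paste0("q_", tolower(ref), "_", tolower(v2))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          kind = "flux_matching",
          constraint = sprintf("%s*(%s)*%s - %s*(%s) = 0",
                               sk$turnover[[ref]], p_to_string(wref), ratio,
                               sk$turnover[[v2]], p_to_string(w2)),
          variable = p$name
        )
      }
    }
  }
  constraints <- if (length(rows) > 0L) dplyr::bind_rows(rows) else
    tibble::tibble(kind = character(0), constraint = character(0), variable = character(0))
  list(turnover = sk$turnover, groups = sk$groups, constraints = constraints)
}

initial_elasticity_map <- function(model) {
  map <- list()
  for (p in model$processes) {
    map[[p$name]] <- list()
    for (v in p$dependencies) {
      map[[p$name]][[v]] <- p_sym(sym_elasticity(p$name, v))
    }
  }
  map
}

elas_poly <- function(map, proc, v) map[[proc]][[v]] %||% p_zero()

build_entries <- function(vars, model, sk, map, turnover_poly) {
  n <- length(vars)
  entries <- vector("list", n * n)
  dim(entries) <- c(n, n)
  for (i in seq_len(n)) {
    vi <- vars[i]
    for (j in seq_len(n)) {
      vj <- vars[j]
      acc <- p_zero()
      for (p in model$processes) {
        sg <- if (vi %in% p$gain) "gain" else if (vi %in% p$loss) "loss" else next
        th <- elas_poly(map, p$name, vj)
        if (p_is_zero(th)) next
        term <- p_mul(sk$weights[[vi]][[sg]][[p$name]], th)
        if (sg == "loss") term <- p_neg(term)
        acc <- p_add(acc, term)
      }
      entries[[i, j]] <- p_mul(turnover_poly[[vi]], acc)
    }
  }
  entries
}

new_gm_jacobian <- function(model, sk, map, turnover_poly, timescale_ref,
                            constraints_applied, fixed_outer = list()) {
  vars <- model$variables
  entries <- build_entries(vars, model, sk, map, turnover_poly)
  structure(
    list(model = model, variables = vars, n = length(vars), entries = entries,
         scale = sk, elasticity_map = map, turnover_poly = turnover_poly,
         timescale_ref = timescale_ref, constraints_applied = constraints_applied,
         fixed_outer = fixed_outer),
    class = "gm_jacobian"
  )
}

#' Build the generalized Jacobian of a model
#'
#' Emits the N x N symbolic Jacobian at the normalized steady state (the
#' all-ones point): entry (i, j) is
#' `alpha_i * sum over processes P of sign(P,i) * weight(P,i) * theta_{P,j}`,
#' with branching eliminations (last weight = 1 - sum of the others) already
#' substituted. Entry (i, j) is identically zero when no process contributing
#' to variable i depends on variable j. Declared constraints are *not* yet
#' applied; see [gm_apply_constraints()].
#'
#' @param model A validated `gm_model`.
#' @return A `gm_jacobian` object.
#' @examples
#' j <- gm_jacobian(gm_fixture("predator_prey"))
#' print(j)
#' @export
gm_jacobian <- function(model) {
  assert_valid(model)
  sk <- scale_skeleton(model)
  map <- initial_elasticity_map(model)
  turnover_poly <- lapply(stats::setNames(model$variables, model$variables),
                          function(v) p_sym(sym_turnover(v)))
  check_symbol_collisions(model, sk, map)
  new_gm_jacobian(model, sk, map, turnover_poly, timescale_ref = NULL,
                  constraints_applied = FALSE)
}

check_symbol_collisions <- function(model, sk, map) {
  syms <- c(vapply(model$variables, sym_turnover, character(1)),
            unlist(lapply(sk$groups, `[[`, "symbols")),
            unlist(lapply(model$processes, function(p)
              vapply(p$dependencies, function(v) sym_elasticity(p$name, v), character(1)))))
  if (anyDuplicated(syms)) {
    stop("generated parameter symbols collide: ",
         paste(unique(syms[duplicated(syms)]), collapse = ", "),
         "; rename variables/processes", call. = FALSE)
  }
}

#' Normalize the timescale of a generalized Jacobian
#'
#' Rescales time by the turnover of a reference variable: its turnover symbol
#' becomes 1 and every other variable's turnover is reinterpreted as the
#' ratio of its turnover to the reference's (e.g. the predator-to-prey
#' turnover ratio). Idempotent for a fixed reference.
#'
#' @param jac A `gm_jacobian`.
#' @param reference Name of the reference variable.
#' @return The rescaled `gm_jacobian`.
#' @export
gm_normalize_timescale <- function(jac, reference) {
  stopifnot(inherits(jac, "gm_jacobian"))
  if (!reference %in% jac$variables) {
    stop(sprintf("unknown reference variable '%s'", reference), call. = FALSE)
  }
  if (!is.null(jac$timescale_ref)) {
    if (identical(jac$timescale_ref, reference)) return(jac)
    stop("timescale already normalized to a different reference", call. = FALSE)
  }
  tp <- jac$turnover_poly
  tp[[reference]] <- p_const(1)
  new_gm_jacobian(jac$model, jac$scale, jac$elasticity_map, tp,
                  timescale_ref = reference,
                  constraints_applied = jac$constraints_applied,
                  fixed_outer = jac$fixed_outer)
}

# ---- constraint application ------------------------------------------------

# Exact elasticities of an explicit closed-form auxiliary w.r.t. its declared
# arguments, by symbolic log-differentiation: e_u = u * dA/du / A. The result
# must not depend on the (unknown) steady-state values of the arguments;
# star-independence is checked by evaluating at the all-ones point and at
# random positive points.
inner_elasticities <- function(cn) {
  expr <- tryCatch(str2lang(cn$expression),
                   error = function(e) stop("cannot parse inner expression: ",
                                            cn$expression, call. = FALSE))
  args <- cn$arguments
  out <- stats::setNames(numeric(length(args)), args)
  probes <- list(stats::setNames(rep(1, length(args)), args),
                 stats::setNames(exp(c(seq_along(args)) / 7), args),
                 stats::setNames(exp(-c(seq_along(args)) / 5), args))
  for (u in args) {
    de <- stats::D(expr, u)
    vals <- vapply(probes, function(pt) {
      env <- as.list(pt)
      eval(de, env) * pt[[u]] / eval(expr, env)
    }, numeric(1))
    if (any(!is.finite(vals))) {
      stop(sprintf("inner form '%s' is not log-differentiable at the normalized point",
                   cn$expression), call. = FALSE)
    }
    if (max(vals) - min(vals) > 1e-8) {
      stop(sprintf(paste0("inner form '%s': elasticity w.r.t. '%s' depends on unknown ",
                          "steady-state values; declare it as a composition instead"),
                   cn$expression, u), call. = FALSE)
    }
    out[[u]] <- vals[1]
  }
  out
}

# Total elasticity (as a polynomial) of an entity w.r.t. model variable v.
# Entities are model variables (delta), processes (current map), or explicit
# auxiliaries (chain rule through their arguments).
entity_elasticity <- function(entity, v, map, model, aux, visiting = character(0)) {
  if (entity %in% visiting) {
    stop("cycle among constraints involving '", entity, "'", call. = FALSE)
  }
  if (entity %in% model$variables) {
    return(if (identical(entity, v)) p_const(1) else p_zero())
  }
  if (!is.null(map[[entity]])) {
    return(elas_poly(map, entity, v))
  }
  if (!is.null(aux[[entity]])) {
    cn <- aux[[entity]]
    acc <- p_zero()
    for (u in names(cn$inner)) {
      inner_e <- entity_elasticity(u, v, map, model, aux, c(visiting, entity))
      acc <- p_add(acc, p_mul(p_const(cn$inner[[u]]), inner_e))
    }
    return(acc)
  }
  stop(sprintf("unknown entity '%s' in constraint", entity), call. = FALSE)
}

#' Apply declared constraints to a generalized Jacobian
#'
#' Resolution order: explicit closed-form auxiliaries first (their
#' elasticities are exact constants by symbolic log-differentiation), then
#' function compositions innermost to outermost (chain rule; each outer
#' elasticity becomes a new free parameter unless pinned via `fixed`), then
#' derivative conditions (the targeted elasticity is set to zero).
#' Conservation laws do not alter the Jacobian entries (the Jacobian keeps
#' full size); their scale-parameter constraints are reported by
#' [gm_scale_parameters()]. Constraint substitution never creates a nonzero
#' entry where no dependency path exists.
#'
#' @param jac A `gm_jacobian`.
#' @return A `gm_jacobian` with substituted elasticity map and entries.
#' @examples
#' j <- gm_jacobian(gm_fixture("predator_prey_conversion"))
#' gm_apply_constraints(j)
#' @export
gm_apply_constraints <- function(jac) {
  stopifnot(inherits(jac, "gm_jacobian"))
  model <- jac$model
  map <- jac$elasticity_map
  fixed_outer <- jac$fixed_outer

  aux <- list()
  for (cn in model$constraints) {
    if (cn$kind == "explicit_inner") {
      cn$inner <- inner_elasticities(cn)
      aux[[cn$name]] <- cn
    }
  }

  comps <- Filter(function(cn) cn$kind == "function_composition", model$constraints)
  remaining <- comps
  guard <- 0L
  while (length(remaining) > 0L) {
    guard <- guard + 1L
    if (guard > length(comps) + 1L) {
      stop("cycle among function-composition constraints", call. = FALSE)
    }
    pending_targets <- vapply(remaining, `[[`, character(1), "process")
    progressed <- FALSE
    keep <- list()
    for (cn in remaining) {
      # apply only when no argument is itself the target of a pending composition
      if (any(cn$arguments %in% setdiff(pending_targets, cn$process))) {
        keep[[length(keep) + 1L]] <- cn
        next
      }
      newmap <- list()
      for (v in model$variables) {
        acc <- p_zero()
        for (u in cn$arguments) {
          h <- cn$fixed[[paste0(tolower(cn$outer), "_", tolower(u))]] %||%
            cn$fixed[[u]]
          hpoly <- if (!is.null(h)) p_const(h) else
            p_sym(paste0(tolower(cn$outer), "_", tolower(u)))
          if (!is.null(h)) {
            fixed_outer[[paste0(tolower(cn$outer), "_", tolower(u))]] <- h
          }
          acc <- p_add(acc, p_mul(hpoly, entity_elasticity(u, v, map, model, aux)))
        }
        if (!p_is_zero(acc)) newmap[[v]] <- acc
      }
      map[[cn$process]] <- newmap
      progressed <- TRUE
    }
    if (!progressed) stop("cycle among function-composition constraints", call. = FALSE)
    remaining <- keep
  }

  for (cn in model$constraints) {
    if (cn$kind == "derivative_condition") {
      map[[cn$process]][[cn$variable]] <- p_const(0)
    }
  }

  new_gm_jacobian(model, jac$scale, map, jac$turnover_poly,
                  timescale_ref = jac$timescale_ref,
                  constraints_applied = TRUE, fixed_outer = fixed_outer)
}

# ---- parameter accounting and numeric evaluation ---------------------------

#' Free parameters of a generalized Jacobian
#'
#' Lists every free symbol: turnover rates (role `turnover`), free branching
#' weights (role `branching`, with their simplex group id; the eliminated
#' weight of each group is one minus the listed ones), and elasticities
#' including outer elasticities introduced by compositions (role
#' `elasticity`). Default sampling ranges follow field practice: turnovers in
#' \[0.5, 2\], elasticities in \[0, 2\] (constant through quadratic response),
#' branching weights on the unit simplex.
#'
#' @param jac A `gm_jacobian`.
#' @return A tibble with columns `symbol`, `role`, `group`, `lo`, `hi`.
#' @export
gm_free_parameters <- function(jac) {
  stopifnot(inherits(jac, "gm_jacobian"))
  syms <- sort(unique(unlist(lapply(jac$entries, p_free_symbols))))
  branch_syms <- unlist(lapply(jac$scale$groups, `[[`, "free"))
  group_of <- stats::setNames(
    rep(vapply(jac$scale$groups, function(g) paste0(g$variable, ":", g$sign), character(1)),
        vapply(jac$scale$groups, function(g) length(g$free), integer(1))),
    branch_syms)
  turn_syms <- vapply(jac$variables, sym_turnover, character(1))
  role <- ifelse(syms %in% branch_syms, "branching",
                 ifelse(syms %in% turn_syms, "turnover", "elasticity"))
  tibble::tibble(
    symbol = syms,
    role = role,
    group = dplyr::if_else(role == "branching", unname(group_of[syms]), NA_character_),
    lo = dplyr::case_when(role == "turnover" ~ 0.5, role == "branching" ~ 0, TRUE ~ 0),
    hi = dplyr::case_when(role == "turnover" ~ 2, role == "branching" ~ 1, TRUE ~ 2)
  )
}

#' Evaluate a generalized Jacobian numerically
#'
#' @param jac A `gm_jacobian`.
#' @param params Named list or vector covering every free symbol of `jac`.
#' @return A numeric `n x n` matrix.
#' @export
gm_eval_jacobian <- function(jac, params) {
  stopifnot(inherits(jac, "gm_jacobian"))
  params <- as.list(params)
  need <- setdiff(sort(unique(unlist(lapply(jac$entries, p_free_symbols)))), names(params))
  if (length(need) > 0L) {
    stop("missing parameter value(s): ", paste(need, collapse = ", "), call. = FALSE)
  }
  out <- matrix(0, jac$n, jac$n, dimnames = list(jac$variables, jac$variables))
  for (i in seq_len(jac$n)) for (j in seq_len(jac$n)) {
    out[i, j] <- p_eval(jac$entries[[i, j]], params)
  }
  out
}

# Compiled vectorized evaluator: returns function(df) -> array [n, n, M],
# where df has one column per free symbol, M rows.
gm_jacobian_evaluator <- function(jac) {
  n <- jac$n
  exprs <- lapply(jac$entries, function(p) str2lang(p_to_string(p)))
  function(df) {
    M <- nrow(df)
    env <- as.list(df)
    arr <- array(0, dim = c(n, n, M))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      val <- eval(exprs[[i + (j - 1L) * n]], env)
      arr[i, j, ] <- val # scalars recycle over M
    }
    arr
  }
}

# Numeric resolution of the full generalized parameter set (turnovers,
# all branching weights incl. eliminated ones, per-process elasticities)
# from values of the free symbols. Used by the realization builder.
gm_resolve_parameters <- function(jac, params) {
  params <- as.list(params)
  vars <- jac$variables
  turnover <- vapply(vars, function(v) p_eval(jac$turnover_poly[[v]], params), numeric(1))
  names(turnover) <- vars
  weights <- list()
  for (v in vars) {
    weights[[v]] <- list()
    for (sg in c("gain", "loss")) {
      for (pn in names(jac$scale$weights[[v]][[sg]])) {
        weights[[v]][[sg]][[pn]] <- p_eval(jac$scale$weights[[v]][[sg]][[pn]], params)
      }
    }
  }
  elas <- list()
  for (pn in names(jac$elasticity_map)) {
    e <- vapply(vars, function(v) p_eval(elas_poly(jac$elasticity_map, pn, v), params),
                numeric(1))
    names(e) <- vars
    elas[[pn]] <- e[e != 0 | vars %in% (jac$model$processes[[match(pn, proc_names(jac$model))]]$dependencies)]
  }
  list(turnover = turnover, weights = weights, elasticities = elas)
}

# ---- export and printing ---------------------------------------------------

#' Character matrix of Jacobian entries
#' @param x A `gm_jacobian`.
#' @param ... Unused.
#' @return Character matrix of plain-text entry expressions.
#' @export
as.character.gm_jacobian <- function(x, ...) {
  out <- matrix(vapply(x$entries, p_to_string, character(1)), x$n, x$n,
                dimnames = list(x$variables, x$variables))
  out
}

#' Export a symbolic Jacobian as JSON
#'
#' Writes entry expression strings plus the free-parameter symbol table.
#'
#' @param jac A `gm_jacobian`.
#' @param path Output file path; `NULL` returns the JSON string.
#' @return The path (or JSON string), invisibly.
#' @export
gm_jacobian_json <- function(jac, path = NULL) {
  obj <- list(
    variables = jac$variables,
    entries = as.character(jac),
    parameters = gm_free_parameters(jac),
    timescale_reference = jac$timescale_ref %||% NA,
    constraints_applied = jac$constraints_applied
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @export
print.gm_jacobian <- function(x, ...) {
  cat(sprintf("<generalized Jacobian> %d x %d (%s)\n", x$n, x$n, x$model$name))
  if (!is.null(x$timescale_ref)) {
    cat(sprintf("  timescale normalized to variable '%s'\n", x$timescale_ref))
  }
  m <- as.character(x)
  for (i in seq_len(x$n)) {
    cat(sprintf("  d%s/dt: [ %s ]\n", x$variables[i], paste(m[i, ], collapse = " | ")))
  }
  invisible(x)
}

# ---- elasticity of explicit functions --------------------------------------

#' Elasticity (exponent parameter) of a function at a point
#'
#' The elasticity of a process `f` at an operating point `at` is the
#' logarithmic derivative `d log f / d log x` evaluated there — the exponent
#' parameter produced by the GM normalization. Any power law `a * x^p` has
#' elasticity `p` at every positive point, regardless of `a`: linear
#' processes give 1, quadratic 2, square-root 1/2.
#'
#' @param f A function of one numeric argument, positive near `at`.
#' @param at Positive evaluation point (the steady-state value).
#' @param step Relative central-difference step on the log scale.
#' @return The elasticity (dimensionless scalar).
#' @examples
#' gm_elasticity(function(x) 3 * x, at = 2)      # 1
#' gm_elasticity(function(x) 0.7 * x^2, at = 1.5) # 2
#' @export
gm_elasticity <- function(f, at, step = 1e-6) {
  stopifnot(is.function(f), at > 0)
  up <- f(at * exp(step)); dn <- f(at * exp(-step))
  if (!is.finite(up) || !is.finite(dn) || up <= 0 || dn <= 0) {
    stop("function must be positive and finite near the evaluation point", call. = FALSE)
  }
  (log(up) - log(dn)) / (2 * step)
}

#' Symbolic elasticity of an expression
#'
#' Exact counterpart of [gm_elasticity()]: differentiates the expression
#' symbolically and evaluates `x * f'(x) / f(x)` at the point.
#'
#' @param expr A one-line character expression in `var`.
#' @param var Variable name.
#' @param at Positive evaluation point.
#' @return The elasticity.
#' @examples
#' gm_elasticity_expr("3 * X", "X", at = 2) # exactly 1
#' @export
gm_elasticity_expr <- function(expr, var, at) {
  e <- str2lang(expr)
  de <- stats::D(e, var)
  env <- stats::setNames(list(at), var)
  val <- eval(e, env)
  if (!is.finite(val) || val == 0) {
    stop("expression must be nonzero and finite at the evaluation point", call. = FALSE)
  }
  at * eval(de, env) / val
}
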