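# Construction of explicit conventional ODE models ("realizations") whose
# steady state sits at the normalized all-ones point and reproduces a chosen
# generalized parameter set, plus round-trip verification.

#' Solve a kinetic function template for a target elasticity
#'
#' Fixes the constants of a one-shape-constant template so that its value at
#' the normalized point 1 equals `weight` (the process's share of the
#' turnover) and its elasticity at 1 equals `target`:
#'
#' * `power_law`: `weight * x^target`; always solvable, elasticity is exact.
#' * `saturating`: `weight * (1 + K) * x / (K + x)` (Holling/Michaelis-Menten
#'   form); the elasticity at 1 is `K / (K + 1)`, so `K = target /
#'   (1 - target)`, achievable only for `0 <= target < 1`. `target = 0`
#'   gives `K = 0`, the constant-response limit.
#' * `custom`: supply `maker`, a function of one shape constant returning a
#'   positive function with value 1 at 1; the shape constant is solved by
#'   bracketed root-finding of the elasticity condition on `bracket`.
#'
#' @param family `"power_law"`, `"saturating"`, or `"custom"`.
#' @param target Target elasticity at the normalized point.
#' @param weight Value at 1 (turnover weight), default 1.
#' @param maker For `custom`: function(shape) -> function(x).
#' @param bracket For `custom`: search interval for the shape constant.
#' @return A `gm_template` list: `family`, `target`, `weight`, constants
#'   (`K` where applicable), `fun` (function of one variable), and `expr`
#'   (plain-text form).
#' @examples
#' gm_solve_template("saturating", target = 1/2) # K = 1: 2x/(1+x)
#' @export
gm_solve_template <- function(family = c("power_law", "saturating", "custom"),
                              target, weight = 1,
                              maker = NULL, bracket = c(1e-6, 1e6)) {
  family <- match.arg(family)
  stopifnot(is.numeric(target), length(target) == 1L, is.finite(target), weight > 0)
  if (family == "power_law") {
    fun <- local({ p <- target; w <- weight; function(x) w * x^p })
    expr <- sprintf("%s * x^%s", format(weight), format(target))
    out <- list(family = family, target = target, weight = weight, K = NULL,
                fun = fun, expr = expr)
  } else if (family == "saturating") {
    if (target < 0 || target >= 1) {
      stop("saturating family achieves elasticities in [0, 1): target out of range",
           call. = FALSE)
    }
    K <- target / (1 - target)
    fun <- local({ K0 <- K; w <- weight; function(x) w * (1 + K0) * x / (K0 + x) })
    expr <- sprintf("%s * %s * x / (%s + x)", format(weight), format(1 + K), format(K))
    out <- list(family = family, target = target, weight = weight, K = K,
                fun = fun, expr = expr)
  } else {
    stopifnot(is.function(maker))
    obj <- function(k) gm_elasticity(maker(k), at = 1) - target
    lo <- obj(bracket[1]); hi <- obj(bracket[2])
    if (!is.finite(lo) || !is.finite(hi) || sign(lo) * sign(hi) > 0) {
      stop("target elasticity not bracketed by the custom template on the given interval",
           call. = FALSE)
    }
    K <- stats::uniroot(obj, bracket, tol = 1e-12)$root
    fun <- local({ f0 <- maker(K); w <- weight; function(x) w * f0(x) })
    out <- list(family = family, target = target, weight = weight, K = K,
                fun = fun, expr = sprintf("%s * custom(K = %s)", format(weight), format(K)))
  }
  structure(out, class = "gm_template")
}

# normalized per-process function (value 1 at the all-ones point)
make_process_fun <- function(elas, template = NULL) {
  deps <- names(elas)
  if (!is.null(template)) {
    if (length(deps) != 1L) {
      stop("templates are restricted to single-dependency processes", call. = FALSE)
    }
    tmpl <- gm_solve_template(template, target = unname(elas), weight = 1)
    f <- tmpl$fun
    return(list(fun = function(x) f(x[[deps]]),
                expr = gsub("\\bx\\b", deps, tmpl$expr),
                family = tmpl$family))
  }
  th <- unname(elas)
  list(
    fun = function(x) prod(vapply(seq_along(deps),
                                  function(i) x[[deps[i]]]^th[i], numeric(1))),
    expr = if (length(deps) == 0L) "1" else
      paste(sprintf("%s^%s", deps, vapply(th, format, character(1))), collapse = " * "),
    family = "power_law"
  )
}

#' Realize a conventional model from a generalized parameter set
#'
#' Constructs explicit kinetics per process, by default the power law
#' `prod_v x_v^theta_{P,v}` (which meets the normalization condition — value
#' one at the all-ones point — for any elasticities), and assembles the ODE
#' right-hand sides with the turnover/branching coefficients of the supplied
#' parameter set. The assembled system has a steady state at the all-ones
#' point by construction, and its Jacobian there equals the symbolic
#' generalized Jacobian evaluated at the same parameters.
#'
#' Per-process saturating templates can be requested via `templates`
#' (restricted to single-dependency processes with elasticity in `[0, 1)`).
#' Pure power-law realizations are flagged with a degeneracy caveat: they can
#' make certain bifurcations degenerate, so template mixing is recommended
#' for bifurcation studies.
#'
#' @param jac A `gm_jacobian` (constraints applied if the model has any).
#' @param params Named values for every free symbol of `jac`.
#' @param templates Named list mapping process names to `"saturating"` (or
#'   `"power_law"`, the default for unlisted processes).
#' @return A `gm_realized` object with elements `rhs` (function of a named
#'   state vector), `process_funs`, `terms` (per-equation coefficients),
#'   `ode_text` (plain-text right-hand sides), `requested` (the resolved
#'   generalized parameter set), `degeneracy_caveat`.
#' @examples
#' j <- gm_jacobian(gm_fixture("one_d_gain_loss"))
#' r <- gm_realize(j, list(alpha_x = 1, g_x = 1/2, l_x = 2))
#' r$ode_text
#' @export
gm_realize <- function(jac, params, templates = list()) {
  stopifnot(inherits(jac, "gm_jacobian"))
  params <- as.list(params)
  if (length(jac$model$constraints) > 0L && !jac$constraints_applied) {
    stop("model has constraints; call gm_apply_constraints() before realizing",
         call. = FALSE)
  }
  need <- setdiff(sort(unique(unlist(lapply(jac$entries, p_free_symbols)))), names(params))
  if (length(need) > 0L) {
    stop("missing parameter value(s): ", paste(need, collapse = ", "), call. = FALSE)
  }
  resolved <- gm_resolve_parameters(jac, params)
  vars <- jac$variables
  funs <- list()
  for (pn in names(resolved$elasticities)) {
    elas <- resolved$elasticities[[pn]]
    funs[[pn]] <- make_process_fun(elas, templates[[pn]])
  }
  terms <- list()
  for (v in vars) {
    for (sg in c("gain", "loss")) {
      for (pn in names(resolved$weights[[v]][[sg]])) {
        coef <- resolved$turnover[[v]] * resolved$weights[[v]][[sg]][[pn]]
        terms[[length(terms) + 1L]] <- list(
          variable = v, process = pn, sign = if (sg == "gain") 1 else -1, coef = coef)
      }
    }
  }
  rhs <- function(x) {
    x <- as.list(x)
    out <- stats::setNames(numeric(length(vars)), vars)
    pvals <- lapply(funs, function(f) f$fun(x))
    for (tm in terms) {
      out[[tm$variable]] <- out[[tm$variable]] + tm$sign * tm$coef * pvals[[tm$process]]
    }
    out
  }
  ode_text <- vapply(vars, function(v) {
    pieces <- character(0)
    for (tm in terms) {
      if (tm$variable != v) next
      piece <- sprintf("%s * %s", format(tm$coef), funs[[tm$process]]$expr)
      pieces <- c(pieces, if (tm$sign < 0) paste0("- ", piece) else
        if (length(pieces) == 0L) piece else paste0("+ ", piece))
    }
    sprintf("d%s/dt = %s", v, paste(pieces, collapse = " "))
  }, character(1))
  all_power <- all(vapply(funs, `[[`, character(1), "family") == "power_law")
  structure(
    list(jac = jac, variables = vars, params = params, requested = resolved,
         process_funs = funs, terms = terms, rhs = rhs, ode_text = unname(ode_text),
         degeneracy_caveat = all_power),
    class = "gm_realized"
  )
}

#' @export
print.gm_realized <- function(x, ...) {
  cat("<realized model>\n")
  for (line in x$ode_text) cat(" ", line, "\n")
  if (x$degeneracy_caveat) {
    cat("  note: pure power-law realization; certain bifurcations degenerate\n")
  }
  invisible(x)
}

#' Central finite-difference Jacobian
#'
#' Numerical Jacobian of a vector field at a point, by central differences.
#' Used as the package's independent oracle for the symbolic Jacobian.
#'
#' @param rhs Function mapping a named state vector to a named derivative
#'   vector.
#' @param x Named numeric evaluation point.
#' @param h Absolute step size.
#' @return Numeric Jacobian matrix (rows = equations, cols = variables).
#' @export
gm_fd_jacobian <- function(rhs, x, h = 1e-6) {
  x <- unlist(x)
  n <- length(x)
  J <- matrix(0, n, n, dimnames = list(names(x), names(x)))
  for (j in seq_len(n)) {
    up <- x; up[j] <- up[j] + h
    dn <- x; dn[j] <- dn[j] - h
    J[, j] <- (unlist(rhs(up)) - unlist(rhs(dn))) / (2 * h)
  }
  J
}

#' Verify a realization by round trip
#'
#' Recomputes the generalized parameters from the realized kinetics alone:
#' turnovers as each variable's total gain at the all-ones point, branching
#' weights as each process's share of it, and elasticities as numeric
#' log-derivatives of the process functions at the all-ones point; and
#' checks the steady-state residual there.
#'
#' @param realized A `gm_realized`.
#' @param step Central-difference step for the log-derivatives.
#' @return A tibble with columns `quantity`, `requested`, `recovered`,
#'   `deviation`, carrying the overall `max_deviation` as an attribute.
#' @examples
#' j <- gm_jacobian(gm_fixture("one_d_gain_loss"))
#' r <- gm_realize(j, list(alpha_x = 1, g_x = 1/2, l_x = 2),
#'                 templates = list(G = "saturating"))
#' v <- gm_verify_roundtrip(r)
#' attr(v, "max_deviation")
#' @export
gm_verify_roundtrip <- function(realized, step = 1e-6) {
  stopifnot(inherits(realized, "gm_realized"))
  vars <- realized$variables
  ones <- stats::setNames(rep(1, length(vars)), vars)
  # residual recomputed from the recorded terms and kinetics (not the cached
  # closure), so any tampering with the stored structure is caught
  resid_vec <- stats::setNames(numeric(length(vars)), vars)
  for (tm in realized$terms) {
    resid_vec[[tm$variable]] <- resid_vec[[tm$variable]] +
      tm$sign * tm$coef * realized$process_funs[[tm$process]]$fun(as.list(ones))
  }
  resid <- max(abs(resid_vec))
  if (resid > 1e-8) {
    stop(sprintf("integrity error: steady-state residual %.3g at the all-ones point",
                 resid), call. = FALSE)
  }
  req <- realized$requested
  rows <- list()
  put <- function(q, want, got) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      quantity = q, requested = want, recovered = got, deviation = abs(got - want))
  }
  # turnovers and branching weights from process values at the all-ones point
  for (v in vars) {
    gains <- names(req$weights[[v]][["gain"]])
    total <- sum(vapply(gains, function(pn) {
      tm <- Filter(function(t) t$variable == v && t$process == pn && t$sign > 0,
                   realized$terms)[[1]]
      tm$coef * realized$process_funs[[pn]]$fun(as.list(ones))
    }, numeric(1)))
    put(paste0("turnover.", v), req$turnover[[v]], total)
    for (sg in c("gain", "loss")) {
      for (pn in names(req$weights[[v]][[sg]])) {
        tm <- Filter(function(t) t$variable == v && t$process == pn,
                     realized$terms)[[1]]
        got <- tm$coef * realized$process_funs[[pn]]$fun(as.list(ones)) / total
        put(paste0("weight.", pn, ".", v), req$weights[[v]][[sg]][[pn]], got)
      }
    }
  }
  # elasticities as numeric log-derivatives at the all-ones point
  for (pn in names(req$elasticities)) {
    f <- realized$process_funs[[pn]]$fun
    for (v in names(req$elasticities[[pn]])) {
      up <- as.list(ones); up[[v]] <- exp(step)
      dn <- as.list(ones); dn[[v]] <- exp(-step)
      got <- (log(f(up)) - log(f(dn))) / (2 * step)
      put(paste0("elasticity.", pn, ".", v), req$elasticities[[pn]][[v]], got)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "max_deviation") <- max(out$deviation)
  attr(out, "steady_state_residual") <- resid
  out
}

#' Integrate a realized model
#'
#' Thin wrapper around `deSolve::ode` for smoke-testing realized dynamics.
#'
#' @param realized A `gm_realized`.
#' @param x0 Named initial state (defaults to a small displacement from the
#'   all-ones steady state).
#' @param times Output times.
#' @return A tibble with a `time` column and one column per variable.
#' @export
gm_simulate <- function(realized, x0 = NULL, times = seq(0, 10, by = 0.1)) {
  stopifnot(inherits(realized, "gm_realized"))
  if (!requireNamespace("deSolve", quietly = TRUE)) {
    stop("gm_simulate requires the deSolve package", call. = FALSE)
  }
  vars <- realized$variables
  if (is.null(x0)) x0 <- stats::setNames(rep(1.05, length(vars)), vars)
  f <- function(t, y, parms) list(unlist(realized$rhs(as.list(y))))
  out <- deSolve::ode(y = unlist(x0), times = times, func = f, parms = NULL)
  tibble::as_tibble(as.data.frame(out)) |>
    stats::setNames(c("time", vars))
}
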