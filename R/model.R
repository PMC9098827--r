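#' Declare a generalized model
#'
#' A generalized model (GM) is the structural skeleton of an ODE system:
#' state variables, signed gain/loss processes with declared dependency sets,
#' and optional auxiliary constraints. Kinetic rate laws are deliberately left
#' unspecified; all downstream analysis works on the normalized Jacobian
#' derived from this structure alone. All state variables and process rates
#' are assumed strictly positive, which is what makes the normalization to an
#' all-ones steady state possible.
#'
#' @param name Model name (free text, used in printing and manifests).
#' @return A `gm_model` object.
#' @examples
#' m <- gm_model("predator-prey") |>
#'   gm_add_variable("X") |>
#'   gm_add_variable("Y") |>
#'   gm_add_process("S", gain = "X", dependencies = "X") |>
#'   gm_add_process("F", loss = "X", dependencies = c("X", "Y")) |>
#'   gm_add_process("L", loss = "X", dependencies = "X") |>
#'   gm_add_process("G", gain = "Y", dependencies = c("X", "Y")) |>
#'   gm_add_process("M", loss = "Y", dependencies = "Y")
#' gm_validate(m)
#' @export
gm_model <- function(name = "model") {
  structure(
    list(name = name, variables = character(0), descriptions = character(0),
         processes = list(), constraints = list()),
    class = "gm_model"
  )
}

check_identifier <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || !grepl("^[A-Za-z][A-Za-z0-9_]*$", x)) {
    stop(sprintf("%s must be a single identifier (letters, digits, underscore): got %s",
                 what, deparse(x)), call. = FALSE)
  }
  x
}

#' Add a state variable
#'
#' Variables represent strictly positive quantities (abundances,
#' concentrations, biomasses). Declaration order fixes the row/column order of
#' the Jacobian.
#'
#' @param model A `gm_model`.
#' @param name Variable identifier, unique within the model.
#' @param description Optional free-text description.
#' @return The extended `gm_model`.
#' @export
gm_add_variable <- function(model, name, description = "") {
  stopifnot(inherits(model, "gm_model"))
  check_identifier(name, "variable name")
  if (name %in% model$variables) {
    stop(sprintf("variable '%s' already declared", name), call. = FALSE)
  }
  model$variables <- c(model$variables, name)
  model$descriptions <- c(model$descriptions, description)
  model
}

#' Add a process
#'
#' A process is a single one-way flow. It may contribute to several equations
#' (a shared process, e.g. a transfer that is a loss for one variable and a
#' gain for another), with at most one sign per equation. Processes that could
#' run in both directions must be declared as two antagonistic one-way
#' processes. The dependency set declares which variables the (unspecified)
#' rate law may depend on; an elasticity parameter will exist exactly for the
#' declared (process, variable) pairs, and undeclared pairs are structural
#' zeros of the Jacobian.
#'
#' @param model A `gm_model`.
#' @param name Process identifier, unique within the model.
#' @param gain,loss Character vectors of variable names to whose equations the
#'   process contributes as a gain resp. a loss. At least one contribution is
#'   required; a variable may not appear in both.
#' @param dependencies Character vector of variable names the rate may depend
#'   on.
#' @return The extended `gm_model`.
#' @export
gm_add_process <- function(model, name, gain = character(0), loss = character(0),
                           dependencies = character(0)) {
  stopifnot(inherits(model, "gm_model"))
  check_identifier(name, "process name")
  if (name %in% vapply(model$processes, `[[`, character(1), "name")) {
    stop(sprintf("process '%s' already declared", name), call. = FALSE)
  }
  gain <- as.character(gain); loss <- as.character(loss)
  dependencies <- as.character(dependencies)
  if (length(gain) + length(loss) == 0L) {
    stop("process must contribute to at least one equation", call. = FALSE)
  }
  unknown <- setdiff(c(gain, loss, dependencies), model$variables)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown variable(s): %s", paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(gain) || anyDuplicated(loss)) {
    stop("duplicate contribution to the same equation", call. = FALSE)
  }
  both <- intersect(gain, loss)
  if (length(both) > 0L) {
    stop(sprintf("process '%s' contributes with both signs to: %s",
                 name, paste(both, collapse = ", ")), call. = FALSE)
  }
  model$processes[[length(model$processes) + 1L]] <-
    list(name = name, gain = gain, loss = loss, dependencies = dependencies)
  model
}

proc_names <- function(model) vapply(model$processes, `[[`, character(1), "name")

get_process <- function(model, name) {
  i <- match(name, proc_names(model))
  if (is.na(i)) stop(sprintf("unknown process '%s'", name), call. = FALSE)
  model$processes[[i]]
}

#' Attach an auxiliary constraint
#'
#' Four constraint kinds are supported, mirroring the ways structural
#' knowledge narrows the generalized parameter space:
#'
#' * `function_composition`: an outer process is an unspecified function of
#'   other processes / auxiliary quantities, e.g. predator gain
#'   `G = H(F)` or `G = H(F, C)`. Chain-rule substitution replaces the outer
#'   process's elasticities by products of new outer elasticities (named
#'   `<outer>_<argument>`, e.g. `h_f`, `h_c`) and the arguments'
#'   elasticities. Individual outer elasticities can be pinned to numeric
#'   values via `fixed` (e.g. `h_f = 1` for constant conversion efficiency).
#' * `explicit_inner`: a closed-form auxiliary quantity, e.g. per-capita
#'   consumption `C = F / Y`. Its elasticities with respect to its arguments
#'   are computed exactly by symbolic log-differentiation at the normalized
#'   point (for `C = F/Y`: 1 w.r.t. `F`, -1 w.r.t. `Y`), never left as free
#'   parameters.
#' * `derivative_condition`: a stationarity/optimality condition
#'   `dP/dV = 0` at the steady state, which pins the elasticity of process
#'   `P` w.r.t. variable `V` to zero.
#' * `conservation_law`: a conserved linear combination of variables. The
#'   Jacobian keeps full size; the law is recorded as constraints on scale
#'   parameters (flux matching), reported by [gm_scale_parameters()].
#'
#' @param model A `gm_model`.
#' @param kind One of `"function_composition"`, `"explicit_inner"`,
#'   `"derivative_condition"`, `"conservation_law"`.
#' @param ... Kind-specific payload fields:
#'   * composition: `process`, `outer` (symbol stem for outer elasticities),
#'     `arguments` (process or auxiliary names), optional `fixed` (named list).
#'   * explicit_inner: `name`, `expression` (character, in declared process /
#'     variable names), `arguments`.
#'   * derivative_condition: `process`, `variable`.
#'   * conservation_law: `coefficients` (named numeric over variables).
#' @return The extended `gm_model`.
#' @export
gm_add_constraint <- function(model,
                              kind = c("function_composition", "explicit_inner",
                                       "derivative_condition", "conservation_law"),
                              ...) {
  stopifnot(inherits(model, "gm_model"))
  kind <- match.arg(kind)
  payload <- list(...)
  pn <- proc_names(model)
  aux <- vapply(Filter(function(cn) cn$kind == "explicit_inner", model$constraints),
                function(cn) cn$name, character(1))
  known <- c(pn, aux)
  if (kind == "function_composition") {
    stopifnot(is.character(payload$process), is.character(payload$outer))
    if (!payload$process %in% pn) {
      stop(sprintf("unknown process '%s'", payload$process), call. = FALSE)
    }
    bad <- setdiff(payload$arguments, known)
    if (length(bad) > 0L) {
      stop(sprintf("composition arguments not declared: %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    if (payload$process %in% payload$arguments) {
      stop("composition cannot take its own process as argument", call. = FALSE)
    }
    payload$fixed <- as.list(payload$fixed %||% list())
  } else if (kind == "explicit_inner") {
    check_identifier(payload$name, "auxiliary name")
    stopifnot(is.character(payload$expression))
    bad <- setdiff(payload$arguments, c(known, model$variables))
    if (length(bad) > 0L) {
      stop(sprintf("inner arguments not declared: %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    }
  } else if (kind == "derivative_condition") {
    if (!payload$process %in% pn) {
      stop(sprintf("unknown process '%s'", payload$process), call. = FALSE)
    }
    if (!payload$variable %in% model$variables) {
      stop(sprintf("unknown variable '%s'", payload$variable), call. = FALSE)
    }
  } else { # conservation_law
    co <- payload$coefficients
    if (is.null(names(co)) || !all(names(co) %in% model$variables)) {
      stop("conservation coefficients must be named after declared variables", call. = FALSE)
    }
  }
  model$constraints[[length(model$constraints) + 1L]] <- c(list(kind = kind), payload)
  model
}

#' Validate a model structure
#'
#' Checks that every state variable has at least one gain and at least one
#' loss process and that all cross-references resolve. Validation is
#' report-based: an empty report means the model is well-formed.
#'
#' @param model A `gm_model`.
#' @return A tibble with columns `variable`, `problem`; zero rows iff valid.
#' @export
gm_validate <- function(model) {
  stopifnot(inherits(model, "gm_model"))
  rows <- list()
  for (v in model$variables) {
    gains <- vapply(model$processes, function(p) v %in% p$gain, logical(1))
    losses <- vapply(model$processes, function(p) v %in% p$loss, logical(1))
    if (!any(gains)) rows[[length(rows) + 1L]] <- tibble::tibble(variable = v, problem = "missing gain")
    if (!any(losses)) rows[[length(rows) + 1L]] <- tibble::tibble(variable = v, problem = "missing loss")
  }
  if (length(model$variables) == 0L) {
    rows[[length(rows) + 1L]] <- tibble::tibble(variable = NA_character_, problem = "no variables declared")
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(variable = character(0), problem = character(0)))
  }
  dplyr::bind_rows(rows)
}

gm_is_valid <- function(model) nrow(gm_validate(model)) == 0L

assert_valid <- function(model) {
  rep <- gm_validate(model)
  if (nrow(rep) > 0L) {
    stop("model structure is not valid:\n",
         paste(sprintf("  %s: %s", rep$variable, rep$problem), collapse = "\n"),
         call. = FALSE)
  }
  invisible(model)
}

#' @export
print.gm_model <- function(x, ...) {
  cat(sprintf("<generalized model> %s\n", x$name))
  cat(sprintf("  variables (%d): %s\n", length(x$variables),
              paste(x$variables, collapse = ", ")))
  for (p in x$processes) {
    contr <- c(if (length(p$gain)) paste0("+", p$gain), if (length(p$loss)) paste0("-", p$loss))
    cat(sprintf("  process %s: %s | depends on {%s}\n", p$name,
                paste(contr, collapse = ", "), paste(p$dependencies, collapse = ", ")))
  }
  if (length(x$constraints) > 0L) {
    cat(sprintf("  constraints: %d\n", length(x$constraints)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
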