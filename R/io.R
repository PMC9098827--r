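# YAML model configuration: declaration schema, lossless round trip.

#' Write a model (and optional ranges) to a YAML configuration
#'
#' The configuration schema mirrors the declaration API: `name`,
#' `variables` (name + description), `processes` (name, gain, loss,
#' dependencies), `constraints` (kind + payload), and optional `ranges`
#' (`symbol: [lo, hi]`) and `parameters` (fixed symbol values). The round
#' trip write -> read is lossless.
#'
#' @param model A `gm_model`.
#' @param path Output file path.
#' @param ranges Optional named list `symbol = c(lo, hi)`.
#' @param parameters Optional named list of fixed parameter values.
#' @return `path`, invisibly.
#' @export
gm_write_yaml <- function(model, path, ranges = NULL, parameters = NULL) {
  stopifnot(inherits(model, "gm_model"))
  obj <- list(
    name = model$name,
    variables = lapply(seq_along(model$variables), function(i)
      list(name = model$variables[i], description = model$descriptions[i])),
    processes = lapply(model$processes, function(p)
      list(name = p$name, gain = as.list(p$gain), loss = as.list(p$loss),
           dependencies = as.list(p$dependencies))),
    constraints = lapply(model$constraints, function(cn) {
      cn$arguments <- as.list(cn$arguments %||% NULL)
      if (length(cn$arguments) == 0L) cn$arguments <- NULL
      if (!is.null(cn$coefficients)) cn$coefficients <- as.list(cn$coefficients)
      cn
    })
  )
  if (!is.null(ranges)) obj$ranges <- lapply(ranges, as.list)
  if (!is.null(parameters)) obj$parameters <- parameters
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a model configuration from YAML
#'
#' Parses and validates a configuration written in the [gm_write_yaml()]
#' schema. Parse errors, schema violations (including branching groups whose
#' explicitly fixed weights do not sum to one, reported by group), and
#' structural validation failures are raised as distinct errors.
#'
#' @param path Path to a YAML configuration.
#' @return A list with elements `model` (validated `gm_model`), `ranges`
#'   (named list or `NULL`), `parameters` (named list or `NULL`).
#' @export
gm_read_yaml <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  obj <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop(sprintf("YAML parse error in %s: %s",
                                                   path, conditionMessage(e)), call. = FALSE))
  for (field in c("variables", "processes")) {
    if (is.null(obj[[field]])) {
      stop(sprintf("schema violation: missing '%s' section", field), call. = FALSE)
    }
  }
  m <- gm_model(obj$name %||% "model")
  for (v in obj$variables) {
    if (is.null(v$name)) stop("schema violation: variable without a name", call. = FALSE)
    m <- gm_add_variable(m, v$name, v$description %||% "")
  }
  for (p in obj$processes) {
    if (is.null(p$name)) stop("schema violation: process without a name", call. = FALSE)
    m <- gm_add_process(m, p$name,
                        gain = unlist(p$gain) %||% character(0),
                        loss = unlist(p$loss) %||% character(0),
                        dependencies = unlist(p$dependencies) %||% character(0))
  }
  for (cn in obj$constraints %||% list()) {
    if (is.null(cn$kind)) stop("schema violation: constraint without a kind", call. = FALSE)
    payload <- cn[setdiff(names(cn), "kind")]
    if (!is.null(payload$arguments)) payload$arguments <- unlist(payload$arguments)
    if (!is.null(payload$coefficients)) payload$coefficients <- unlist(payload$coefficients)
    m <- do.call(gm_add_constraint, c(list(m, kind = cn$kind), payload))
  }
  rep <- gm_validate(m)
  if (nrow(rep) > 0L) {
    stop("model validation failed:\n",
         paste(sprintf("  %s: %s", rep$variable, rep$problem), collapse = "\n"),
         call. = FALSE)
  }
  ranges <- obj$ranges
  if (!is.null(ranges)) {
    for (nm in names(ranges)) {
      v <- unlist(ranges[[nm]])
      if (length(v) != 2L || !is.numeric(v) || v[1] > v[2]) {
        stop(sprintf("schema violation: range for '%s' must be [lo, hi]", nm),
             call. = FALSE)
      }
      ranges[[nm]] <- v
    }
  }
  parameters <- obj$parameters
  if (!is.null(parameters)) {
    check_fixed_branching(m, parameters)
  }
  list(model = m, ranges = ranges, parameters = parameters)
}

# explicit weights fully covering a branching group must sum to one
check_fixed_branching <- function(model, parameters) {
  sk <- scale_skeleton(model)
  for (g in sk$groups) {
    if (all(g$symbols %in% names(parameters))) {
      s <- sum(unlist(parameters[g$symbols]))
      if (abs(s - 1) > 1e-8) {
        stop(sprintf("schema violation: branching group %s:%s weights sum to %g, not 1",
                     g$variable, g$sign, s), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}
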