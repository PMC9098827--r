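# Ensemble exploration of the generalized parameter space.

#' Parameter ranges for ensemble sampling
#'
#' Starts from the defaults of [gm_free_parameters()] and applies named
#' overrides `symbol = c(lo, hi)`. Branching-weight symbols are sampled
#' jointly on the unit simplex (flat Dirichlet over each group), so range
#' overrides for them are rejected.
#'
#' @param jac A `gm_jacobian`.
#' @param ... Named numeric length-2 overrides, e.g. `g_x = c(0, 1)`.
#' @return A tibble of ranges (columns `symbol`, `role`, `group`, `lo`, `hi`).
#' @export
gm_ranges <- function(jac, ...) {
  rng <- gm_free_parameters(jac)
  overrides <- list(...)
  for (nm in names(overrides)) {
    i <- match(nm, rng$symbol)
    if (is.na(i)) stop(sprintf("'%s' is not a free parameter of this Jacobian", nm),
                       call. = FALSE)
    if (rng$role[i] == "branching") {
      stop(sprintf("'%s' is a branching weight; it is sampled on the simplex", nm),
           call. = FALSE)
    }
    v <- overrides[[nm]]
    if (!is.numeric(v) || length(v) != 2L || v[1] > v[2]) {
      stop(sprintf("range for '%s' must be c(lo, hi) with lo <= hi", nm), call. = FALSE)
    }
    if (rng$role[i] == "turnover" && v[1] <= 0) {
      stop(sprintf("turnover range for '%s' must be strictly positive", nm), call. = FALSE)
    }
    rng$lo[i] <- v[1]; rng$hi[i] <- v[2]
  }
  rng
}

check_ranges_cover <- function(jac, ranges) {
  need <- sort(unique(unlist(lapply(jac$entries, p_free_symbols))))
  missing <- setdiff(need, ranges$symbol)
  if (length(missing) > 0L) {
    stop("ranges do not cover Jacobian symbol(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Draw M parameter sets: scalar parameters uniform in [lo, hi]; each
# branching group jointly flat-Dirichlet on its simplex (the eliminated
# weight is implied as one minus the free ones).
draw_parameters <- function(jac, ranges, M) {
  df <- list()
  scalars <- ranges[ranges$role != "branching", ]
  for (i in seq_len(nrow(scalars))) {
    df[[scalars$symbol[i]]] <- stats::runif(M, scalars$lo[i], scalars$hi[i])
  }
  for (g in jac$scale$groups) {
    k <- length(g$symbols)
    e <- matrix(stats::rexp(M * k), M, k)
    w <- e / rowSums(e)
    for (i in seq_along(g$free)) df[[g$free[i]]] <- w[, i]
  }
  tibble::as_tibble(df)
}

#' Leading eigenvalue of a numeric matrix
#'
#' Returns an eigenvalue of maximal real part; ties on the real part are
#' broken by larger imaginary modulus, and the representative with
#' `Im >= 0` is returned. Dense eigendecomposition is used throughout (all
#' systems in scope are small).
#'
#' @param J A square numeric matrix with finite entries.
#' @return A complex scalar.
#' @examples
#' leading_eigenvalue(matrix(c(0, 1, -1, 0), 2, 2)) # +1i
#' @export
leading_eigenvalue <- function(J) {
  if (!is.matrix(J) || nrow(J) != ncol(J) || !all(is.finite(J))) {
    stop("J must be a square numeric matrix with finite entries", call. = FALSE)
  }
  ev <- eigen(J, only.values = TRUE)$values
  ev <- as.complex(ev)
  ord <- order(-Re(ev), -abs(Im(ev)))
  lead <- ev[ord[1]]
  if (Im(lead) < 0) lead <- Conj(lead)
  lead
}

#' Binary stability indicator
#'
#' 1 if the steady state is stable (`Re(lambda0) < 0`, strict), else 0;
#' a leading eigenvalue exactly on the imaginary axis counts as unstable.
#'
#' @param lambda0 Leading eigenvalue (complex or numeric scalar).
#' @return Integer 0 or 1.
#' @export
stability_indicator <- function(lambda0) {
  as.integer(Re(lambda0) < 0)
}

#' Sample an ensemble of generalized parameter sets
#'
#' Draws `M` random parameter sets (uniform per scalar parameter, flat
#' Dirichlet per branching group), evaluates the Jacobian for each, and
#' records the leading eigenvalue and the binary stability indicator.
#' Identical `(ranges, M, seed)` give identical results.
#'
#' @param jac A `gm_jacobian`.
#' @param M Number of samples.
#' @param seed Integer RNG seed.
#' @param ranges Ranges tibble from [gm_ranges()]; default ranges if `NULL`.
#' @return A `gm_ensemble` tibble: one row per sample, one column per free
#'   parameter, plus `lambda_re`, `lambda_im`, `stable`.
#' @examples
#' ens <- gm_sample_ensemble(gm_jacobian(gm_fixture("one_d_gain_loss")),
#'                           M = 500, seed = 1)
#' mean(ens$stable)
#' @export
gm_sample_ensemble <- function(jac, M, seed = 1L, ranges = NULL) {
  stopifnot(inherits(jac, "gm_jacobian"), M >= 1)
  ranges <- ranges %||% gm_ranges(jac)
  check_ranges_cover(jac, ranges)
  set.seed(seed)
  params <- draw_parameters(jac, ranges, M)
  res <- classify_samples(jac, params)
  out <- dplyr::bind_cols(params, res)
  class(out) <- c("gm_ensemble", class(out))
  attr(out, "seed") <- seed
  attr(out, "ranges") <- ranges
  attr(out, "jacobian") <- jac
  out
}

classify_samples <- function(jac, params) {
  M <- nrow(params)
  evalr <- gm_jacobian_evaluator(jac)
  arr <- evalr(params)
  if (jac$n == 1L) {
    lam <- complex(real = arr[1, 1, ], imaginary = 0)
  } else {
    lam <- vapply(seq_len(M), function(m) leading_eigenvalue(arr[, , m]), complex(1))
  }
  tibble::tibble(lambda_re = Re(lam), lambda_im = Im(lam),
                 stable = stability_indicator(lam))
}

#' Stability correlation of each parameter
#'
#' Correlates each sampled parameter with the binary stability indicator. A
#' parameter that fully determines stability scores +1 (stabilizing) or -1
#' (destabilizing); the score is the Pearson (point-biserial) correlation so
#' that this calibration holds. Set `normalize = FALSE` for the raw
#' covariance.
#'
#' @param ens A `gm_ensemble` from [gm_sample_ensemble()].
#' @param normalize Use Pearson correlation (default) instead of covariance.
#' @return A `gm_correlation` tibble with columns `symbol`, `score`.
#' @export
gm_stability_correlation <- function(ens, normalize = TRUE) {
  stopifnot(inherits(ens, "gm_ensemble"), nrow(ens) >= 2)
  pcols <- setdiff(names(ens), c("lambda_re", "lambda_im", "stable"))
  s <- ens$stable
  if (stats::sd(s) == 0) {
    warning("stability indicator is constant over the ensemble; scores undefined")
    score <- rep(NA_real_, length(pcols))
  } else {
    score <- vapply(pcols, function(p) {
      x <- ens[[p]]
      if (stats::sd(x) == 0) return(NA_real_)
      if (normalize) stats::cor(x, s) else stats::cov(x, s)
    }, numeric(1))
  }
  out <- tibble::tibble(symbol = pcols, score = unname(score))
  class(out) <- c("gm_correlation", class(out))
  out
}

#' Proportion-of-stable-webs sweep
#'
#' Varies one or two parameters systematically over a grid while all other
#' parameters are randomized, and records per grid cell the proportion of
#' stable parameter sets (PSW).
#'
#' @param jac A `gm_jacobian`.
#' @param sweep Named list of grid vectors for 1 or 2 free parameters,
#'   e.g. `list(l_x = seq(0, 2, by = 0.5))`.
#' @param M Samples per grid cell.
#' @param seed Integer RNG seed.
#' @param ranges Ranges for the randomized remainder (default ranges if
#'   `NULL`).
#' @return A `gm_sweep` tibble: swept parameter columns, `psw`, `n`.
#' @examples
#' j <- gm_jacobian(gm_fixture("one_d_gain_loss"))
#' gm_psw_sweep(j, list(l_x = c(0.5, 1, 1.5, 2)), M = 200, seed = 1)
#' @export
gm_psw_sweep <- function(jac, sweep, M = 1000L, seed = 1L, ranges = NULL) {
  stopifnot(inherits(jac, "gm_jacobian"), is.list(sweep))
  if (length(sweep) < 1L || length(sweep) > 2L || is.null(names(sweep))) {
    stop("sweep must be a named list of 1 or 2 grid vectors", call. = FALSE)
  }
  if (any(vapply(sweep, length, integer(1)) == 0L)) {
    stop("sweep grids must be nonempty", call. = FALSE)
  }
  ranges <- ranges %||% gm_ranges(jac)
  check_ranges_cover(jac, ranges)
  bad <- setdiff(names(sweep), ranges$symbol)
  if (length(bad) > 0L) {
    stop("swept parameter(s) not in the Jacobian: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(ranges$role[match(names(sweep), ranges$symbol)] == "branching")) {
    stop("branching weights cannot be swept directly", call. = FALSE)
  }
  grid <- tidyr::expand_grid(!!!sweep)
  rest <- ranges[!ranges$symbol %in% names(sweep), ]
  set.seed(seed)
  psw <- numeric(nrow(grid))
  for (cell in seq_len(nrow(grid))) {
    rng_cell <- ranges
    for (p in names(sweep)) {
      i <- match(p, rng_cell$symbol)
      rng_cell$lo[i] <- rng_cell$hi[i] <- grid[[p]][cell]
    }
    params <- draw_parameters(jac, rng_cell, M)
    psw[cell] <- mean(classify_samples(jac, params)$stable)
  }
  out <- dplyr::mutate(grid, psw = psw, n = as.integer(M))
  class(out) <- c("gm_sweep", class(out))
  attr(out, "seed") <- seed
  attr(out, "swept") <- names(sweep)
  out
}

# ---- tidiers and plots -----------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-parameter summary of an ensemble
#'
#' One row per sampled parameter with its stability-correlation score.
#'
#' @param x A `gm_ensemble`.
#' @param ... Unused.
#' @return A tibble with columns `symbol`, `score`.
#' @export
tidy.gm_ensemble <- function(x, ...) {
  out <- gm_stability_correlation(x)
  tibble::as_tibble(out)
}

#' One-row summary of an ensemble
#'
#' @param x A `gm_ensemble`.
#' @param ... Unused.
#' @return A one-row tibble: `n_samples`, `psw`, `mean_lambda_re`, `seed`.
#' @export
glance.gm_ensemble <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x),
    psw = mean(x$stable),
    mean_lambda_re = mean(x$lambda_re),
    seed = attr(x, "seed")
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a PSW sweep
#'
#' Line plot for one swept parameter, heatmap for two.
#'
#' @param object A `gm_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gm_sweep <- function(object, ...) {
  swept <- attr(object, "swept")
  if (length(swept) == 1L) {
    ggplot2::ggplot(object, ggplot2::aes(x = .data[[swept[1]]], y = .data$psw)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::ylim(0, 1) +
      ggplot2::labs(y = "proportion of stable webs")
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = .data[[swept[1]]], y = .data[[swept[2]]],
                                         fill = .data$psw)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "PSW")
  }
}

#' Plot stability-correlation scores
#'
#' @param object A `gm_correlation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gm_correlation <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$symbol, .data$score),
                               y = .data$score)) +
    ggplot2::geom_col() + ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "stability correlation")
}

#' @importFrom rlang .data
NULL
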