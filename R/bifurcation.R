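# Bifurcation detection along parameter paths and classification grids.
#
# In a generalized Jacobian there are two generic local bifurcations of the
# steady state: a single real eigenvalue crossing zero (saddle-node type;
# detected by a sign change of det J, since the determinant is the product of
# the eigenvalues) and a complex conjugate pair crossing the imaginary axis
# (Hopf; detected by tracking the largest real part among non-real
# eigenvalues). Both detectors bracket on a grid and refine by bisection.

#' Define a parameter path
#'
#' Either a straight segment in one parameter (all other parameters held at
#' `base`), or an explicit list of waypoints (named parameter sets, linearly
#' interpolated componentwise).
#'
#' @param base Named list/vector of values for every free parameter (for the
#'   segment form, the swept parameter's entry is overwritten).
#' @param param Name of the swept parameter (segment form).
#' @param from,to Segment endpoints (segment form).
#' @param waypoints Optional list of named parameter sets (waypoint form).
#' @return A `gm_path` object.
#' @export
gm_path <- function(base = NULL, param = NULL, from = NULL, to = NULL,
                    waypoints = NULL) {
  if (!is.null(waypoints)) {
    stopifnot(is.list(waypoints), length(waypoints) >= 2L)
    return(structure(list(kind = "waypoints", waypoints = lapply(waypoints, as.list)),
                     class = "gm_path"))
  }
  stopifnot(!is.null(base), is.character(param), is.numeric(from), is.numeric(to))
  structure(list(kind = "segment", base = as.list(base), param = param,
                 from = from, to = to),
            class = "gm_path")
}

# parameter set at path coordinate t in [0, 1]
path_point <- function(path, t) {
  if (path$kind == "segment") {
    pt <- path$base
    pt[[path$param]] <- path$from + t * (path$to - path$from)
    return(pt)
  }
  wps <- path$waypoints
  k <- length(wps) - 1L
  seg <- min(max(floor(t * k), 0L), k - 1L)
  u <- t * k - seg
  a <- wps[[seg + 1L]]; b <- wps[[seg + 2L]]
  out <- a
  for (nm in names(a)) out[[nm]] <- a[[nm]] + u * (b[[nm]] - a[[nm]])
  out
}

path_location <- function(path, t) {
  if (path$kind == "segment") path$from + t * (path$to - path$from) else t
}

check_path <- function(jac, path) {
  pt <- path_point(path, 0)
  need <- setdiff(sort(unique(unlist(lapply(jac$entries, p_free_symbols)))), names(pt))
  if (length(need) > 0L) {
    stop("path does not cover Jacobian symbol(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

empty_hits <- function() {
  tibble::tibble(type = character(0), location = numeric(0), t = numeric(0),
                 residual = numeric(0), eigen_re = numeric(0), eigen_im = numeric(0))
}

#' Locate zero-eigenvalue (saddle-node-type) bifurcations along a path
#'
#' Evaluates `det J` on an initial bracketing grid along the path, brackets
#' every sign change, and refines each root by bisection. At a reported hit
#' `|det J|` is below the solver tolerance and the Jacobian has a real
#' eigenvalue of correspondingly small magnitude.
#'
#' @param jac A `gm_jacobian`.
#' @param path A `gm_path`.
#' @param tol Residual tolerance on `|det J|` at a hit.
#' @param n_grid Initial bracketing resolution (default 200 path points).
#' @return A tibble of hits (columns `type`, `location`, `t`, `residual`,
#'   `eigen_re`, `eigen_im`), in path order; zero rows if none.
#' @examples
#' j <- gm_jacobian(gm_fixture("one_d_gain_loss"))
#' p <- gm_path(base = list(alpha_x = 1, l_x = 1), param = "g_x",
#'              from = 0, to = 2)
#' scan_zero_eigenvalue(j, p)
#' @export
scan_zero_eigenvalue <- function(jac, path, tol = 1e-8, n_grid = 200L) {
  stopifnot(inherits(jac, "gm_jacobian"), inherits(path, "gm_path"))
  check_path(jac, path)
  f <- function(t) {
    d <- det(gm_eval_jacobian(jac, path_point(path, t)))
    if (!is.finite(d)) stop("non-finite determinant along path", call. = FALSE)
    d
  }
  ts <- seq(0, 1, length.out = n_grid)
  vals <- vapply(ts, f, numeric(1))
  hits <- list()
  for (i in seq_len(n_grid - 1L)) {
    lo <- vals[i]; hi <- vals[i + 1L]
    if (lo == 0 && i > 1L) next # counted at the left bracket
    if (sign(lo) * sign(hi) > 0) next
    root <- stats::uniroot(f, c(ts[i], ts[i + 1L]), tol = .Machine$double.eps^0.75)
    J <- gm_eval_jacobian(jac, path_point(path, root$root))
    ev <- eigen(J, only.values = TRUE)$values
    crit <- ev[which.min(Mod(ev))]
    hits[[length(hits) + 1L]] <- tibble::tibble(
      type = "zero_eigenvalue", location = path_location(path, root$root),
      t = root$root, residual = abs(det(J)),
      eigen_re = Re(crit), eigen_im = Im(crit))
  }
  if (length(hits) == 0L) return(empty_hits())
  out <- dplyr::arrange(dplyr::bind_rows(hits), t)
  out[out$residual < tol, , drop = FALSE]
}

# largest real part among non-real eigenvalues; NA if the spectrum is real
max_re_nonreal <- function(J, nonreal_tol = 1e-9) {
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[abs(Im(ev)) > nonreal_tol]
  if (length(ev) == 0L) return(NA_real_)
  max(Re(ev))
}

#' Locate Hopf bifurcations along a path
#'
#' Tracks the largest real part among non-real eigenvalues along the path,
#' brackets its sign changes, and refines by bisection. Each hit is verified
#' to have a genuinely non-real critical pair and `|det J|` above tolerance
#' (excluding zero-eigenvalue crossings).
#'
#' @inheritParams scan_zero_eigenvalue
#' @param tol Tolerance on `|Re(lambda_pair)|` at a hit.
#' @return A tibble of hits, as in [scan_zero_eigenvalue()], with
#'   `type = "hopf"` and the critical pair's eigenvalue (`Im >= 0`
#'   representative).
#' @export
scan_hopf <- function(jac, path, tol = 1e-8, n_grid = 200L) {
  stopifnot(inherits(jac, "gm_jacobian"), inherits(path, "gm_path"))
  if (jac$n < 2L) {
    stop("no Hopf bifurcation in a one-dimensional system", call. = FALSE)
  }
  check_path(jac, path)
  f <- function(t) max_re_nonreal(gm_eval_jacobian(jac, path_point(path, t)))
  ts <- seq(0, 1, length.out = n_grid)
  vals <- vapply(ts, f, numeric(1))
  hits <- list()
  for (i in seq_len(n_grid - 1L)) {
    lo <- vals[i]; hi <- vals[i + 1L]
    if (is.na(lo) || is.na(hi)) next
    if (lo == 0 && i > 1L) next
    if (sign(lo) * sign(hi) > 0) next
    a <- ts[i]; b <- ts[i + 1L]; fa <- lo
    for (it in seq_len(80L)) { # bisection (f may be non-smooth where pairs merge)
      mid <- (a + b) / 2
      fm <- f(mid)
      if (is.na(fm)) break
      if (sign(fm) == sign(fa)) { a <- mid; fa <- fm } else b <- mid
    }
    root <- (a + b) / 2
    J <- gm_eval_jacobian(jac, path_point(path, root))
    ev <- eigen(J, only.values = TRUE)$values
    cand <- ev[Im(ev) > 1e-9]
    if (length(cand) == 0L) next
    crit <- cand[which.min(abs(Re(cand)))]
    if (abs(Re(crit)) >= tol) next
    if (abs(Im(crit)) <= tol) next
    if (abs(det(J)) <= tol) next # zero-eigenvalue crossing, not a Hopf
    hits[[length(hits) + 1L]] <- tibble::tibble(
      type = "hopf", location = path_location(path, root), t = root,
      residual = abs(Re(crit)), eigen_re = Re(crit), eigen_im = Im(crit))
  }
  if (length(hits) == 0L) return(empty_hits())
  dplyr::arrange(dplyr::bind_rows(hits), t)
}

#' Bialternate-product Hopf test matrix
#'
#' The bialternate product `2J (.) I` has eigenvalues `lambda_i + lambda_j`
#' (i > j), so its determinant vanishes whenever an eigenvalue pair of `J`
#' sums to zero — in particular on a Hopf locus. Provided as an algebraic
#' cross-check for small systems (the construction is practical up to about
#' ten variables); note its determinant also vanishes for symmetric real
#' pairs, so it is a necessary, not sufficient, Hopf indicator.
#'
#' @param J Square numeric matrix, `n >= 2`.
#' @return The `n(n-1)/2` square bialternate-product matrix.
#' @export
gm_bialternate <- function(J) {
  stopifnot(is.matrix(J), nrow(J) == ncol(J), nrow(J) >= 2)
  n <- nrow(J)
  pairs <- which(lower.tri(matrix(TRUE, n, n)), arr.ind = TRUE) # p > q
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  m <- nrow(pairs)
  B <- matrix(0, m, m)
  for (a in seq_len(m)) {
    p <- pairs[a, 1]; q <- pairs[a, 2]
    for (b in seq_len(m)) {
      r <- pairs[b, 1]; s <- pairs[b, 2]
      val <- 0
      if (r == q) {
        val <- -J[p, s]
      } else if (r != p && s == q) {
        val <- J[p, r]
      } else if (r == p && s == q) {
        val <- J[p, p] + J[q, q]
      } else if (r == p && s != q) {
        val <- J[q, s]
      } else if (s == p) {
        val <- -J[q, r]
      }
      B[a, b] <- val
    }
  }
  B
}

#' Classify a stability diagram grid
#'
#' Evaluates the leading eigenvalue over a 2- or 3-parameter grid, holding
#' the remaining parameters at a single fixed set (deterministic diagrams)
#' or, with `randomize = TRUE`, reporting the proportion of stable webs per
#' cell over randomized remainders. Classes: `stable` (`Re(lambda0) < 0`),
#' `unstable_oscillatory` (unstable with non-real leading eigenvalue),
#' `unstable_real`.
#'
#' @param jac A `gm_jacobian`.
#' @param axes Named list of 2 or 3 grid vectors over free parameters.
#' @param fixed Named values for all remaining free parameters; if `NULL`
#'   they are drawn once (seeded) from the default ranges.
#' @param randomize Randomize the remainder per cell and add a `psw` column.
#' @param M Samples per cell when `randomize = TRUE`.
#' @param seed Integer RNG seed.
#' @return A `gm_grid` tibble: axis columns, `class`, `lambda_re`,
#'   `lambda_im` (and `psw` when randomized).
#' @export
classify_grid <- function(jac, axes, fixed = NULL, randomize = FALSE,
                          M = 200L, seed = 1L) {
  stopifnot(inherits(jac, "gm_jacobian"), is.list(axes))
  if (length(axes) < 1L || length(axes) > 3L || is.null(names(axes))) {
    stop("axes must be a named list of 1-3 grid vectors", call. = FALSE)
  }
  free <- gm_free_parameters(jac)
  bad <- setdiff(names(axes), free$symbol)
  if (length(bad) > 0L) {
    stop("axis parameter(s) not free in the Jacobian: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rest <- setdiff(free$symbol, names(axes))
  set.seed(seed)
  if (is.null(fixed)) {
    rng <- gm_ranges(jac)
    draw <- draw_parameters(jac, rng, 1L)
    fixed <- as.list(draw[1, rest, drop = FALSE])
  } else {
    fixed <- as.list(fixed)
    missing <- setdiff(rest, names(fixed))
    if (length(missing) > 0L) {
      stop("fixed values missing for: ", paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  grid <- tidyr::expand_grid(!!!axes)
  res <- vector("list", nrow(grid))
  for (cell in seq_len(nrow(grid))) {
    pt <- fixed
    for (nm in names(axes)) pt[[nm]] <- grid[[nm]][cell]
    lam <- leading_eigenvalue(gm_eval_jacobian(jac, pt))
    cls <- if (Re(lam) < 0) "stable" else if (abs(Im(lam)) > 1e-9)
      "unstable_oscillatory" else "unstable_real"
    row <- tibble::tibble(class = cls, lambda_re = Re(lam), lambda_im = Im(lam))
    if (randomize) {
      rng <- gm_ranges(jac)
      for (nm in names(axes)) {
        i <- match(nm, rng$symbol)
        rng$lo[i] <- rng$hi[i] <- grid[[nm]][cell]
      }
      params <- draw_parameters(jac, rng, M)
      row$psw <- mean(classify_samples(jac, params)$stable)
    }
    res[[cell]] <- row
  }
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  class(out) <- c("gm_grid", class(out))
  attr(out, "axes") <- names(axes)
  out
}

#' Plot a stability-classification grid
#'
#' Tile plot over the first two axes; a third axis, if present, is faceted.
#'
#' @param object A `gm_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gm_grid <- function(object, ...) {
  ax <- attr(object, "axes")
  if (length(ax) == 1L) {
    return(ggplot2::ggplot(object, ggplot2::aes(x = .data[[ax[1]]], y = .data$lambda_re,
                                                colour = .data$class)) +
             ggplot2::geom_point())
  }
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]],
                                            fill = .data$class)) +
    ggplot2::geom_tile()
  if (length(ax) == 3L) p <- p + ggplot2::facet_wrap(ax[3], labeller = "label_both")
  p
}
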