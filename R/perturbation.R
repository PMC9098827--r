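# Press-perturbation response and eigenvector-based sensitivity/influence.

#' Steady-state shift under a press perturbation
#'
#' A sustained (press) perturbation with direct impact vector `p` (one entry
#' per equation, in units of the normalized turnover) shifts the normalized
#' steady state by `delta = -J^-1 p` to first order. An entry of 0.05 in the
#' result is a 5% increase of that variable's steady-state value. Adding a
#' small loss (e.g. harvesting a fraction `eps` of a variable's turnover)
#' corresponds to a direct impact of `-eps` on that variable's equation.
#'
#' @param J Square numeric Jacobian, evaluated at a stable steady state away
#'   from bifurcations (singular or near-singular `J` means the steady state
#'   sits at a bifurcation and the response is undefined; the condition
#'   number is guarded: warning above 1e8, error above 1e12).
#' @param p Numeric press vector, one entry per variable.
#' @return A tibble with columns `variable`, `delta` (relative shift).
#' @examples
#' j <- gm_jacobian(gm_fixture("predator_prey")) |> gm_normalize_timescale("X")
#' J <- gm_eval_jacobian(j, list(alpha_y = 1, s_x = 1, f_x = 1, f_y = 1,
#'                               l_x = 1, g_x = 1, g_y = 1.2, m_y = 1,
#'                               sigma_f_x = 0.5))
#' press_response(J, c(-0.01, 0)) # harvest 1% of prey turnover
#' @export
press_response <- function(J, p) {
  if (!is.matrix(J) || nrow(J) != ncol(J) || !all(is.finite(J))) {
    stop("J must be a square numeric matrix with finite entries", call. = FALSE)
  }
  p <- as.numeric(p)
  if (length(p) != nrow(J) || !all(is.finite(p))) {
    stop("press vector must be finite with one entry per variable", call. = FALSE)
  }
  kap <- kappa(J, exact = TRUE)
  if (!is.finite(kap) || kap > 1e12) {
    stop("Jacobian is singular or numerically singular: steady state at a bifurcation; response undefined",
         call. = FALSE)
  }
  if (kap > 1e8) {
    warning("Jacobian is ill-conditioned (near a bifurcation); response may be inaccurate")
  }
  delta <- solve(J, -p)
  vars <- rownames(J) %||% paste0("V", seq_len(nrow(J)))
  tibble::tibble(variable = vars, delta = as.numeric(delta))
}

#' Sensitivity and influence scores
#'
#' Eigenvector-based scores of how strongly each variable responds to
#' (`sensitivity`) and propagates (`influence`) typical perturbations:
#' `Se_i = log(sum_n |v_{n,i}| / |lambda_n|)` over the left eigenvectors
#' `v_n`, and `In_i = log(sum_n |w_{n,i}| / |lambda_n|)` over the right
#' eigenvectors `w_n` (also written Im_i; "influence" is used here).
#' Eigenvectors are bi-orthogonally normalized: right eigenvectors to unit
#' Euclidean norm and left eigenvectors so that `v_n . w_n = 1`, which makes
#' the scores independent of eigenvector scaling. Moduli and `|lambda_n|`
#' keep the scores real for complex conjugate pairs; for real negative
#' eigenvalues `|lambda_n| = -lambda_n`. Dynamical importance is the product
#' `Se_i * In_i`.
#'
#' @param J Square numeric Jacobian; must be diagonalizable. Intended for
#'   stable states (all `Re(lambda_n) < 0`); an unstable state produces a
#'   warning but scores are still returned.
#' @return A `gm_scores` tibble: `variable`, `sensitivity`, `influence`,
#'   `importance`.
#' @examples
#' sensitivity_influence(diag(c(-1, -4)))
#' @export
sensitivity_influence <- function(J) {
  if (!is.matrix(J) || nrow(J) != ncol(J) || !all(is.finite(J))) {
    stop("J must be a square numeric matrix with finite entries", call. = FALSE)
  }
  n <- nrow(J)
  E <- eigen(J)
  lam <- as.complex(E$values)
  W <- matrix(as.complex(E$vectors), n, n)
  # defective matrices have (numerically) dependent eigenvector sets
  sv <- svd(W, nu = 0, nv = 0)$d
  if (sv[length(sv)] / sv[1] < 1e-10) {
    stop("Jacobian is (numerically) defective: eigenvector basis is singular", call. = FALSE)
  }
  if (any(Re(lam) >= 0)) {
    warning("state is not stable (Re(lambda) >= 0 for some eigenvalue); scores returned anyway")
  }
  nrm <- sqrt(colSums(Mod(W)^2))
  W <- sweep(W, 2, nrm, "/")
  V <- solve(W) # row n is the left eigenvector v_n with v_n . w_n = 1
  se <- vapply(seq_len(n), function(i) log(sum(Mod(V[, i]) / Mod(lam))), numeric(1))
  infl <- vapply(seq_len(n), function(i) log(sum(Mod(W[i, ]) / Mod(lam))), numeric(1))
  vars <- rownames(J) %||% paste0("V", seq_len(n))
  out <- tibble::tibble(variable = vars, sensitivity = se, influence = infl,
                        importance = se * infl)
  class(out) <- c("gm_scores", class(out))
  out
}

#' Dynamical importance
#'
#' Elementwise product of the sensitivity and influence scores.
#'
#' @param scores A `gm_scores` tibble from [sensitivity_influence()].
#' @return A tibble with columns `variable`, `importance`.
#' @export
dynamical_importance <- function(scores) {
  stopifnot(is.data.frame(scores),
            all(c("variable", "sensitivity", "influence") %in% names(scores)))
  tibble::tibble(variable = scores$variable,
                 importance = scores$sensitivity * scores$influence)
}
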