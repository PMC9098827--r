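# Sparse multivariate polynomial algebra over named parameter symbols.
#
# Generalized-Jacobian entries are, by construction, polynomials in the scale
# and exponent parameter symbols (linear in each elasticity), so a canonical
# expanded term list supports exact symbolic equality, substitution (e.g. the
# branching elimination sigma_bar = 1 - sigma, or chain-rule replacement of
# elasticities under constraints), and fast vectorized numeric evaluation.
#
# Representation: a gm_poly holds a list of terms; each term is
# list(c = <numeric coefficient>, m = <named integer vector of exponents>).
# Terms are kept in canonical form: exponents sorted by symbol name, like
# monomials merged, zero coefficients dropped, terms ordered by monomial key.

term_key <- function(m) {
  if (length(m) == 0L) return("")
  paste(names(m), m, sep = "^", collapse = "*")
}

p_canonical <- function(terms) {
  if (length(terms) == 0L) return(structure(list(terms = list()), class = "gm_poly"))
  terms <- lapply(terms, function(t) {
    m <- t$m[t$m != 0L]
    if (length(m) > 1L) m <- m[order(names(m))]
    list(c = t$c, m = m)
  })
  keys <- vapply(terms, function(t) term_key(t$m), character(1))
  out <- list()
  for (k in unique(sort(keys))) {
    idx <- which(keys == k)
    co <- sum(vapply(terms[idx], function(t) t$c, numeric(1)))
    if (abs(co) > 1e-12) out[[length(out) + 1L]] <- list(c = co, m = terms[[idx[1]]]$m)
  }
  structure(list(terms = out), class = "gm_poly")
}

p_zero <- function() p_canonical(list())

p_const <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1L, is.finite(x))
  p_canonical(list(list(c = x, m = structure(integer(0), names = character(0)))))
}

p_sym <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  m <- structure(1L, names = name)
  p_canonical(list(list(c = 1, m = m)))
}

as_poly <- function(x) {
  if (inherits(x, "gm_poly")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(p_const(x))
  if (is.character(x) && length(x) == 1L) return(p_sym(x))
  stop("cannot coerce to gm_poly", call. = FALSE)
}

p_add <- function(a, b) {
  a <- as_poly(a); b <- as_poly(b)
  p_canonical(c(a$terms, b$terms))
}

p_neg <- function(a) {
  a <- as_poly(a)
  p_canonical(lapply(a$terms, function(t) list(c = -t$c, m = t$m)))
}

p_sub <- function(a, b) p_add(a, p_neg(b))

mono_mul <- function(m1, m2) {
  if (length(m1) == 0L) return(m2)
  if (length(m2) == 0L) return(m1)
  nm <- union(names(m1), names(m2))
  out <- structure(integer(length(nm)), names = nm)
  out[names(m1)] <- out[names(m1)] + m1
  out[names(m2)] <- out[names(m2)] + m2
  out
}

p_mul <- function(a, b) {
  a <- as_poly(a); b <- as_poly(b)
  if (length(a$terms) == 0L || length(b$terms) == 0L) return(p_zero())
  out <- vector("list", length(a$terms) * length(b$terms))
  k <- 0L
  for (ta in a$terms) for (tb in b$terms) {
    k <- k + 1L
    out[[k]] <- list(c = ta$c * tb$c, m = mono_mul(ta$m, tb$m))
  }
  p_canonical(out)
}

p_pow <- function(a, n) {
  stopifnot(n >= 0L, n == round(n))
  out <- p_const(1)
  a <- as_poly(a)
  for (i in seq_len(n)) out <- p_mul(out, a)
  out
}

p_sum <- function(ps) Reduce(p_add, ps, accumulate = FALSE, p_zero())

#' @noRd
p_is_zero <- function(a) length(as_poly(a)$terms) == 0L

# Exact (expansion-based) equality of two polynomials.
p_equal <- function(a, b, tol = 1e-10) {
  d <- p_sub(a, b)
  all(vapply(d$terms, function(t) abs(t$c) <= tol, logical(1)))
}

p_free_symbols <- function(a) {
  a <- as_poly(a)
  sort(unique(unlist(lapply(a$terms, function(t) names(t$m)))))
}

# Substitute symbol -> polynomial (exponents handled by repeated products).
p_substitute <- function(a, sym, repl) {
  a <- as_poly(a); repl <- as_poly(repl)
  out <- p_zero()
  for (t in a$terms) {
    if (sym %in% names(t$m)) {
      k <- t$m[[sym]]
      rest <- t$m[setdiff(names(t$m), sym)]
      base <- p_canonical(list(list(c = t$c, m = rest)))
      out <- p_add(out, p_mul(base, p_pow(repl, k)))
    } else {
      out <- p_add(out, p_canonical(list(t)))
    }
  }
  out
}

p_substitute_all <- function(a, subs) {
  for (nm in names(subs)) a <- p_substitute(a, nm, subs[[nm]])
  a
}

# Numeric evaluation; `values` is a named list/vector, entries may be vectors
# (all of a common length) for vectorized evaluation over samples.
p_eval <- function(a, values) {
  a <- as_poly(a)
  values <- as.list(values)
  if (length(a$terms) == 0L) return(0)
  acc <- 0
  for (t in a$terms) {
    prod <- t$c
    for (nm in names(t$m)) {
      v <- values[[nm]]
      if (is.null(v)) stop(sprintf("no value supplied for symbol '%s'", nm), call. = FALSE)
      prod <- prod * v^t$m[[nm]]
    }
    acc <- acc + prod
  }
  acc
}

# Render as a plain-text expression, parseable by R (used for export and for
# compiled vectorized evaluation).
p_to_string <- function(a) {
  a <- as_poly(a)
  if (length(a$terms) == 0L) return("0")
  pieces <- vapply(a$terms, function(t) {
    mono <- if (length(t$m) == 0L) "" else
      paste(ifelse(t$m == 1L, names(t$m), paste0(names(t$m), "^", t$m)), collapse = "*")
    co <- t$c
    if (mono == "") return(format(co, digits = 15))
    if (co == 1) return(mono)
    if (co == -1) return(paste0("-", mono))
    paste0(format(co, digits = 15), "*", mono)
  }, character(1))
  out <- pieces[1]
  for (p in pieces[-1]) {
    out <- if (startsWith(p, "-")) paste0(out, " - ", substring(p, 2)) else paste0(out, " + ", p)
  }
  out
}

#' @export
format.gm_poly <- function(x, ...) p_to_string(x)

#' @export
print.gm_poly <- function(x, ...) {
  cat("<polynomial> ", p_to_string(x), "\n", sep = "")
  invisible(x)
}
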