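# Lexicographic Groebner bases: R interface to the compiled fraction-free
# Buchberger kernel (src/groebner.cpp).
#
# Inputs are integer-coefficient polynomials (exact in doubles, < 2^53);
# the kernel works in arbitrary-precision integers, so basis coefficients
# can exceed what a double represents exactly. Returned polynomials
# therefore carry both a numeric coefficient vector (rounded to double,
# used by all floating-point consumers) and the exact decimal strings in
# the "coef_str" attribute (used by the exact reduction below).

# lex compare of exponent vectors: +1 if a > b, -1 if a < b, 0 if equal
lex_cmp <- function(a, b) {
  d <- a - b
  nz <- which(d != 0)
  if (!length(nz)) return(0L)
  if (d[nz[1L]] > 0) 1L else -1L
}

lead_expo <- function(p) p$expo[1L, ]
lead_coef <- function(p) p$coef[1L]

coef_strings <- function(p) {
  s <- attr(p, "coef_str")
  if (!is.null(s)) return(s)
  poly_check_coef(p$coef)
  sprintf("%.0f", p$coef)
}

expo_int <- function(p) matrix(as.integer(p$expo), ncol = length(p$vars))

#' Lexicographic Groebner basis (production path)
#'
#' Buchberger's algorithm with the coprimality and chain criteria,
#' normal-strategy pair selection, and fraction-free exact integer
#' arithmetic (arbitrary precision, in compiled code). Variables are
#' ordered `vars[1] > vars[2] > ...`, so trailing variables are
#' "retained": the smallest basis elements involve them only.
#'
#' @param polys list of `crnpoly` over a common ring.
#' @param max_pairs safety cap on processed S-pairs.
#' @return list of `crnpoly`: the reduced basis (inter-reduced, primitive,
#'   positive leading coefficients), sorted by increasing leading monomial
#'   so the first element lies in the smallest elimination ideal. Each
#'   element carries exact decimal coefficients in `attr(, "coef_str")`.
#' @export
groebner_basis <- function(polys, max_pairs = 20000L) {
  vars <- polys[[1L]]$vars
  inp <- lapply(polys, function(p) {
    stopifnot(identical(p$vars, vars))
    poly_primitive(poly_normalize(p))
  })
  inp <- Filter(Negate(poly_is_zero), inp)
  if (!length(inp)) stop("all input polynomials are zero")
  res <- cpp_groebner(lapply(inp, coef_strings), lapply(inp, expo_int),
                      as.integer(max_pairs))
  lapply(res, function(g) {
    p <- structure(list(coef = as.numeric(g$coef),
                        expo = matrix(as.numeric(g$expo),
                                      ncol = length(vars)),
                        vars = vars),
                   class = "crnpoly")
    attr(p, "coef_str") <- as.character(g$coef_str)
    p
  })
}

#' Exact normal form modulo a basis
#'
#' Fully reduces `p` against `basis` in exact integer arithmetic. The
#' remainder is zero exactly when `p` lies in the ideal generated by a
#' Groebner `basis`; used to verify ideal membership of the steady-state
#' equations in the computed bases.
#'
#' @param p a `crnpoly` with integer coefficients below 2^53.
#' @param basis list of `crnpoly` (typically from [groebner_basis()]).
#' @return the remainder as a `crnpoly` (zero polynomial when `p` is in
#'   the ideal).
#' @export
reduce_mod_basis <- function(p, basis) {
  vars <- p$vars
  p <- poly_primitive(poly_normalize(p))
  if (poly_is_zero(p)) return(p)
  r <- cpp_reduce(coef_strings(p), expo_int(p),
                  lapply(basis, coef_strings), lapply(basis, expo_int))
  out <- structure(list(coef = as.numeric(r$coef),
                        expo = matrix(as.numeric(r$expo), ncol = length(vars)),
                        vars = vars),
                   class = "crnpoly")
  attr(out, "coef_str") <- as.character(r$coef_str)
  out
}
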