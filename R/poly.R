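# Multivariate polynomials with exact integer coefficients.
#
# Coefficients are stored as doubles but kept integral: IEEE doubles represent
# integers exactly up to 2^53, and every operation checks that bound. Rational
# inputs are cleared to a common denominator per polynomial (multiplying an
# equation by a positive constant changes neither its zero set nor the ideal
# it generates up to saturation by that unit). Terms are kept sorted in
# decreasing lexicographic order with vars[1] the highest variable, which is
# the elimination order used throughout.

.COEF_MAX <- 2^53

#' Construct a polynomial from terms
#'
#' Builds a `crnpoly` object over the variable list `vars` (lexicographic
#' order: `vars[1]` is the highest, i.e. eliminated-first, variable).
#'
#' @param coef numeric vector of integer-valued coefficients, one per term.
#' @param expo integer matrix of exponents, one row per term, one column per
#'   variable in `vars`.
#' @param vars character vector of variable names.
#' @return A `crnpoly`: list with elements `coef`, `expo`, `vars`, terms
#'   sorted in decreasing lex order, like terms combined, zero terms dropped.
#' @keywords internal
#' @export
poly_new <- function(coef, expo, vars) {
  expo <- matrix(as.numeric(expo), ncol = length(vars))
  stopifnot(length(coef) == nrow(expo))
  p <- structure(list(coef = as.numeric(coef), expo = expo, vars = vars),
                 class = "crnpoly")
  poly_normalize(p)
}

#' @keywords internal
poly_check_coef <- function(coef) {
  if (any(!is.finite(coef)) || any(abs(coef) >= .COEF_MAX))
    stop("coefficient overflow beyond exact-integer range (2^53); ",
         "try smaller / simpler rational parameter values", call. = FALSE)
  coef
}

# Combine like terms, drop zeros, sort in decreasing lex order.
poly_normalize <- function(p) {
  if (length(p$coef) == 0L) return(p)
  poly_check_coef(p$coef)
  key <- apply(p$expo, 1L, paste, collapse = ",")
  if (anyDuplicated(key)) {
    cs <- rowsum(p$coef, key, reorder = FALSE)
    keep <- !duplicated(key)
    p$expo <- p$expo[keep, , drop = FALSE]
    p$coef <- as.numeric(cs[match(key[keep], rownames(cs)), 1L])
    poly_check_coef(p$coef)
  }
  nz <- p$coef != 0
  p$coef <- p$coef[nz]
  p$expo <- p$expo[nz, , drop = FALSE]
  if (length(p$coef) > 1L) {
    ord <- do.call(order, c(lapply(seq_along(p$vars), function(j) p$expo[, j]),
                            list(decreasing = TRUE)))
    p$coef <- p$coef[ord]
    p$expo <- p$expo[ord, , drop = FALSE]
  }
  p
}

#' Zero, constant and single-variable polynomials
#'
#' @param vars character vector naming the ring variables in lex order.
#' @param c integer-valued constant.
#' @param name variable name (must appear in `vars`).
#' @return A `crnpoly`.
#' @keywords internal
#' @export
poly_zero <- function(vars)
  structure(list(coef = numeric(0),
                 expo = matrix(numeric(0), ncol = length(vars)),
                 vars = vars), class = "crnpoly")

#' @rdname poly_zero
#' @export
poly_const <- function(c, vars) {
  if (c == 0) return(poly_zero(vars))
  poly_new(c, matrix(0, 1L, length(vars)), vars)
}

#' @rdname poly_zero
#' @export
poly_var <- function(name, vars) {
  j <- match(name, vars)
  if (is.na(j)) stop("unknown variable: ", name)
  e <- matrix(0, 1L, length(vars))
  e[1L, j] <- 1
  poly_new(1, e, vars)
}

poly_is_zero <- function(p) length(p$coef) == 0L

#' Polynomial arithmetic
#'
#' Exact ring operations on `crnpoly` objects sharing the same variable list.
#'
#' @param p,q `crnpoly` objects over identical `vars`.
#' @param s integer-valued scalar.
#' @return A `crnpoly`.
#' @keywords internal
#' @export
poly_add <- function(p, q) {
  stopifnot(identical(p$vars, q$vars))
  poly_normalize(structure(list(coef = c(p$coef, q$coef),
                                expo = rbind(p$expo, q$expo),
                                vars = p$vars), class = "crnpoly"))
}

#' @rdname poly_add
#' @export
poly_sub <- function(p, q) poly_add(p, poly_scale(q, -1))

#' @rdname poly_add
#' @export
poly_scale <- function(p, s) {
  p$coef <- poly_check_coef(p$coef * s)
  if (s == 0) return(poly_zero(p$vars))
  p
}

# multiply by a single term coef * x^expo (expo: numeric vector)
poly_mul_term <- function(p, coef, expo) {
  if (coef == 0 || poly_is_zero(p)) return(poly_zero(p$vars))
  p$coef <- poly_check_coef(p$coef * coef)
  p$expo <- p$expo + rep(expo, each = nrow(p$expo))
  p # lex order is preserved by multiplying every term by the same monomial
}

#' @rdname poly_add
#' @export
poly_mul <- function(p, q) {
  stopifnot(identical(p$vars, q$vars))
  if (poly_is_zero(p) || poly_is_zero(q)) return(poly_zero(p$vars))
  np <- nrow(p$expo); nq <- nrow(q$expo)
  coef <- as.vector(outer(p$coef, q$coef))
  ip <- rep(seq_len(np), times = nq)
  iq <- rep(seq_len(nq), each = np)
  poly_normalize(structure(list(coef = coef,
                                expo = p$expo[ip, , drop = FALSE] +
                                       q$expo[iq, , drop = FALSE],
                                vars = p$vars), class = "crnpoly"))
}

#' Total degree of a polynomial
#' @param p a `crnpoly`.
#' @return integer total degree (`-Inf` for the zero polynomial).
#' @keywords internal
#' @export
poly_total_degree <- function(p) {
  if (poly_is_zero(p)) return(-Inf)
  max(rowSums(p$expo))
}

#' Degree in one variable
#' @param p a `crnpoly`.
#' @param name variable name.
#' @keywords internal
#' @export
poly_degree <- function(p, name) {
  j <- match(name, p$vars)
  if (poly_is_zero(p)) return(-Inf)
  max(p$expo[, j])
}

#' Partial derivative
#' @param p a `crnpoly`.
#' @param name variable to differentiate with respect to.
#' @return A `crnpoly`.
#' @keywords internal
#' @export
poly_deriv <- function(p, name) {
  j <- match(name, p$vars)
  if (is.na(j)) stop("unknown variable: ", name)
  keep <- if (poly_is_zero(p)) logical(0) else p$expo[, j] > 0
  coef <- p$coef[keep] * p$expo[keep, j]
  expo <- p$expo[keep, , drop = FALSE]
  if (length(coef)) expo[, j] <- expo[, j] - 1
  poly_new(coef, expo, p$vars)
}

#' Evaluate a polynomial numerically
#'
#' @param p a `crnpoly`.
#' @param values named numeric vector covering every variable that occurs
#'   in `p` with nonzero exponent.
#' @return numeric scalar.
#' @keywords internal
#' @export
poly_eval <- function(p, values) {
  if (poly_is_zero(p)) return(0)
  x <- values[p$vars]
  miss <- if (length(p$vars)) is.na(x) & apply(p$expo, 2L, function(e) any(e > 0))
  if (any(miss)) stop("missing values for: ",
                      paste(p$vars[miss], collapse = ", "))
  x[is.na(x)] <- 1 # unused variables
  sum(p$coef * apply(p$expo, 1L, function(e) prod(x^e)))
}

#' Substitute an exact rational value for a variable
#'
#' Replaces `name` by `num/den` and clears the denominator by multiplying the
#' whole polynomial by `den^d` (`d` = degree in `name`), a positive scaling
#' that preserves the zero set. The variable stays in the ring (its exponents
#' become 0).
#'
#' @param p a `crnpoly`.
#' @param name variable to substitute.
#' @param num,den integer-valued numerator and (positive) denominator.
#' @return A `crnpoly` with integer coefficients.
#' @keywords internal
#' @export
poly_subst_rational <- function(p, name, num, den = 1) {
  j <- match(name, p$vars)
  if (is.na(j)) stop("unknown variable: ", name)
  if (den <= 0) stop("denominator must be positive")
  if (poly_is_zero(p)) return(p)
  d <- max(p$expo[, j])
  if (d == 0 && den == 1) return(p)
  e <- p$expo[, j]
  p$coef <- poly_check_coef(p$coef * num^e * den^(d - e))
  p$expo[, j] <- 0
  g <- poly_content(p$coef)
  if (g > 1) p$coef <- p$coef / g
  poly_normalize(p)
}

# gcd of integer-valued doubles
int_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) { t <- a %% b; a <- b; b <- t }
  a
}

poly_content <- function(coef) {
  g <- 0
  for (c in coef) { g <- int_gcd(g, c); if (g == 1) break }
  max(g, 1)
}

# divide out the integer content; make the leading coefficient positive
poly_primitive <- function(p) {
  if (poly_is_zero(p)) return(p)
  g <- poly_content(p$coef)
  if (p$coef[1L] < 0) g <- -g
  if (g != 1) p$coef <- p$coef / g
  p
}

#' Compare polynomials up to a nonzero scalar
#'
#' @param p,q `crnpoly` objects over identical `vars`.
#' @return logical; `TRUE` when `p = s*q` for some nonzero rational `s`.
#' @keywords internal
#' @export
poly_equal_up_to_scale <- function(p, q, tol = 1e-9) {
  if (poly_is_zero(p) || poly_is_zero(q))
    return(poly_is_zero(p) && poly_is_zero(q))
  if (!identical(dim(p$expo), dim(q$expo)) || any(p$expo != q$expo))
    return(FALSE)
  a <- p$coef / p$coef[1L]
  b <- q$coef / q$coef[1L]
  max(abs(a - b)) <= tol * max(abs(a))
}

#' Render a polynomial as a string
#'
#' @param p a `crnpoly`.
#' @return character scalar such as `"2*x1^2*x2 - 3"`.
#' @keywords internal
#' @export
poly_to_string <- function(p) {
  if (poly_is_zero(p)) return("0")
  terms <- vapply(seq_along(p$coef), function(i) {
    e <- p$expo[i, ]
    facs <- p$vars[e > 0]
    pow <- e[e > 0]
    mono <- paste(ifelse(pow == 1, facs, paste0(facs, "^", pow)),
                  collapse = "*")
    c0 <- p$coef[i]
    if (mono == "") return(format(c0))
    if (c0 == 1) mono else if (c0 == -1) paste0("-", mono)
    else paste0(format(c0), "*", mono)
  }, character(1))
  out <- terms[1L]
  for (t in terms[-1L])
    out <- if (startsWith(t, "-")) paste0(out, " - ", substring(t, 2L))
           else paste0(out, " + ", t)
  out
}

#' @export
print.crnpoly <- function(x, ...) {
  cat(poly_to_string(x), "\n")
  invisible(x)
}

#' @export
format.crnpoly <- function(x, ...) poly_to_string(x)

# coefficients of a univariate polynomial (constant term first);
# errors if any other variable occurs.
poly_univariate_coefs <- function(p, name) {
  j <- match(name, p$vars)
  if (poly_is_zero(p)) return(0)
  other <- p$expo[, -j, drop = FALSE]
  if (any(other > 0)) stop("polynomial is not univariate in ", name)
  d <- max(p$expo[, j])
  coefs <- numeric(d + 1L)
  coefs[p$expo[, j] + 1L] <- p$coef
  coefs
}

# restrict/reorder the ring of p to `vars` (all occurring variables must map)
poly_change_ring <- function(p, vars) {
  idx <- match(p$vars, vars)
  used <- if (poly_is_zero(p)) rep(FALSE, length(p$vars))
          else apply(p$expo, 2L, function(e) any(e > 0))
  if (any(used & is.na(idx)))
    stop("variable(s) not in target ring: ",
         paste(p$vars[used & is.na(idx)], collapse = ", "))
  expo <- matrix(0, nrow(p$expo), length(vars))
  for (j in seq_along(p$vars))
    if (!is.na(idx[j])) expo[, idx[j]] <- p$expo[, j]
  poly_new(p$coef, expo, vars)
}
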