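# Exact rational linear algebra on num/den matrix pairs. Numerators and
# denominators are integer-valued doubles (exact below 2^53); every entry is
# kept reduced (gcd 1, positive denominator). Used for the RREF of the
# stoichiometric matrix and the left null space: conservation vectors must be
# exact for the steady-state system to be consistent, so no floating-point
# pivot tolerances appear here.

rat_reduce <- function(num, den) {
  if (any(den == 0)) stop("zero denominator")
  sgn <- ifelse(den < 0, -1, 1)
  num <- num * sgn; den <- den * sgn
  g <- mapply(int_gcd, num, den)
  g[g == 0] <- 1
  list(num = num / g, den = den / g)
}

rat_add <- function(a, b) {
  r <- rat_reduce(a$num * b$den + b$num * a$den, a$den * b$den)
  poly_check_coef(c(r$num, r$den)); r
}

rat_mul <- function(a, b) {
  r <- rat_reduce(a$num * b$num, a$den * b$den)
  poly_check_coef(c(r$num, r$den)); r
}

rat_div <- function(a, b) rat_mul(a, list(num = b$den, den = b$num))

#' Approximate a double by an exact rational
#'
#' Continued-fraction expansion, stopping when the convergent reproduces `x`
#' to `tol` (relative). Decimal inputs such as `0.2` recover `1/5`.
#'
#' @param x numeric scalar.
#' @param tol relative tolerance.
#' @param max_den largest denominator tried.
#' @return list with integer-valued `num`, `den`.
#' @keywords internal
#' @export
as_rational <- function(x, tol = 1e-12, max_den = 1e9) {
  if (!is.finite(x)) stop("non-finite value")
  h0 <- 0; h1 <- 1; k0 <- 1; k1 <- 0; b <- x
  repeat {
    a <- floor(b)
    h <- a * h1 + h0; k <- a * k1 + k0
    if (k > max_den) break
    h0 <- h1; h1 <- h; k0 <- k1; k1 <- k
    if (abs(h / k - x) <= tol * max(1, abs(x))) break
    if (abs(b - a) < 1e-15) break
    b <- 1 / (b - a)
  }
  rat_reduce(h1, k1)
}

#' Reduced row echelon form with exact fraction arithmetic
#'
#' Gauss-Jordan elimination over the rationals: leading entries are 1 with
#' zeros above and below each pivot; zero rows are dropped.
#'
#' @param M numeric matrix. Non-integer entries are converted to exact
#'   rationals by [as_rational()].
#' @return list with `RD` (numeric matrix, the nonzero RREF rows), `pivots`
#'   (pivot column indices), `rank`, and `RD_rat` (`num`/`den` matrices
#'   holding the same rows exactly).
#' @export
#' @examples
#' rref_rational(matrix(c(1, 2, 2, 4), 2, 2))
rref_rational <- function(M) {
  M <- as.matrix(M)
  nr <- nrow(M); nc <- ncol(M)
  num <- matrix(0, nr, nc); den <- matrix(1, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    r <- if (M[i, j] == round(M[i, j])) list(num = M[i, j], den = 1)
         else as_rational(M[i, j])
    num[i, j] <- r$num; den[i, j] <- r$den
  }
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(nc)) {
    if (row > nr) break
    pr <- which(num[row:nr, col] != 0)
    if (!length(pr)) next
    pr <- pr[1L] + row - 1L
    if (pr != row) {
      num[c(row, pr), ] <- num[c(pr, row), ]
      den[c(row, pr), ] <- den[c(pr, row), ]
    }
    piv <- list(num = num[row, col], den = den[row, col])
    for (j in seq_len(nc)) {
      e <- rat_div(list(num = num[row, j], den = den[row, j]), piv)
      num[row, j] <- e$num; den[row, j] <- e$den
    }
    for (i in seq_len(nr)) {
      if (i == row || num[i, col] == 0) next
      f <- list(num = -num[i, col], den = den[i, col])
      for (j in seq_len(nc)) {
        e <- rat_add(list(num = num[i, j], den = den[i, j]),
                     rat_mul(f, list(num = num[row, j], den = den[row, j])))
        num[i, j] <- e$num; den[i, j] <- e$den
      }
    }
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  rk <- length(pivots)
  keep <- seq_len(rk)
  list(RD = (num / den)[keep, , drop = FALSE],
       pivots = pivots,
       rank = rk,
       RD_rat = list(num = num[keep, , drop = FALSE],
                     den = den[keep, , drop = FALSE]))
}

#' Integer basis of the left null space
#'
#' Solves \eqn{w^T N = 0} exactly. Each basis vector is scaled to integer
#' entries with gcd 1 and a positive first nonzero entry, so conservation
#' vectors are reproducible across runs.
#'
#' @param N numeric matrix (species x reactions).
#' @return list of integer-valued numeric vectors of length `nrow(N)`;
#'   empty when `N` has full row rank.
#' @export
#' @examples
#' left_nullspace(matrix(c(-1, 1), 2, 1)) # A -> B conserves A + B
left_nullspace <- function(N) {
  r <- rref_rational(t(as.matrix(N)))
  s <- nrow(as.matrix(N))
  free <- setdiff(seq_len(s), r$pivots)
  lapply(free, function(j) {
    w <- numeric(s)
    w[j] <- 1
    if (r$rank > 0) {
      cn <- r$RD_rat$num[, j]; cd <- r$RD_rat$den[, j]
      l <- 1
      for (d in cd) l <- l / int_gcd(l, d) * d # lcm of denominators
      w <- w * l
      w[r$pivots] <- w[r$pivots] - cn * (l / cd)
    }
    g <- poly_content(w)
    w <- w / g
    fz <- which(w != 0)[1L]
    if (!is.na(fz) && w[fz] < 0) w <- -w
    w
  })
}
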