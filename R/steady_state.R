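# The steady-state (AD) system and its solution by lexicographic elimination.
#
# Steady states solve N v(k,x) = 0 inside one stoichiometric compatibility
# class. Multiplying by the RREF reduction RD of N preserves the solution
# set (RD has the same row space as N), giving rank(N) independent equations;
# the conservation relations w.x = T complete a square system, here called
# the AD system. A lexicographic Groebner basis of AD is echelon-shaped:
# its first element involves only the retained variable(s) and symbolic
# parameters, and the remaining coordinates follow by back-substitution.

#' Build the steady-state (AD) polynomial system
#'
#' Assembles `{rows of RD %*% v(k, x)}` followed by the compatibility-class
#' equations `w.x - T`, over the lexicographic ring
#' `eliminated species > retained species > symbolic parameters`.
#' Numeric rate constants are substituted exactly (as rationals) before
#' elimination; totals and rate labels given as character names stay
#' symbolic, placed at the bottom of the order so one elimination can serve
#' a whole parameter scan.
#'
#' @param net a `reaction_network`.
#' @param k named vector/list of rate constants; numeric entries are
#'   substituted, character entries (or missing labels) remain symbolic.
#'   Character entries must equal their own label name.
#' @param totals one entry per conservation law: positive numeric, or a
#'   character name (e.g. `"et"`) to keep the total symbolic.
#' @param retain character vector of species to retain (eliminated last, so
#'   the first basis element is a polynomial in them alone); default the
#'   last species.
#' @param eliminate_order optional explicit order for the eliminated
#'   species; default alphabetical.
#' @return A `steady_state_system`: list with `equations` (list of
#'   `crnpoly`), `vars` (ring order), `retained`, `params` (symbolic
#'   parameter names), `net`, `analysis`, `k`, `totals`.
#' @export
#' @examples
#' net <- parse_network("A <-> B ; k1, k2")
#' sys <- build_ad_system(net, c(k1 = 1, k2 = 2), totals = list(3))
#' sapply(sys$equations, poly_to_string)
build_ad_system <- function(net, k, totals = list(), retain = NULL,
                            eliminate_order = NULL) {
  if (is.null(retain)) retain <- net$species[net$s]
  if (!all(retain %in% net$species))
    stop("retained species not in network: ",
         paste(setdiff(retain, net$species), collapse = ", "))
  an <- conservation_analysis(net)
  ncons <- length(an$conservation)
  totals <- as.list(totals)
  if (length(totals) != ncons)
    stop("network has ", ncons, " conservation law(s); got ",
         length(totals), " total(s)")

  k <- as.list(k)
  labs <- rate_labels(net)
  miss <- setdiff(labs, names(k))
  if (length(miss))
    stop("missing rate constant(s) for reaction(s): ",
         paste(miss, collapse = ", "))
  sym_k <- labs[vapply(k[labs], is.character, logical(1))]
  num_k <- setdiff(labs, sym_k)
  for (lb in num_k) if (!is.finite(k[[lb]]) || k[[lb]] <= 0)
    stop("rate constant ", lb, " must be positive")

  sym_totals <- unlist(Filter(is.character, totals))
  params <- c(sym_k, sym_totals)
  elim <- setdiff(net$species, retain)
  elim <- if (is.null(eliminate_order)) sort(elim) else {
    if (!setequal(eliminate_order, elim)) stop("eliminate_order must be a ",
      "permutation of the non-retained species")
    eliminate_order
  }
  vars <- c(elim, retain, params)

  # RD %*% v assembled with rational term coefficients (RD entry times the
  # numeric rate value) and cleared once per row by the lcm of the term
  # denominators, which stays small when denominators share factors
  k_rat <- lapply(k[num_k], as_rational)
  names(k_rat) <- num_k
  Yr <- reactant_exponents(net)
  rows <- lapply(seq_len(an$rank), function(i) {
    num <- numeric(0); den <- numeric(0)
    expo <- matrix(numeric(0), 0L, length(vars))
    for (j in seq_len(net$r)) {
      if (an$RD_rat$num[i, j] == 0) next
      cf <- list(num = an$RD_rat$num[i, j], den = an$RD_rat$den[i, j])
      lab <- net$reactions[[j]]$rate
      e <- numeric(length(vars))
      e[match(net$species, vars)] <- Yr[, j]
      if (lab %in% num_k) cf <- rat_mul(cf, k_rat[[lab]])
      else e[match(lab, vars)] <- 1
      num <- c(num, cf$num); den <- c(den, cf$den)
      expo <- rbind(expo, e)
    }
    L <- 1
    for (d in unique(den)) L <- L / int_gcd(L, d) * d
    poly_primitive(poly_new(num * (L / den), expo, vars))
  })
  cons_eqs <- conservation_equations(an, totals, vars = vars)
  structure(list(equations = c(rows, cons_eqs), vars = vars,
                 retained = retain, params = params, net = net,
                 analysis = an, k = k, totals = totals),
            class = "steady_state_system")
}

#' Lexicographic Groebner elimination of the AD system
#'
#' Runs the production Buchberger path on the AD equations under the
#' system's elimination order and identifies the first element: the basis
#' polynomial containing only retained variables and symbolic parameters.
#'
#' @param sys a `steady_state_system`.
#' @param max_pairs passed to [groebner_basis()].
#' @return A `triangular_basis`: list with `polys` (reduced lex basis,
#'   ascending leading monomials), `first_element`, `consistent` (FALSE when
#'   the basis is `{1}`, i.e. no steady state in the class), plus the
#'   system's `vars`, `retained`, `params`, `net`, `k`, `analysis`.
#' @export
groebner_elimination <- function(sys, max_pairs = 20000L) {
  basis <- groebner_basis(sys$equations, max_pairs = max_pairs)
  unit <- length(basis) == 1L && poly_total_degree(basis[[1L]]) == 0
  keepvars <- c(sys$retained, sys$params)
  first <- NULL
  if (!unit) {
    for (g in basis) {
      supp <- sys$vars[apply(g$expo, 2L, function(e) any(e > 0))]
      if (all(supp %in% keepvars)) { first <- g; break }
    }
  }
  structure(list(polys = basis, first_element = first, consistent = !unit,
                 vars = sys$vars, retained = sys$retained,
                 params = sys$params, net = sys$net, k = sys$k,
                 analysis = sys$analysis, equations = sys$equations),
            class = "triangular_basis")
}

#' @export
print.triangular_basis <- function(x, ...) {
  if (!x$consistent) {
    cat("inconsistent system: no steady state in this compatibility class\n")
    return(invisible(x))
  }
  cat("lex Groebner basis,", length(x$polys), "polynomials; order:",
      paste(x$vars, collapse = " > "), "\n")
  for (g in x$polys) cat("  ", poly_to_string(g), "\n")
  invisible(x)
}

# real roots of a univariate coefficient vector (constant term first):
# companion-matrix eigenvalues, one Newton polish step, spurious-imaginary
# filter and near-duplicate merging
poly_roots_real <- function(coefs, imag_tol = 1e-9) {
  mx <- max(abs(coefs))
  if (mx == 0) stop("degenerate (identically zero) polynomial")
  coefs <- coefs / mx
  while (length(coefs) > 1L && abs(coefs[length(coefs)]) < 1e-13)
    coefs <- coefs[-length(coefs)]
  d <- length(coefs) - 1L
  if (d <= 0L) return(numeric(0))
  if (d == 1L) return(-coefs[1L] / coefs[2L])
  monic <- coefs / coefs[d + 1L]
  Cm <- matrix(0, d, d)
  if (d > 1L) Cm[cbind(2:d, 1:(d - 1L))] <- 1
  Cm[, d] <- -monic[1:d]
  ev <- eigen(Cm, only.values = TRUE)$values
  f <- function(z) sum(coefs * z^(0:d))
  fp <- function(z) sum(coefs[-1L] * (1:d) * z^(0:(d - 1L)))
  ev <- vapply(ev, function(z) {
    dz <- fp(z)
    if (Mod(dz) > 1e-14) z - f(z) / dz else z
  }, complex(1))
  re <- Re(ev[abs(Im(ev)) <= imag_tol * (Mod(ev) + 1)])
  if (!length(re)) return(numeric(0))
  re <- sort(re)
  keep <- c(TRUE, diff(re) > 1e-8 * (abs(re[-length(re)]) + 1))
  re[keep]
}

# numeric (double) substitution for a set of variables, rescaled so the
# largest coefficient magnitude is 1; exact arithmetic stops at the
# elimination, all downstream solving is floating point
subst_values <- function(p, values) {
  for (nm in names(values)) {
    if (poly_degree(p, nm) > 0) p <- subst_numeric(p, nm, values[[nm]])
  }
  if (!poly_is_zero(p)) {
    m <- max(abs(p$coef))
    if (m > 0 && (m > 1e6 || m < 1e-6)) p$coef <- p$coef / m
  }
  p
}

#' Solve a triangular basis by back-substitution
#'
#' Substitutes numeric values for every symbolic parameter, then walks the
#' echelon basis from the retained variable upwards: at each variable the
#' lowest-degree introducing polynomial is solved for its real roots
#' (companion matrix + Newton polish) and the other polynomials act as
#' filters; branches with a non-real or negative coordinate are discarded.
#' Points on the boundary (a near-zero coordinate) are reported separately
#' from interior (strictly positive) steady states. Interior points are
#' Newton-polished on the full AD system and must pass [residual_check()].
#'
#' @param basis a `triangular_basis` from [groebner_elimination()].
#' @param param_values named list/vector of numeric values for
#'   `basis$params` (ignored entries allowed).
#' @param residual_tol acceptance threshold for the steady-state residual,
#'   relative to the largest reaction rate at the point.
#' @return list with `points` (list of `steady_state_point`: `x`, named
#'   concentrations; `residual`), `boundary` (points with a zero
#'   coordinate), `n` (number of interior positive steady states).
#' @export
solve_triangular <- function(basis, param_values = list(),
                             residual_tol = 1e-9) {
  if (!basis$consistent)
    return(list(points = list(), boundary = list(), n = 0L))
  param_values <- as.list(param_values)
  need <- setdiff(basis$params, names(param_values))
  if (length(need))
    stop("numeric value(s) required for parameter(s): ",
         paste(need, collapse = ", "))
  polys <- lapply(basis$polys, function(p)
    subst_values(p, param_values[basis$params]))
  polys <- Filter(Negate(poly_is_zero), polys)
  species_vars <- setdiff(basis$vars, basis$params)
  vidx <- match(species_vars, basis$vars)
  totals_num <- as.numeric(unlist(param_values[basis$params]))
  scale0 <- max(c(1, abs(totals_num)))
  pos_tol <- 1e-10 * scale0

  partial <- list(stats::setNames(numeric(0), character(0)))
  for (u in rev(seq_along(species_vars))) {
    uname <- species_vars[u]
    later <- species_vars[seq_along(species_vars) > u]
    intro <- Filter(function(p) {
      supp <- basis$vars[apply(p$expo, 2L, function(e) any(e > 0))]
      poly_degree(p, uname) > 0 && all(supp %in% c(uname, later))
    }, polys)
    if (!length(intro))
      stop("variable ", uname, " is not determined by the basis ",
           "(positive-dimensional solution set?)")
    nxt <- list()
    for (sol in partial) {
      uni <- lapply(intro, function(p) {
        q <- p
        for (nm in names(sol)) if (poly_degree(q, nm) > 0)
          q <- subst_numeric(q, nm, sol[[nm]])
        poly_univariate_coefs(q, uname)
      })
      degs <- vapply(uni, function(cf) {
        cf <- cf / max(abs(cf), 1e-300)
        d <- length(cf)
        while (d > 1L && abs(cf[d]) < 1e-13) d <- d - 1L
        d - 1L
      }, numeric(1))
      solvable <- which(degs > 0)
      if (!length(solvable)) next # all constraints degenerate at this branch
      pick <- solvable[which.min(degs[solvable])]
      roots <- poly_roots_real(uni[[pick]])
      for (rt in roots) {
        if (rt < -pos_tol) next
        ok <- TRUE
        for (j in seq_along(uni)) {
          if (j == pick) next
          cf <- uni[[j]]
          val <- sum(cf * rt^(seq_along(cf) - 1L))
          if (abs(val) > 1e-6 * max(abs(cf), 1)) { ok <- FALSE; break }
        }
        if (ok) nxt[[length(nxt) + 1L]] <- c(sol,
                                             stats::setNames(rt, uname))
      }
    }
    partial <- nxt
    if (!length(partial)) break
  }

  k_num <- basis$k
  for (pn in basis$params) if (pn %in% names(k_num)) k_num[[pn]] <-
    param_values[[pn]]
  points <- list(); boundary <- list()
  for (sol in partial) {
    x <- sol[basis$net$species]
    names(x) <- basis$net$species
    if (any(x <= pos_tol)) {
      boundary[[length(boundary) + 1L]] <-
        structure(list(x = pmax(x, 0), residual =
                         residual_check(basis$net, k_num, pmax(x, 0))),
                  class = "steady_state_point")
      next
    }
    x <- newton_polish(basis$equations, basis$vars, basis$net$species, x,
                       param_values)
    res <- residual_check(basis$net, k_num, x)
    rates <- abs(rate_eval(basis$net, k_num, x))
    if (res <= residual_tol * max(rates, 1)) {
      points[[length(points) + 1L]] <-
        structure(list(x = x, residual = res), class = "steady_state_point")
    }
  }
  # deduplicate points that met through different branches
  if (length(points) > 1L) {
    keep <- rep(TRUE, length(points))
    for (i in seq_along(points)) for (j in seq_len(i - 1L)) {
      if (keep[j] && max(abs(points[[i]]$x - points[[j]]$x)) <
            1e-7 * scale0) { keep[i] <- FALSE; break }
    }
    points <- points[keep]
  }
  ord <- order(vapply(points, function(p)
    p$x[basis$retained[1L]], numeric(1)))
  list(points = points[ord], boundary = boundary, n = length(points))
}

# plain double-precision substitution (used inside branch solving)
subst_numeric <- function(p, name, value) {
  j <- match(name, p$vars)
  e <- p$expo[, j]
  p$coef <- p$coef * value^e
  p$expo[, j] <- 0
  poly_normalize_num(p)
}

# like poly_normalize but without the exact-integer overflow guard
poly_normalize_num <- function(p) {
  if (length(p$coef) == 0L) return(p)
  key <- apply(p$expo, 1L, paste, collapse = ",")
  if (anyDuplicated(key)) {
    cs <- rowsum(p$coef, key, reorder = FALSE)
    keep <- !duplicated(key)
    p$expo <- p$expo[keep, , drop = FALSE]
    p$coef <- as.numeric(cs[match(key[keep], rownames(cs)), 1L])
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

# Newton refinement on the square AD system (doubles)
newton_polish <- function(equations, vars, species, x, param_values,
                          iters = 6L) {
  eqs <- lapply(equations, function(p) subst_values(p, param_values))
  J_polys <- lapply(eqs, function(p)
    lapply(species, function(s) poly_deriv(p, s)))
  vals <- unlist(param_values)
  for (it in seq_len(iters)) {
    env <- c(x, vals)
    Fv <- vapply(eqs, poly_eval, numeric(1), values = env)
    Jm <- t(vapply(J_polys, function(row)
      vapply(row, poly_eval, numeric(1), values = env), numeric(length(species))))
    step <- tryCatch(solve(Jm, Fv), error = function(e) NULL)
    if (is.null(step)) break
    xn <- x - stats::setNames(as.numeric(step), species)
    if (any(xn <= 0)) { xn <- pmax(xn, 1e-300) }
    if (max(abs(xn - x)) < 1e-14 * max(abs(x), 1)) { x <- xn; break }
    x <- xn
  }
  x
}

#' Steady-state residual
#'
#' Maximum absolute entry of `N %*% v(k, x)`, computed by direct numeric
#' evaluation of the mass-action rates — a path independent of the
#' polynomial elimination machinery.
#'
#' @param net a `reaction_network`.
#' @param k named numeric rate constants (complete).
#' @param x numeric concentration vector (species order or named).
#' @return numeric scalar.
#' @export
residual_check <- function(net, k, x) {
  if (!is.null(names(x))) x <- x[net$species]
  max(abs(rhs_eval(net, k, x)))
}

#' First basis element as univariate coefficients
#'
#' Convenience accessor: substitutes numeric parameter values into the first
#' basis element and returns its coefficient vector in the retained
#' variable (constant term first).
#'
#' @param basis a `triangular_basis` with a single retained variable.
#' @param param_values named numeric values for the symbolic parameters.
#' @return numeric coefficient vector.
#' @export
retained_polynomial <- function(basis, param_values = list()) {
  stopifnot(length(basis$retained) == 1L)
  if (is.null(basis$first_element))
    stop("no basis element in the retained variable alone")
  p <- subst_values(basis$first_element, as.list(param_values))
  poly_univariate_coefs(p, basis$retained)
}
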