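# Mass-action kinetics: symbolic rate vector, ODE right-hand side, Jacobian.
#
# Rate constants are ring variables placed below all species in the
# lexicographic order, so they can stay symbolic through elimination;
# numeric values are substituted exactly (as rationals) only when equations
# are assembled, or as doubles when evaluating. The rate of reaction j is
# v_j = k_j * prod_i x_i^{y_ij} with y_j the reactant complex vector, so the
# monomial degree equals the reactant complex's total stoichiometry (and a
# zero-complex reactant gives the constant rate k_j).

ring_vars <- function(net, extra = character(0))
  c(net$species, unique(rate_labels(net)), extra)

# reactant exponent matrix (s x r): column j = reactant complex vector of j
reactant_exponents <- function(net)
  matrix(vapply(net$reactions,
                function(rx) complex_vector(net, rx$reactant),
                numeric(net$s)),
         nrow = net$s)

#' Symbolic mass-action rate vector
#'
#' Entry j is the monomial `k_j * prod(x^y_j)` over the reactant complex
#' `y_j`. Rate labels are ring variables (placed after all species in the
#' lex order), so the vector is fully symbolic; numeric rate values are
#' substituted later, exactly, when steady-state equations are assembled.
#'
#' @param net a `reaction_network`.
#' @param vars optional ring (defaults to species then rate labels).
#' @return list of `r` `crnpoly` monomials in reaction order.
#' @export
#' @examples
#' v <- rate_vector(parse_network("A + B -> C ; k3"))
#' poly_to_string(v[[1]])
rate_vector <- function(net, vars = ring_vars(net)) {
  Yr <- reactant_exponents(net)
  lapply(seq_len(net$r), function(j) {
    e <- numeric(length(vars))
    e[match(net$species, vars)] <- Yr[, j]
    lab <- net$reactions[[j]]$rate
    e[match(lab, vars)] <- 1
    poly_new(1, matrix(e, 1L), vars)
  })
}

#' Mass-action ODE system for a reaction network
#'
#' Bundles the network with its symbolic rate vector `v`, right-hand side
#' `N %*% v`, and (lazily computed) Jacobian. Numeric rate constants, when
#' supplied, are checked for completeness and positivity but kept alongside
#' the symbolic forms.
#'
#' @param net a `reaction_network`.
#' @param k optional named numeric vector/list of rate-constant values; must
#'   cover every rate label it names with positive values. Labels left out
#'   remain symbolic.
#' @return A `mass_action_system`: list with `net`, `vars` (ring order:
#'   species, then rate labels), `v`, `rhs`, `k`.
#' @export
#' @examples
#' sys <- mass_action_system(parse_network("A -> B ; k1"), c(k1 = 2))
#' poly_to_string(sys$rhs[[1]])
mass_action_system <- function(net, k = NULL) {
  if (!is.null(k)) {
    k <- unlist(k)
    labs <- rate_labels(net)
    miss <- setdiff(names(k), labs)
    if (length(miss)) stop("unknown rate label(s): ",
                           paste(miss, collapse = ", "))
    if (any(k <= 0)) stop("rate constants must be positive: ",
                          paste(names(k)[k <= 0], collapse = ", "))
  }
  vars <- ring_vars(net)
  v <- rate_vector(net, vars)
  structure(list(net = net, vars = vars, v = v,
                 rhs = ode_rhs_polys(net, v, vars), k = k),
            class = "mass_action_system")
}

ode_rhs_polys <- function(net, v, vars) {
  N <- stoichiometric_matrix(net)
  lapply(seq_len(net$s), function(i) {
    acc <- poly_zero(vars)
    for (j in seq_len(net$r))
      if (N[i, j] != 0) acc <- poly_add(acc, poly_scale(v[[j]], N[i, j]))
    acc
  })
}

#' ODE right-hand side N %*% v
#'
#' @param system a `mass_action_system`.
#' @return list of `s` `crnpoly`, one per species, symbolic in species and
#'   rate labels.
#' @export
ode_rhs <- function(system) system$rhs

#' Right-hand side via the complex-matrix decomposition Y Ia K Phi
#'
#' Alternative construction of the same polynomials from the decomposition
#' N v = Y Ia K Phi(x): K is the r x c matrix with k_j at (j, reactant
#' complex of j) and Phi the vector of complex monomials. Agrees with
#' [ode_rhs()] symbolically; kept as an independent construction used for
#' cross-checks.
#'
#' @param net a `reaction_network`.
#' @return list of `s` `crnpoly`.
#' @export
kphi_rhs <- function(net) {
  vars <- ring_vars(net)
  # Phi: one monomial per complex
  phi <- lapply(seq_len(net$c), function(cj) {
    e <- numeric(length(vars))
    e[match(net$species, vars)] <- complex_vector(net, cj)
    poly_new(1, matrix(e, 1L), vars)
  })
  # K Phi: entry j = k_j * Phi[reactant complex of j]
  kphi <- lapply(seq_len(net$r), function(j) {
    lab <- net$reactions[[j]]$rate
    e <- numeric(length(vars)); e[match(lab, vars)] <- 1
    poly_mul(poly_new(1, matrix(e, 1L), vars),
             phi[[net$reactions[[j]]$reactant]])
  })
  YIa <- complex_matrix(net) %*% incidence_matrix(net)
  lapply(seq_len(net$s), function(i) {
    acc <- poly_zero(vars)
    for (j in seq_len(net$r))
      if (YIa[i, j] != 0) acc <- poly_add(acc, poly_scale(kphi[[j]], YIa[i, j]))
    acc
  })
}

#' Symbolic Jacobian of the mass-action right-hand side
#'
#' @param system a `mass_action_system`.
#' @return s x s matrix (as a list-of-rows) of `crnpoly`, entry (i, j) =
#'   d(rhs_i)/d(x_j).
#' @export
jacobian_polys <- function(system) {
  sp <- system$net$species
  lapply(system$rhs, function(f) lapply(sp, function(x) poly_deriv(f, x)))
}

#' Evaluate the Jacobian at a numeric point
#'
#' @param system a `mass_action_system` (numeric `k` required unless given
#'   here).
#' @param x named (or species-ordered) numeric concentration vector.
#' @param k named numeric rate constants; defaults to `system$k`.
#' @return s x s numeric matrix.
#' @export
jacobian_eval <- function(system, x, k = system$k) {
  net <- system$net
  if (is.null(names(x))) names(x) <- net$species
  kv <- unlist(k)[rate_labels(net)]
  if (any(is.na(kv))) stop("numeric values required for every rate constant")
  Yr <- reactant_exponents(net)
  N <- stoichiometric_matrix(net)
  J <- matrix(0, net$s, net$s, dimnames = list(net$species, net$species))
  xs <- x[net$species]
  for (j in seq_len(net$r)) {
    y <- Yr[, j]
    for (l in which(y > 0)) {
      e <- y; e[l] <- e[l] - 1
      dv <- kv[j] * y[l] * prod(xs^e)
      J[, l] <- J[, l] + N[, j] * dv
    }
  }
  J
}

# fast numeric rate vector / rhs used by integrators and residual checks;
# independent of the symbolic polynomial path
rate_eval <- function(net, k, x) {
  kv <- unlist(k)[rate_labels(net)]
  if (any(is.na(kv))) stop("numeric values required for every rate constant")
  Yr <- reactant_exponents(net)
  xs <- as.numeric(x)[seq_len(net$s)]
  kv * apply(Yr, 2L, function(y) prod(xs^y))
}

rhs_eval <- function(net, k, x)
  as.numeric(stoichiometric_matrix(net) %*% rate_eval(net, k, x))
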