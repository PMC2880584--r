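# Conservation analysis: rank, RREF of the stoichiometric matrix, left null
# space (conservation vectors), and stoichiometric compatibility classes.
# The dynamics are confined to parallel translates of the stoichiometric
# subspace T = span of the reaction vectors; each translate is selected by
# the totals w . x = T_i, one per conservation vector w.

#' Conservation analysis of a reaction network
#'
#' Computes, in exact rational arithmetic, the rank of the stoichiometric
#' matrix N, the nonzero rows RD of its reduced row echelon form, an integer
#' basis of the left null space (the conservation vectors w with
#' \eqn{w^T N = 0}), and an orthonormal basis of the stoichiometric subspace.
#'
#' @param net a `reaction_network`.
#' @return A `conservation_analysis`: list with `N`, `rank`, `RD`, `RD_rat`
#'   (exact num/den form), `pivots`, `conservation` (list of integer
#'   vectors, length `s - rank`), `subspace_basis` (s x rank orthonormal
#'   matrix spanning T).
#' @export
#' @examples
#' an <- conservation_analysis(parse_network("A -> B ; k1"))
#' an$rank; an$conservation
conservation_analysis <- function(net) {
  N <- stoichiometric_matrix(net)
  rr <- rref_rational(N)
  cons <- left_nullspace(N)
  B <- if (rr$rank > 0) qr.Q(qr(N))[, seq_len(rr$rank), drop = FALSE]
       else matrix(0, net$s, 0L)
  structure(list(net = net, N = N, rank = rr$rank, RD = rr$RD,
                 RD_rat = rr$RD_rat, pivots = rr$pivots,
                 conservation = cons, subspace_basis = B),
            class = "conservation_analysis")
}

#' @export
print.conservation_analysis <- function(x, ...) {
  cat("rank(N) =", x$rank, "; conservation laws:", length(x$conservation),
      "\n")
  for (w in x$conservation) {
    nz <- which(w != 0)
    cat("  ", paste(ifelse(w[nz] == 1, x$net$species[nz],
                           paste0(w[nz], "*", x$net$species[nz])),
                    collapse = " + "), "= const\n")
  }
  invisible(x)
}

#' Compatibility-class (conservation) equations
#'
#' Builds the affine polynomials `w . x - T`, one per conservation vector.
#' A total may be numeric (fixed class) or a character name, which becomes a
#' symbolic ring variable placed below all species in the lex order so a
#' single elimination can serve a whole bifurcation scan.
#'
#' @param analysis a `conservation_analysis`.
#' @param totals list/vector with one entry per conservation vector, numeric
#'   or character (symbolic name). Named entries are matched to conservation
#'   vectors by index names `"T1"`, `"T2"`, ...; unnamed entries are taken in
#'   order.
#' @param vars ring variables; must contain all species and any symbolic
#'   total names.
#' @return list of `crnpoly`, one per conservation vector.
#' @export
conservation_equations <- function(analysis, totals,
                                   vars = ring_vars(analysis$net,
                                     extra = unlist(Filter(is.character,
                                                           as.list(totals))))) {
  ncons <- length(analysis$conservation)
  if (ncons == 0L) return(list())
  totals <- as.list(totals)
  if (!is.null(names(totals)) && any(names(totals) != ""))
    totals <- totals[order(match(names(totals),
                                 paste0("T", seq_len(ncons))))]
  if (length(totals) != ncons)
    stop("need one total per conservation vector; conservation vectors: ",
         paste(vapply(analysis$conservation, paste, character(1),
                      collapse = ","), collapse = " ; "))
  sp <- analysis$net$species
  lapply(seq_len(ncons), function(i) {
    w <- analysis$conservation[[i]]
    nz <- which(w != 0)
    expo <- matrix(0, length(nz), length(vars))
    expo[cbind(seq_along(nz), match(sp[nz], vars))] <- 1
    p <- poly_new(w[nz], expo, vars)
    ti <- totals[[i]]
    if (is.character(ti)) {
      poly_sub(p, poly_var(ti, vars))
    } else {
      if (!is.finite(ti) || ti <= 0)
        stop("total for conservation vector ", i, " must be positive")
      r <- as_rational(ti)
      # clear the rational total: den*(w.x) - num, a positive scaling
      poly_sub(poly_scale(p, r$den), poly_const(r$num, vars))
    }
  })
}

#' Conserved totals along a trajectory
#'
#' Utility used to verify that each `w . x(t)` stays constant along
#' integrated trajectories.
#'
#' @param analysis a `conservation_analysis`.
#' @param x numeric matrix (rows = time points, columns = species) or vector.
#' @return matrix (or vector) of totals, one column per conservation vector.
#' @export
conserved_totals <- function(analysis, x) {
  W <- do.call(cbind, analysis$conservation)
  if (is.null(W)) return(NULL)
  if (is.null(dim(x))) as.numeric(x %*% W) else x %*% W
}
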