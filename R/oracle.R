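# Textbook Buchberger oracle over the rationals, used only to cross-validate
# the production Groebner path on small systems. Deliberately naive and
# arithmetically independent: monic polynomials with explicit num/den
# coefficient pairs, all S-pairs processed with no selection strategy or
# pair criteria, plain division-algorithm reduction.

rp_norm <- function(p) {
  if (!length(p$num)) return(p)
  key <- apply(p$expo, 1L, paste, collapse = ",")
  if (anyDuplicated(key)) {
    ord <- order(key)
    p$num <- p$num[ord]; p$den <- p$den[ord]
    p$expo <- p$expo[ord, , drop = FALSE]
    key <- key[ord]
    i <- 1L
    while (i < length(p$num)) {
      if (key[i] == key[i + 1L]) {
        s <- rat_add(list(num = p$num[i], den = p$den[i]),
                     list(num = p$num[i + 1L], den = p$den[i + 1L]))
        p$num[i] <- s$num; p$den[i] <- s$den
        p$num <- p$num[-(i + 1L)]; p$den <- p$den[-(i + 1L)]
        p$expo <- p$expo[-(i + 1L), , drop = FALSE]
        key <- key[-(i + 1L)]
      } else i <- i + 1L
    }
  }
  nz <- p$num != 0
  p$num <- p$num[nz]; p$den <- p$den[nz]
  p$expo <- p$expo[nz, , drop = FALSE]
  if (length(p$num) > 1L) {
    ord <- do.call(order, c(lapply(seq_len(ncol(p$expo)),
                                   function(j) p$expo[, j]),
                            list(decreasing = TRUE)))
    p$num <- p$num[ord]; p$den <- p$den[ord]
    p$expo <- p$expo[ord, , drop = FALSE]
  }
  p
}

rp_from_crnpoly <- function(p)
  rp_norm(list(num = p$coef, den = rep(1, length(p$coef)), expo = p$expo,
               vars = p$vars))

rp_is_zero <- function(p) length(p$num) == 0L

rp_monic <- function(p) {
  if (rp_is_zero(p)) return(p)
  lc <- list(num = p$num[1L], den = p$den[1L])
  for (i in seq_along(p$num)) {
    e <- rat_div(list(num = p$num[i], den = p$den[i]), lc)
    p$num[i] <- e$num; p$den[i] <- e$den
  }
  p
}

# p - coef * x^mono * g
rp_submul <- function(p, coef, mono, g) {
  n2 <- length(g$num)
  num <- c(p$num, numeric(n2)); den <- c(p$den, rep(1, n2))
  for (i in seq_len(n2)) {
    e <- rat_mul(coef, list(num = -g$num[i], den = g$den[i]))
    num[length(p$num) + i] <- e$num; den[length(p$num) + i] <- e$den
  }
  expo <- rbind(p$expo, g$expo + rep(mono, each = n2))
  rp_norm(list(num = num, den = den, expo = expo, vars = p$vars))
}

rp_reduce <- function(p, G) {
  rem <- list(num = numeric(0), den = numeric(0),
              expo = p$expo[0, , drop = FALSE], vars = p$vars)
  while (!rp_is_zero(p)) {
    lp <- p$expo[1L, ]
    red <- NULL
    for (g in G) if (all(g$expo[1L, ] <= lp)) { red <- g; break }
    if (is.null(red)) {
      rem$num <- c(rem$num, p$num[1L]); rem$den <- c(rem$den, p$den[1L])
      rem$expo <- rbind(rem$expo, lp)
      p$num <- p$num[-1L]; p$den <- p$den[-1L]
      p$expo <- p$expo[-1L, , drop = FALSE]
    } else {
      c0 <- rat_div(list(num = p$num[1L], den = p$den[1L]),
                    list(num = red$num[1L], den = red$den[1L]))
      p <- rp_submul(p, c0, lp - red$expo[1L, ], red)
    }
  }
  rp_norm(rem)
}

rp_spoly <- function(f, g) {
  l <- pmax(f$expo[1L, ], g$expo[1L, ])
  f1 <- rp_submul(list(num = numeric(0), den = numeric(0),
                       expo = f$expo[0, , drop = FALSE], vars = f$vars),
                  list(num = -1, den = 1), l - f$expo[1L, ], rp_monic(f))
  rp_submul(f1, list(num = 1, den = 1), l - g$expo[1L, ], rp_monic(g))
}

#' Textbook Buchberger oracle (small systems only)
#'
#' Plain Buchberger over the rationals with lexicographic order: every
#' S-pair is reduced with the division algorithm until the pair set is
#' exhausted, then the basis is minimalized and fully inter-reduced. Scope
#' is restricted to at most 3 effective variables and total degree 4; the
#' oracle exists to cross-validate [groebner_basis()] in tests, not to be
#' fast.
#'
#' @param polys list of `crnpoly` over a common ring.
#' @return reduced Groebner basis as a list of `crnpoly` (primitive integer
#'   form, positive leading coefficients), sorted as in [groebner_basis()].
#' @export
buchberger_oracle <- function(polys) {
  vars <- polys[[1L]]$vars
  used <- rep(FALSE, length(vars))
  for (p in polys) {
    stopifnot(identical(p$vars, vars))
    if (!poly_is_zero(p)) used <- used | apply(p$expo, 2L, function(e) any(e > 0))
    if (poly_total_degree(p) > 4)
      stop("oracle scope exceeded: total degree > 4", call. = FALSE)
  }
  if (sum(used) > 3L)
    stop("oracle scope exceeded: more than 3 variables", call. = FALSE)
  G <- Filter(Negate(rp_is_zero), lapply(polys, rp_from_crnpoly))
  if (!length(G)) stop("all input polynomials are zero")
  queue <- list()
  for (i in seq_along(G)) for (j in seq_along(G)) if (i < j)
    queue[[length(queue) + 1L]] <- c(i, j)
  while (length(queue)) {
    ij <- queue[[1L]]; queue[[1L]] <- NULL
    s <- rp_reduce(rp_spoly(G[[ij[1L]]], G[[ij[2L]]]), G)
    if (rp_is_zero(s)) next
    if (all(s$expo[1L, ] == 0)) { # unit: inconsistent system
      G <- list(rp_norm(list(num = 1, den = 1,
                             expo = matrix(0, 1L, length(vars)),
                             vars = vars)))
      break
    }
    G[[length(G) + 1L]] <- s
    for (i in seq_len(length(G) - 1L))
      queue[[length(queue) + 1L]] <- c(i, length(G))
  }
  # minimalize
  keep <- rep(TRUE, length(G))
  for (i in seq_along(G)) for (j in seq_along(G)) {
    if (i == j || !keep[j]) next
    if (keep[i] && all(G[[j]]$expo[1L, ] <= G[[i]]$expo[1L, ])) {
      keep[i] <- FALSE; break
    }
  }
  G <- G[keep]
  # full inter-reduction to the unique reduced basis
  repeat {
    changed <- FALSE
    for (i in seq_along(G)) {
      r <- rp_reduce(G[[i]], G[-i])
      if (!isTRUE(all.equal(r$num / r$den, G[[i]]$num / G[[i]]$den)) ||
          nrow(r$expo) != nrow(G[[i]]$expo) || any(r$expo != G[[i]]$expo)) {
        changed <- TRUE
        if (rp_is_zero(r)) { G <- G[-i] } else G[[i]] <- r
        break
      }
    }
    if (!changed) break
  }
  # convert to primitive integer crnpoly form for comparison
  out <- lapply(G, function(g) {
    l <- 1
    for (d in g$den) l <- l / int_gcd(l, d) * d
    poly_primitive(poly_new(g$num * (l / g$den), g$expo, vars))
  })
  lm <- do.call(rbind, lapply(out, lead_expo))
  ord <- do.call(order, lapply(seq_along(vars), function(j) lm[, j]))
  out[ord]
}
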