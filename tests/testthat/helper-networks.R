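# Shared fixtures and independent numeric oracles used across the suite.

toy_ab <- function() parse_network("A <-> B ; k1, k2")

edelstein_text <- c("species: A B C",
                    "A <-> 2A ; k1, k2",
                    "A + B <-> C ; k3, k4",
                    "C <-> B ; k5, k6")

# classic round-valued parameterization used where exact rational
# cross-checks (oracle, closed forms) want small coefficients
edelstein_classic_k <- c(k1 = 8.5, k2 = 1, k3 = 1, k4 = 1, k5 = 1, k6 = 0.2)

# hand-derived retained-variable cubic for the Edelstein network after
# eliminating x3 = et - x2 and solving the second AD equation for x2:
# (k1 A - k2 A^2 - k5 et)(k3 A + k4 + k5 + k6) + (k5 + k6)(k4 + k5) et
edelstein_cubic_oracle <- function(k, et) {
  K <- k[["k4"]] + k[["k5"]] + k[["k6"]]
  c2 <- -k[["k2"]] * k[["k3"]]                                  # A^3
  c1 <- k[["k1"]] * k[["k3"]] - k[["k2"]] * K                   # A^2
  c0 <- k[["k1"]] * K - k[["k5"]] * et * k[["k3"]]              # A^1
  cc <- -k[["k5"]] * et * K +
    (k[["k5"]] + k[["k6"]]) * (k[["k4"]] + k[["k5"]]) * et      # A^0
  c(cc, c0, c1, c2)
}

# random integer-coefficient polynomial within the Buchberger-oracle scope
random_small_poly <- function(vars, max_terms = 3L, max_deg = 2L) {
  nt <- sample.int(max_terms, 1L)
  repeat {
    coef <- sample(c(-3:-1, 1:3), nt, replace = TRUE)
    expo <- matrix(sample(0:max_deg, nt * length(vars), replace = TRUE),
                   nt, length(vars))
    keep <- rowSums(expo) <= 4
    if (any(keep)) {
      p <- poly_new(coef[keep], expo[keep, , drop = FALSE], vars)
      if (!crnsteady:::poly_is_zero(p)) return(p)
    }
  }
}

# Independent multi-start root finder on the un-reduced steady-state system
# {N v(k, x) = 0} united with the conservation equations: damped
# Gauss-Newton least-squares iterations from log-uniform random starts,
# followed by positivity filtering and deduplication. Shares no code with
# the Groebner elimination path.
multistart_roots <- function(net, k, totals, n_starts = 80L, seed = 1L,
                             tol = 1e-10) {
  an <- conservation_analysis(net)
  N <- an$N
  W <- do.call(rbind, an$conservation)
  masys <- mass_action_system(net, k)
  Ffun <- function(x) {
    c(as.numeric(N %*% crnsteady:::rate_eval(net, k, x)),
      if (!is.null(W)) as.numeric(W %*% x) - unlist(totals))
  }
  Jfun <- function(x) {
    rbind(jacobian_eval(masys, stats::setNames(x, net$species)),
          W)
  }
  scale0 <- max(c(unlist(totals), 1))
  found <- list()
  set.seed(seed)
  for (s in seq_len(n_starts)) {
    x <- exp(stats::runif(net$s, log(1e-4), log(2))) * scale0
    for (it in 1:80) {
      Fv <- Ffun(x)
      if (max(abs(Fv)) < tol * scale0) break
      J <- Jfun(x)
      step <- tryCatch(qr.solve(J, Fv), error = function(e) NULL)
      if (is.null(step)) break
      lambda <- 1
      repeat {
        xn <- x - lambda * step
        if (all(xn > 0) || lambda < 1e-6) break
        lambda <- lambda / 2
      }
      if (any(xn <= 0)) break
      x <- xn
    }
    if (max(abs(Ffun(x))) < tol * scale0 && all(x > 1e-8 * scale0)) {
      dup <- any(vapply(found, function(y)
        max(abs(y - x)) < 1e-6 * scale0, logical(1)))
      if (!dup) found[[length(found) + 1L]] <- x
    }
  }
  found[order(vapply(found, function(x) x[1L], numeric(1)))]
}
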