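# Mass-action rate vectors, ODE right-hand side, Jacobian.

test_that("Edelstein rate vector is the hand-derived monomial list", {
  net <- parse_network(edelstein_text)
  v <- rate_vector(net)
  expect_equal(vapply(v, poly_to_string, character(1)),
               c("A*k1", "A^2*k2", "A*B*k3", "C*k4", "C*k5", "B*k6"))
})

test_that("a zero-complex reactant gives a constant rate", {
  net <- parse_network("0 -> C3 ; ks\nC3 -> 0 ; kd")
  v <- rate_vector(net)
  expect_equal(poly_to_string(v[[1]]), "ks")
  # at x = 0 every rate with a species factor vanishes
  expect_equal(unname(crnsteady:::rate_eval(net, c(ks = 2, kd = 3), 0)),
               c(2, 0))
})

test_that("Edelstein ODEs match the hand-derived right-hand side", {
  net <- parse_network(edelstein_text)
  sys <- mass_action_system(net)
  k <- edelstein_classic_k
  set.seed(31)
  for (i in 1:10) {
    x <- stats::setNames(stats::runif(3, 0.1, 3), c("A", "B", "C"))
    env <- c(x, k)
    rhs <- vapply(sys$rhs, poly_eval, numeric(1), values = env)
    A <- x["A"]; B <- x["B"]; C <- x["C"]
    expect_equal(unname(rhs[1]),
                 unname(k["k1"]*A - k["k2"]*A^2 - k["k3"]*A*B + k["k4"]*C),
                 tolerance = 1e-12)
    expect_equal(unname(rhs[2]),
                 unname(-k["k3"]*A*B + k["k4"]*C + k["k5"]*C - k["k6"]*B),
                 tolerance = 1e-12)
    expect_equal(unname(rhs[3]),
                 unname(k["k3"]*A*B - k["k4"]*C - k["k5"]*C + k["k6"]*B),
                 tolerance = 1e-12)
  }
})

test_that("N v equals the Y Ia K Phi decomposition symbolically", {
  nets <- list(parse_network(edelstein_text), apoptosis_network()$network,
               random_network(4, 6, seed = 5, n_conservation = 1)$network,
               random_network(3, 5, seed = 6, n_conservation = 0)$network)
  for (net in nets) {
    sys <- mass_action_system(net)
    alt <- kphi_rhs(net)
    for (i in seq_len(net$s))
      expect_true(crnsteady:::poly_is_zero(poly_sub(sys$rhs[[i]],
                                                    alt[[i]])))
  }
})

test_that("monomial degree equals the reactant total stoichiometry", {
  net <- apoptosis_network()$network
  v <- rate_vector(net)
  Yr <- crnsteady:::reactant_exponents(net)
  for (j in seq_len(net$r)) # +1 for the rate-label factor
    expect_equal(poly_total_degree(v[[j]]), sum(Yr[, j]) + 1)
})

test_that("conservation vectors annihilate rhs and Jacobian", {
  for (fx in list(edelstein_network(), apoptosis_network())) {
    net <- fx$network
    sys <- mass_action_system(net, fx$parameters)
    an <- conservation_analysis(net)
    set.seed(41)
    for (w in an$conservation) {
      comb <- Reduce(poly_add, Map(poly_scale, sys$rhs, w))
      expect_true(crnsteady:::poly_is_zero(comb))
      x <- stats::setNames(stats::runif(net$s, 0.1, 2), net$species)
      J <- jacobian_eval(sys, x)
      expect_lt(max(abs(w %*% J)), 1e-12 * max(abs(J)))
    }
  }
})

test_that("Jacobian entries match symbolic differentiation and finite diff", {
  net <- parse_network(edelstein_text)
  k <- edelstein_classic_k
  sys <- mass_action_system(net, k)
  x <- c(A = 0.7, B = 1.3, C = 0.4)
  J <- jacobian_eval(sys, x)
  # J[1,1] = k1 - 2 k2 A - k3 B
  expect_equal(J[1, 1],
               unname(k["k1"] - 2 * k["k2"] * x["A"] - k["k3"] * x["B"]))
  # against the symbolic matrix
  Jp <- jacobian_polys(sys)
  env <- c(x, k)
  for (i in 1:3) for (j in 1:3)
    expect_equal(J[i, j], poly_eval(Jp[[i]][[j]], env), tolerance = 1e-12)
  # against central differences of the numeric rhs
  h <- 1e-6
  for (j in 1:3) {
    up <- dn <- x
    up[j] <- x[j] + h; dn[j] <- x[j] - h
    fd <- (crnsteady:::rhs_eval(net, k, up) -
             crnsteady:::rhs_eval(net, k, dn)) / (2 * h)
    expect_equal(unname(J[, j]), fd, tolerance = 1e-6)
  }
})

test_that("invalid rate constants are rejected", {
  net <- toy_ab()
  expect_error(mass_action_system(net, c(k1 = 1, k2 = -2)), "positive")
  expect_error(mass_action_system(net, c(k1 = 1, bogus = 2)), "unknown")
  expect_error(build_ad_system(net, c(k1 = 1), totals = list(1)),
               "missing rate")
})
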