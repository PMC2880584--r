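# Exact rational RREF, left null space, compatibility classes.

test_that("RREF of simple matrices is canonical", {
  I3 <- diag(3)
  r <- rref_rational(I3)
  expect_equal(r$RD, I3)
  expect_equal(r$pivots, 1:3)
  # idempotence
  r2 <- rref_rational(r$RD)
  expect_equal(r2$RD, r$RD)
})

test_that("Edelstein N reduces to the two-row echelon form", {
  net <- parse_network(edelstein_text)
  r <- rref_rational(stoichiometric_matrix(net))
  expect_equal(r$rank, 2)
  expect_equal(unname(r$RD),
               rbind(c(1, -1, 0, 0, -1, 1),
                     c(0, 0, 1, -1, -1, 1)))
})

test_that("RREF preserves the null space of random rational matrices", {
  set.seed(51)
  for (i in 1:10) {
    M <- matrix(sample(-3:3, 12, replace = TRUE), 3, 4) / 2
    r <- rref_rational(M)
    # same solution sets: each matrix's rows lie in the other's row space
    expect_equal(qr(rbind(M, r$RD))$rank, qr(M)$rank)
    expect_equal(qr(M)$rank, r$rank)
  }
})

test_that("left null spaces of the worked examples are as derived", {
  expect_equal(left_nullspace(matrix(c(-1, 1), 2, 1)), list(c(1, 1)))
  net <- parse_network(edelstein_text)
  expect_equal(left_nullspace(stoichiometric_matrix(net)),
               list(c(0, 1, 1)))
  # apoptosis: total activated caspase 8 over free and complexed forms
  fx <- apoptosis_network()
  ns <- left_nullspace(stoichiometric_matrix(fx$network))
  expect_equal(length(ns), 1)
  expect_equal(ns[[1]], c(1, 0, 1, 0, 0, 1, 1))
})

test_that("rank + number of conservation laws = species count", {
  nets <- list(toy_ab(), parse_network(edelstein_text),
               apoptosis_network()$network)
  set.seed(61)
  for (i in 1:50) {
    s <- sample(3:6, 1)
    nc <- sample(0:min(2, s - 2), 1)
    nets[[length(nets) + 1L]] <-
      random_network(s, s + sample(1:3, 1), seed = 1000 + i,
                     n_conservation = nc)$network
  }
  for (net in nets) {
    an <- conservation_analysis(net)
    expect_equal(an$rank + length(an$conservation), net$s)
    N <- an$N
    for (w in an$conservation) {
      expect_true(all(w %*% N == 0))
      # normalized: integer entries, gcd 1, positive first nonzero
      expect_true(all(w == round(w)))
      expect_equal(crnsteady:::poly_content(w), 1)
      expect_gt(w[which(w != 0)[1]], 0)
    }
  }
})

test_that("conservation equations are the affine class constraints", {
  net <- parse_network(edelstein_text)
  an <- conservation_analysis(net)
  eqs <- conservation_equations(an, list("et"))
  expect_equal(length(eqs), 1)
  expect_equal(poly_to_string(eqs[[1]]), "B + C - et")
  eqs2 <- conservation_equations(an, list(2.5))
  expect_equal(poly_eval(eqs2[[1]],
                         c(A = 9, B = 1, C = 1.5,
                           stats::setNames(rep(1, 6),
                                           paste0("k", 1:6)))), 0)
  expect_error(conservation_equations(an, list()), "one total")
  # full-rank network: no equations
  net0 <- random_network(3, 5, seed = 6, n_conservation = 0)$network
  expect_equal(conservation_equations(conservation_analysis(net0),
                                      list()), list())
})

test_that("conserved totals stay constant along trajectories", {
  for (fx in list(edelstein_network(), apoptosis_network())) {
    masys <- mass_action_system(fx$network, fx$parameters)
    an <- conservation_analysis(fx$network)
    set.seed(71)
    x0 <- stats::setNames(stats::runif(fx$network$s, 0.5, 2),
                          fx$network$species)
    tr <- simulate_trajectory(masys, x0, t_end = 50)
    tots <- conserved_totals(an, tr[, -1, drop = FALSE])
    drift <- apply(tots, 2, function(col) max(abs(col - col[1])))
    expect_lt(max(drift), 1e-8 * max(abs(tots)))
  }
})
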