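# Jacobian-spectrum classification and integration cross-checks.

test_that("the reversible isomerization is stable with one conservation zero", {
  net <- toy_ab()
  sys <- mass_action_system(net, c(k1 = 1, k2 = 1))
  rep_ <- classify_steady_state(sys, c(A = 1, B = 1))
  expect_equal(rep_$label, "stable")
  expect_equal(length(rep_$eigenvalues), 2)
  expect_equal(length(rep_$reduced_eigenvalues), 1)
  expect_equal(Re(rep_$reduced_eigenvalues), -2, tolerance = 1e-12)
  expect_equal(rep_$n_zero, 1)
})

test_that("fixture steady states split 2 stable / 1 unstable in the window", {
  for (fx in list(edelstein_network(), apoptosis_network())) {
    tb <- groebner_elimination(build_ad_system(fx$network, fx$parameters,
                                               totals = list("et"),
                                               retain = fx$retain))
    sol <- solve_triangular(tb, list(et = fx$witness_total))
    expect_equal(sol$n, 3)
    sys <- mass_action_system(fx$network, fx$parameters)
    an <- conservation_analysis(fx$network)
    labels <- vapply(sol$points, function(p)
      classify_steady_state(sys, p, an)$label, character(1))
    # points are ordered by the retained coordinate: saddle in the middle
    expect_equal(labels, c("stable", "unstable", "stable"))
    for (p in sol$points) {
      rep_ <- classify_steady_state(sys, p, an)
      expect_equal(rep_$n_zero, fx$network$s - an$rank)
    }
  }
})

test_that("eigenvalue labels match integration fate", {
  for (fx in list(edelstein_network(), apoptosis_network())) {
    tb <- groebner_elimination(build_ad_system(fx$network, fx$parameters,
                                               totals = list("et"),
                                               retain = fx$retain))
    sol <- solve_triangular(tb, list(et = fx$witness_total))
    sys <- mass_action_system(fx$network, fx$parameters)
    for (p in sol$points)
      expect_true(confirm_stability(sys, p, t_end = 400))
  }
})

test_that("perturbed starts on either side of the saddle diverge", {
  fx <- edelstein_network()
  tb <- groebner_elimination(build_ad_system(fx$network, fx$parameters,
                                             totals = list("et"),
                                             retain = "A"))
  sol <- solve_triangular(tb, list(et = fx$witness_total))
  sys <- mass_action_system(fx$network, fx$parameters)
  saddle <- sol$points[[2]]$x
  lo <- sol$points[[1]]$x; hi <- sol$points[[3]]$x
  ends <- vapply(c(-1e-3, 1e-3), function(d) {
    x0 <- saddle; x0["A"] <- saddle["A"] * (1 + d)
    # keep the start inside the same compatibility class
    tr <- simulate_trajectory(sys, x0, t_end = 2000)
    tr[nrow(tr), "A"]
  }, numeric(1))
  expect_equal(unname(ends[1]), unname(lo["A"]), tolerance = 1e-3)
  expect_equal(unname(ends[2]), unname(hi["A"]), tolerance = 1e-3)
})

test_that("the reduced spectrum is invariant to the subspace basis choice", {
  fx <- edelstein_network()
  sys <- mass_action_system(fx$network, fx$parameters)
  an <- conservation_analysis(fx$network)
  tb <- groebner_elimination(build_ad_system(fx$network, fx$parameters,
                                             totals = list("et"),
                                             retain = "A"))
  p <- solve_triangular(tb, list(et = fx$witness_total))$points[[2]]
  J <- jacobian_eval(sys, p$x)
  B <- an$subspace_basis
  ev1 <- sort(Re(eigen(t(B) %*% J %*% B, only.values = TRUE)$values))
  set.seed(121)
  Q <- qr.Q(qr(matrix(stats::rnorm(ncol(B)^2), ncol(B)))) # random rotation
  B2 <- B %*% Q
  ev2 <- sort(Re(eigen(t(B2) %*% J %*% B2, only.values = TRUE)$values))
  expect_equal(ev1, ev2, tolerance = 1e-10)
})

test_that("simulate_trajectory validates inputs and stays put at rest", {
  fx <- edelstein_network()
  sys <- mass_action_system(fx$network, fx$parameters)
  expect_error(simulate_trajectory(sys, c(A = -1, B = 1, C = 1), 1),
               "non-negative")
  tb <- groebner_elimination(build_ad_system(fx$network, fx$parameters,
                                             totals = list("et"),
                                             retain = "A"))
  p <- solve_triangular(tb, list(et = fx$witness_total))$points[[1]]
  tr <- simulate_trajectory(sys, p$x, t_end = 100)
  expect_lt(max(abs(tr[nrow(tr), -1] - p$x)), 1e-6 * max(p$x))
})
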