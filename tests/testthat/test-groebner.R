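# Production Groebner elimination vs the textbook rational oracle, plus
# exact big-integer arithmetic in the compiled kernel.

test_that("compiled big-integer arithmetic matches R on exact doubles", {
  set.seed(81)
  for (i in 1:200) {
    a <- floor(stats::runif(1, -1e15, 1e15))
    b <- floor(stats::runif(1, 1, 1e9))
    r <- crnsteady:::cpp_bigint_selftest(sprintf("%.0f", a),
                                         sprintf("%.0f", b))$res
    expect_identical(as.numeric(r[1]), a + b)
    q <- as.numeric(r[4]); rem <- as.numeric(r[5])
    if (a >= 0) expect_identical(q * b + rem, a)
  }
  # beyond-double product verified via string identity
  p <- crnsteady:::cpp_bigint_selftest("123456789012345678901234567890",
                                       "987654321098765432109")$res
  expect_identical(as.character(p[2]),
                   "121932631137021795226076817523485749121223746380010")
})

test_that("textbook examples give the expected reduced bases", {
  vars <- c("x", "y")
  x <- poly_var("x", vars); y <- poly_var("y", vars)
  one <- poly_const(1, vars)
  # {x^2 - y, y - 1} -> {y - 1, x^2 - 1}
  b <- groebner_basis(list(poly_sub(poly_mul(x, x), y), poly_sub(y, one)))
  expect_equal(vapply(b, poly_to_string, character(1)),
               c("y - 1", "x^2 - 1"))
  # ideal membership collapse: {x^2 - 1, x - 1} -> {x - 1}
  b2 <- groebner_basis(list(poly_sub(poly_mul(x, x), one),
                            poly_sub(x, one)))
  expect_equal(vapply(b2, poly_to_string, character(1)), "x - 1")
  # already-triangular linear system {x - 1, y - x} -> {y - 1, x - 1}
  b3 <- groebner_basis(list(poly_sub(x, one), poly_sub(y, x)))
  expect_equal(vapply(b3, poly_to_string, character(1)),
               c("y - 1", "x - 1"))
  # the unit ideal stays {1}
  b4 <- buchberger_oracle(list(one))
  expect_equal(poly_to_string(b4[[1]]), "1")
})

test_that("production and oracle bases agree on random small systems", {
  set.seed(91)
  n_ok <- 0
  while (n_ok < 22) {
    nv <- sample(2:3, 1)
    vars <- c("x", "y", "z")[seq_len(nv)]
    polys <- lapply(seq_len(sample(2:3, 1)),
                    function(i) random_small_poly(vars))
    ob <- tryCatch(buchberger_oracle(polys), error = function(e) NULL)
    if (is.null(ob)) next # oracle overflow/scope on this draw
    pb <- groebner_basis(polys)
    expect_equal(length(pb), length(ob))
    for (i in seq_along(pb))
      expect_true(poly_equal_up_to_scale(pb[[i]], ob[[i]]))
    n_ok <- n_ok + 1
  }
})

test_that("the Edelstein AD system yields the same basis on both paths", {
  net <- parse_network(edelstein_text)
  sys <- build_ad_system(net, edelstein_classic_k, totals = list(30),
                         retain = "A")
  eqs <- lapply(sys$equations, crnsteady:::poly_change_ring,
                vars = c("B", "C", "A"))
  ob <- buchberger_oracle(eqs)
  pb <- groebner_basis(eqs)
  expect_equal(length(pb), length(ob))
  for (i in seq_along(pb))
    expect_true(poly_equal_up_to_scale(pb[[i]], ob[[i]]))
})

test_that("every input polynomial reduces to zero against its basis", {
  for (fx in list(edelstein_network(), apoptosis_network())) {
    sys <- build_ad_system(fx$network, fx$parameters,
                           totals = list(fx$witness_total),
                           retain = fx$retain)
    basis <- groebner_basis(sys$equations)
    for (p in sys$equations)
      expect_true(crnsteady:::poly_is_zero(reduce_mod_basis(p, basis)))
  }
})

test_that("oracle refuses inputs outside its scope", {
  vars <- c("w", "x", "y", "z")
  polys <- lapply(1:2, function(i) {
    poly_new(c(1, 1), rbind(c(1, 1, 1, 1), c(0, 0, 0, 0)), vars)
  })
  expect_error(buchberger_oracle(polys), "scope")
  big <- poly_new(1, matrix(c(5, 0), 1), c("x", "y"))
  expect_error(buchberger_oracle(list(big)), "scope")
})

test_that("inconsistent systems collapse to the unit ideal", {
  vars <- "x"
  x <- poly_var("x", vars)
  polys <- list(poly_sub(x, poly_const(1, vars)),
                poly_sub(x, poly_const(2, vars)))
  b <- groebner_basis(polys)
  expect_equal(length(b), 1)
  expect_equal(poly_total_degree(b[[1]]), 0)
  ob <- buchberger_oracle(polys)
  expect_equal(poly_to_string(ob[[1]]), "1")
})
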