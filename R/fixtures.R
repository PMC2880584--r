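# Bundled example networks and generators for test inputs.
#
# The Edelstein network (autocatalytic production of A, A <-> 2A, with
# enzymatic removal A + B <-> C <-> B) is the classic three-species
# bistable scheme. The apoptosis network models caspase-8-dependent
# activation of caspase 3 with inhibition by BAR; its reaction list is a
# documented reconstruction built to the stated constraints (seven species,
# fourteen mass-action reactions, conserved total of activated caspase 8
# across its free and complexed forms, a BAR degradation constant kd) — the
# original figure defining the exact list is not available, so the
# reconstruction is labelled as such. Each fixture ships with a rate set
# found by the seeded bistable-parameter search below, together with the
# seed and the witness value of the conserved total.

fixture_file <- function(...)
  system.file("extdata", ..., package = "crnsteady", mustWork = TRUE)

load_fixture <- function(crn, yaml_file) {
  net <- read_crn(fixture_file(crn))
  pars <- yaml::read_yaml(fixture_file(yaml_file))
  list(network = net,
       parameters = unlist(pars$rates),
       retain = pars$retain,
       window = unlist(pars$window),
       witness_total = pars$witness_total,
       search_seed = pars$search_seed,
       known = pars$known)
}

#' Bundled fixture networks
#'
#' `edelstein_network()`: 3 species, 5 complexes, 6 reactions, one
#' conservation law (B + C); `apoptosis_network()`: 7 species, 14
#' reactions, conserved total of activated caspase 8
#' (C8a + C8aC3 + C8aBAR + C8aC3BAR). Both records carry a rate-constant
#' set with a verified three-steady-state window in the conserved total,
#' found by [bistable_parameter_search()] with the stored seed.
#'
#' @return list with `network` (a `reaction_network`), `parameters` (named
#'   rate constants), `retain` (reporter species), `window` (lo/hi of the
#'   verified multistationarity window in the total), `witness_total` (a
#'   total inside it), `search_seed`, `known` (expected structural counts).
#' @export
edelstein_network <- function()
  load_fixture("edelstein.crn", "edelstein_params.yaml")

#' @rdname edelstein_network
#' @export
apoptosis_network <- function()
  load_fixture("apoptosis.crn", "apoptosis_params.yaml")

# complexes of total stoichiometry <= 2 over s species (as coefficient
# vectors), including the zero complex
all_small_complexes <- function(s) {
  out <- list(numeric(s))
  for (i in seq_len(s)) {
    e <- numeric(s); e[i] <- 1; out[[length(out) + 1L]] <- e
    e[i] <- 2; out[[length(out) + 1L]] <- e
  }
  if (s > 1L) for (i in seq_len(s - 1L)) for (j in (i + 1L):s) {
    e <- numeric(s); e[i] <- 1; e[j] <- 1
    out[[length(out) + 1L]] <- e
  }
  out
}

#' Seeded random mass-action network with planted conservation laws
#'
#' Draws reactant/product complexes of total stoichiometry at most 2 and
#' accepts a reaction only when every planted conservation vector `w`
#' annihilates its reaction vector (`w . (product - reactant) = 0`), so the
#' planted vectors lie in the left null space of N by construction. With
#' `n_conservation = 0`, resampling continues until N has full row rank.
#'
#' @param s number of species (>= 2).
#' @param r number of reactions (>= 1).
#' @param seed integer seed; identical seeds give identical networks.
#' @param n_conservation number of planted conservation laws (0 <= n < s).
#' @param max_tries attempts before giving up.
#' @return list with `network`, `planted` (list of planted integer
#'   vectors), `seed`.
#' @export
random_network <- function(s, r, seed, n_conservation = 1L,
                           max_tries = 2000L) {
  stopifnot(s >= 2L, r >= 1L, n_conservation >= 0L, n_conservation < s)
  withr::local_seed(seed)
  species <- paste0("X", seq_len(s))
  cxs <- all_small_complexes(s)
  for (attempt in seq_len(max_tries)) {
    planted <- lapply(seq_len(n_conservation), function(i) {
      w <- numeric(s)
      while (sum(w != 0) < 2L) w <- sample(0:2, s, replace = TRUE)
      w / poly_content(w)
    })
    # weight class of each complex under the planted vectors; a reaction
    # conserves every planted w iff its two complexes share a class
    wclass <- vapply(cxs, function(e)
      paste(vapply(planted, function(w) sum(w * e), numeric(1)),
            collapse = ","), character(1))
    sizes <- table(wclass)
    if (n_conservation > 0L &&
        sum(sizes * (sizes - 1)) < r) next # not enough distinct reactions
    eligible <- which(wclass %in% names(sizes)[sizes >= 2L] |
                        n_conservation == 0L)
    reactions <- list(); keys <- character(0)
    tries <- 0L
    while (length(reactions) < r && tries < max_tries) {
      tries <- tries + 1L
      li <- eligible[sample.int(length(eligible), 1L)]
      lhs <- cxs[[li]]
      ok <- which(wclass == wclass[li] | n_conservation == 0L)
      ok <- setdiff(ok, li)
      if (!length(ok)) next
      rhs <- cxs[[ok[sample.int(length(ok), 1L)]]]
      key <- paste(c(lhs, rhs), collapse = ",")
      if (key %in% keys) next
      keys <- c(keys, key)
      reactions[[length(reactions) + 1L]] <- list(lhs = lhs, rhs = rhs)
    }
    if (length(reactions) < r) next
    lines <- vapply(seq_len(r), function(j) {
      side <- function(e) {
        if (all(e == 0)) return("0")
        nz <- which(e > 0)
        paste(ifelse(e[nz] == 1, species[nz],
                     paste0(e[nz], species[nz])), collapse = " + ")
      }
      paste0(side(reactions[[j]]$lhs), " -> ", side(reactions[[j]]$rhs),
             " ; k", j)
    }, character(1))
    net <- parse_network(c(paste("species:", paste(species, collapse = " ")),
                           lines))
    rk <- rref_rational(stoichiometric_matrix(net))$rank
    if (n_conservation == 0L && rk < s) next
    if (n_conservation > 0L && rk > s - n_conservation) next
    return(list(network = net, planted = planted, seed = seed))
  }
  stop("could not satisfy the generation constraints in ", max_tries,
       " attempts")
}

#' Search for a rate-constant set with a three-steady-state window
#'
#' Seeded random search over log-uniform rate constants: for each draw the
#' AD system is eliminated once with the conserved total symbolic, and the
#' retained-variable polynomial's positive real roots are counted over a
#' log grid of the total (a cheap screen), and candidate totals are then
#' confirmed by full back-substitution, so an accepted draw has three
#' steady states with every coordinate positive. Absence of a find is not
#' a proof of monostationarity.
#'
#' @param net a `reaction_network` with at least one conservation law.
#' @param retained reporter species (single name).
#' @param seed integer seed.
#' @param n_draws search budget.
#' @param k_range range of the log-uniform draws: either a single `c(lo,
#'   hi)` used for every constant, or a named list of per-label ranges
#'   (labels left out use the default `c(0.01, 10)`) encoding mechanistic
#'   priors such as slow complex dissociation.
#' @param total_range range of scanned totals (log grid).
#' @param total_grid grid size for the total.
#' @return list with `k` (named rates), `witness_total`, `seed`, `draw`
#'   (index of the accepted draw); or `NULL` when the budget is exhausted.
#' @export
bistable_parameter_search <- function(net, retained, seed, n_draws = 200L,
                                      k_range = c(0.01, 10),
                                      total_range = c(0.1, 100),
                                      total_grid = 40L) {
  an <- conservation_analysis(net)
  if (!length(an$conservation)) stop("network has no conservation law")
  withr::local_seed(seed)
  labs <- unique(rate_labels(net))
  rng <- matrix(rep(c(0.01, 10), length(labs)), nrow = 2L,
                dimnames = list(NULL, labs))
  if (is.list(k_range)) {
    for (nm in names(k_range)) rng[, nm] <- k_range[[nm]]
  } else rng[] <- k_range
  ets <- exp(seq(log(total_range[1L]), log(total_range[2L]),
                 length.out = total_grid))
  for (d in seq_len(n_draws)) {
    k <- stats::setNames(
      signif(exp(stats::runif(length(labs), log(rng[1L, ]),
                              log(rng[2L, ]))), 2),
      labs)
    tb <- tryCatch({
      totals <- as.list(c("et", rep(1, length(an$conservation) - 1L)))
      groebner_elimination(build_ad_system(net, k, totals = totals,
                                           retain = retained))
    }, error = function(e) NULL)
    if (is.null(tb) || !tb$consistent || is.null(tb$first_element)) next
    for (et in ets) {
      cf <- tryCatch(retained_polynomial(tb, list(et = et)),
                     error = function(e) NULL)
      if (is.null(cf)) next
      rts <- tryCatch(poly_roots_real(cf), error = function(e) numeric(0))
      if (sum(rts > 1e-10 * et) < 3L) next
      n <- tryCatch(solve_triangular(tb, list(et = et))$n,
                    error = function(e) 0L)
      if (n >= 3L)
        return(list(k = k, witness_total = et, seed = seed, draw = d))
    }
  }
  NULL
}
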