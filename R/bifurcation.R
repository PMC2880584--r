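# Bifurcation scans over a conserved total or a rate constant.
#
# One symbolic elimination (the scanned quantity kept as the lowest lex
# variable) serves the whole scan: at each grid value the triangular basis
# is solved numerically, positive steady states are counted and classified,
# and the parameter values where the count changes (fold points) are
# refined by bisection on the count.

new_diagram <- function(parameter, grid, solver, net, k, retained) {
  pts <- lapply(grid, solver)
  counts <- vapply(pts, function(s) s$n, integer(1) + 0L)
  sys_num <- NULL
  branches <- do.call(rbind, lapply(seq_along(grid), function(i) {
    sol <- pts[[i]]
    if (!sol$n) return(NULL)
    data.frame(parameter = grid[i],
               value = vapply(sol$points, function(p) p$x[retained][[1L]],
                              numeric(1)),
               stability = vapply(sol$points, function(p) p$stability,
                                  character(1)))
  }))
  structure(list(parameter = parameter, grid = grid, counts = counts,
                 branches = branches, solutions = pts, solver = solver,
                 retained = retained, fold_points = numeric(0),
                 multistationarity_intervals = NULL),
            class = "bifurcation_diagram")
}

refine_folds <- function(diagram, max_iter = 60L) {
  grid <- diagram$grid; counts <- diagram$counts
  folds <- numeric(0)
  for (i in seq_len(length(grid) - 1L)) {
    if (counts[i] == counts[i + 1L]) next
    lo <- grid[i]; hi <- grid[i + 1L]
    clo <- counts[i]
    for (it in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      cm <- diagram$solver(mid)$n
      if (cm == clo) lo <- mid else hi <- mid
      if ((hi - lo) <= 1e-6 * max(abs(hi), 1e-12)) break
    }
    folds <- c(folds, (lo + hi) / 2)
  }
  diagram$fold_points <- folds
  diagram
}

#' Multistationarity intervals of a diagram
#'
#' Parameter ranges with two or more positive steady states, with endpoints
#' refined by bisection on the steady-state count to relative width 1e-6.
#'
#' @param diagram a `bifurcation_diagram`.
#' @return data.frame with columns `lo`, `hi` (empty when monostationary).
#' @export
multistationarity_interval <- function(diagram) {
  if (!length(diagram$fold_points)) diagram <- refine_folds(diagram)
  grid <- diagram$grid; counts <- diagram$counts
  edges <- sort(c(min(grid), diagram$fold_points, max(grid)))
  out <- NULL
  for (i in seq_len(length(edges) - 1L)) {
    mid <- (edges[i] + edges[i + 1L]) / 2
    if (diagram$solver(mid)$n >= 2L)
      out <- rbind(out, data.frame(lo = edges[i], hi = edges[i + 1L]))
  }
  # merge adjacent intervals sharing an endpoint
  if (!is.null(out) && nrow(out) > 1L) {
    merged <- out[1L, ]
    for (i in 2L:nrow(out)) {
      if (abs(out$lo[i] - merged$hi[nrow(merged)]) < 1e-9 * max(out$lo[i], 1))
        merged$hi[nrow(merged)] <- out$hi[i]
      else merged <- rbind(merged, out[i, ])
    }
    out <- merged
  }
  if (is.null(out)) data.frame(lo = numeric(0), hi = numeric(0)) else out
}

scan_grid <- function(lo, hi, n) {
  if (lo <= 0) seq(lo, hi, length.out = n)
  else if (hi / lo > 100) exp(seq(log(lo), log(hi), length.out = n))
  else seq(lo, hi, length.out = n)
}

attach_stability <- function(sol, masys, analysis) {
  sol$points <- lapply(sol$points, function(p) {
    p$stability <- classify_steady_state(masys, p, analysis)$label
    p
  })
  sol
}

#' Scan a conserved total
#'
#' Performs one Groebner elimination with the scanned total symbolic, then
#' solves and classifies steady states across the grid, recording counts,
#' branches, refined fold points and multistationarity intervals.
#'
#' @param net a `reaction_network` with at least one conservation law.
#' @param k complete named numeric rate constants.
#' @param retained species reported on the diagram's vertical axis.
#' @param lo,hi scan range for the total (positive).
#' @param grid number of grid points (log-spaced when the range spans more
#'   than two decades).
#' @param other_totals numeric values for the remaining conservation laws,
#'   in order, when the network has more than one.
#' @param scan_index which conservation law to scan (default 1).
#' @return A `bifurcation_diagram`: `grid`, `counts`, `branches`
#'   (data.frame: parameter, value, stability), `fold_points`,
#'   `multistationarity_intervals`, and per-grid `solutions`.
#' @export
scan_conserved_total <- function(net, k, retained, lo, hi, grid = 200L,
                                 other_totals = list(), scan_index = 1L) {
  an <- conservation_analysis(net)
  ncons <- length(an$conservation)
  if (ncons == 0L)
    stop("network has no conservation law; scan a rate constant instead ",
         "(scan_rate_constant)")
  totals <- as.list(rep(NA, ncons))
  others <- as.list(other_totals)
  ti <- 1L
  for (i in seq_len(ncons)) {
    if (i == scan_index) totals[[i]] <- "et"
    else { totals[[i]] <- others[[ti]]; ti <- ti + 1L }
  }
  sys <- build_ad_system(net, k, totals = totals, retain = retained)
  tb <- groebner_elimination(sys)
  masys <- mass_action_system(net, unlist(k))
  solver <- function(et)
    attach_stability(solve_triangular(tb, list(et = et)), masys, an)
  d <- new_diagram("et", scan_grid(lo, hi, grid), solver, net, k, retained)
  d$basis <- tb
  d <- refine_folds(d)
  d$multistationarity_intervals <- multistationarity_interval(d)
  d
}

#' Scan a rate constant
#'
#' Same contract as [scan_conserved_total()], with a rate constant kept
#' symbolic through the elimination and all conserved totals fixed.
#'
#' @param net a `reaction_network`.
#' @param k named numeric rate constants for all labels except the scanned
#'   one (a value for it, if present, is ignored).
#' @param label the scanned rate-constant label.
#' @param lo,hi scan range (positive).
#' @param totals numeric totals, one per conservation law.
#' @param retained species reported on the diagram.
#' @param grid number of grid points.
#' @return A `bifurcation_diagram`.
#' @export
scan_rate_constant <- function(net, k, label, lo, hi, totals, retained,
                               grid = 200L) {
  if (!label %in% rate_labels(net)) stop("unknown rate label: ", label)
  k <- as.list(k)
  k[[label]] <- label # keep symbolic
  an <- conservation_analysis(net)
  sys <- build_ad_system(net, k, totals = as.list(totals), retain = retained)
  tb <- groebner_elimination(sys)
  solver <- function(kval) {
    kk <- k; kk[[label]] <- kval
    masys <- mass_action_system(net, unlist(kk))
    pv <- stats::setNames(list(kval), label)
    attach_stability(solve_triangular(tb, pv), masys, an)
  }
  d <- new_diagram(label, scan_grid(lo, hi, grid), solver, net, k, retained)
  d$basis <- tb
  d <- refine_folds(d)
  d$multistationarity_intervals <- multistationarity_interval(d)
  d
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat("bifurcation scan of", x$parameter, "over [",
      signif(min(x$grid), 4), ",", signif(max(x$grid), 4), "],",
      length(x$grid), "points\n")
  cat("steady-state counts:", paste(rle(x$counts)$values, collapse = " -> "),
      "\n")
  if (length(x$fold_points))
    cat("fold points:", paste(signif(x$fold_points, 8), collapse = ", "),
        "\n")
  mi <- x$multistationarity_intervals
  if (!is.null(mi) && nrow(mi))
    for (i in seq_len(nrow(mi)))
      cat("multistationarity for", x$parameter, "in [",
          signif(mi$lo[i], 8), ",", signif(mi$hi[i], 8), "]\n")
  invisible(x)
}
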