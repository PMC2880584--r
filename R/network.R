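# Reaction-network representation and the .crn text dialect.
#
# A network is three ordered sets: species, complexes (the formal integer
# combinations of species on either side of a reaction arrow, including the
# zero complex "0" of open systems), and reactions. All matrix constructions
# (complex matrix Y, incidence matrix Ia, stoichiometric matrix N = Y %*% Ia)
# use these orders, so they are kept stable: first appearance in the file,
# with an optional "species:" header pinning the species numbering.

SPECIES_RX <- "[A-Za-z_][A-Za-z0-9_]*"

parse_complex_side <- function(txt, line_no) {
  txt <- trimws(txt)
  if (txt == "0") return(list())          # the zero complex
  if (grepl("^\\+|\\+$|\\+\\s*\\+", txt))
    stop("line ", line_no, ": malformed complex '", txt, "'", call. = FALSE)
  parts <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
  if (!length(parts) || any(parts == ""))
    stop("line ", line_no, ": malformed complex '", txt, "'", call. = FALSE)
  out <- list()
  for (p in parts) {
    m <- regmatches(p, regexec(paste0("^([0-9]*\\.?[0-9]*)\\s*(",
                                      SPECIES_RX, ")$"), p))[[1]]
    if (!length(m))
      stop("line ", line_no, ": cannot parse species term '", p, "'",
           call. = FALSE)
    coef <- if (m[2] == "") 1 else as.numeric(m[2])
    if (is.na(coef) || coef != round(coef) || coef <= 0)
      stop("line ", line_no, ": stoichiometric coefficient in '", p,
           "' must be a positive integer", call. = FALSE)
    sp <- m[3]
    out[[sp]] <- (if (is.null(out[[sp]])) 0 else out[[sp]]) + coef
  }
  out
}

complex_key <- function(cx) {
  if (!length(cx)) return("0")
  nm <- sort(names(cx))
  paste(paste0(unlist(cx[nm]), "*", nm), collapse = "+")
}

#' Parse a reaction network from .crn text
#'
#' The `.crn` dialect: one reaction per line, `"A + B -> C ; k3"`; reversible
#' arrows `"A <-> 2A ; k1, k2"` expand to a forward and a backward reaction
#' with the two rate labels in that order; `"0"` denotes the zero complex
#' (synthesis/degradation in open systems); integer stoichiometric
#' coefficients prefix species names (`"2A"` or `"2 A"`); `#` starts a
#' comment; an optional header `"species: A B C"` pins the species order
#' (otherwise first appearance).
#'
#' @param text character scalar (or vector of lines) with the network
#'   description.
#' @return A `reaction_network`: list with `species` (ordered names),
#'   `complexes` (list of named coefficient vectors, first-appearance order,
#'   deduplicated), `reactions` (list of `(reactant, product, rate)` with
#'   complex indices), and counts `s`, `c`, `r`.
#' @seealso [read_crn()], [complex_matrix()], [stoichiometric_matrix()]
#' @export
#' @examples
#' net <- parse_network("A <-> 2A ; k1, k2\nA + B <-> C ; k3, k4")
#' net$s; net$r
parse_network <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- sub("#.*$", "", lines)
  declared <- character(0)
  raw <- list() # (reactant complex, product complex, rate label, line no)
  labels_seen <- character(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (grepl("^species\\s*:", ln)) {
      declared <- strsplit(trimws(sub("^species\\s*:", "", ln)),
                           "[,[:space:]]+")[[1]]
      next
    }
    halves <- strsplit(ln, ";", fixed = TRUE)[[1]]
    if (length(halves) != 2L)
      stop("line ", i, ": expected '<reaction> ; <rate label(s)>'",
           call. = FALSE)
    labels <- trimws(strsplit(halves[2], ",", fixed = TRUE)[[1]])
    rev_arrow <- grepl("<->", halves[1], fixed = TRUE)
    sides <- trimws(strsplit(halves[1],
                             if (rev_arrow) "<->" else "->",
                             fixed = TRUE)[[1]])
    if (length(sides) != 2L)
      stop("line ", i, ": expected exactly one reaction arrow", call. = FALSE)
    n_lab <- if (rev_arrow) 2L else 1L
    if (length(labels) != n_lab || any(labels == ""))
      stop("line ", i, ": expected ", n_lab, " rate label(s)", call. = FALSE)
    lhs <- parse_complex_side(sides[1], i)
    rhs <- parse_complex_side(sides[2], i)
    if (identical(complex_key(lhs), complex_key(rhs)))
      stop("line ", i, ": null reaction (reactant equals product)",
           call. = FALSE)
    for (lb in labels) {
      if (lb %in% labels_seen)
        stop("line ", i, ": duplicate rate label '", lb, "'", call. = FALSE)
      labels_seen <- c(labels_seen, lb)
    }
    raw[[length(raw) + 1L]] <- list(lhs = lhs, rhs = rhs, rate = labels[1])
    if (rev_arrow)
      raw[[length(raw) + 1L]] <- list(lhs = rhs, rhs = lhs, rate = labels[2])
  }
  if (!length(raw)) stop("no reactions found", call. = FALSE)

  species <- declared
  for (rx in raw) for (nm in c(names(rx$lhs), names(rx$rhs)))
    if (!nm %in% species) species <- c(species, nm)

  complexes <- list(); keys <- character(0)
  cx_index <- function(cx) {
    k <- complex_key(cx)
    j <- match(k, keys)
    if (is.na(j)) {
      keys <<- c(keys, k)
      complexes[[length(complexes) + 1L]] <<- cx
      j <- length(complexes)
    }
    j
  }
  reactions <- lapply(raw, function(rx)
    list(reactant = cx_index(rx$lhs), product = cx_index(rx$rhs),
         rate = rx$rate))

  structure(list(species = species, complexes = complexes,
                 reactions = reactions, s = length(species),
                 c = length(complexes), r = length(reactions)),
            class = "reaction_network")
}

#' Read / write .crn files
#'
#' @param path file path.
#' @param net a `reaction_network`.
#' @return `read_crn`: a `reaction_network`. `write_crn`: `path`, invisibly.
#' @export
read_crn <- function(path) parse_network(readLines(path, warn = FALSE))

complex_to_string <- function(cx) {
  if (!length(cx)) return("0")
  paste(ifelse(unlist(cx) == 1, names(cx),
               paste0(unlist(cx), names(cx))), collapse = " + ")
}

#' @rdname read_crn
#' @export
write_crn <- function(net, path) {
  lines <- c(paste("species:", paste(net$species, collapse = " ")),
             vapply(net$reactions, function(rx)
               paste0(complex_to_string(net$complexes[[rx$reactant]]), " -> ",
                      complex_to_string(net$complexes[[rx$product]]), " ; ",
                      rx$rate), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("reaction network:", x$s, "species,", x$c, "complexes,", x$r,
      "reactions\n")
  cat("species:", paste(x$species, collapse = ", "), "\n")
  for (rx in x$reactions)
    cat(" ", complex_to_string(x$complexes[[rx$reactant]]), "->",
        complex_to_string(x$complexes[[rx$product]]), " [", rx$rate, "]\n")
  invisible(x)
}

complex_vector <- function(net, j) {
  y <- numeric(net$s)
  cx <- net$complexes[[j]]
  y[match(names(cx), net$species)] <- unlist(cx)
  y
}

#' Network matrices
#'
#' `complex_matrix` returns the species x complexes matrix Y whose columns
#' are the complex stoichiometric vectors; `incidence_matrix` the complexes x
#' reactions matrix Ia with -1 at each reaction's reactant complex and +1 at
#' its product complex; `stoichiometric_matrix` the species x reactions
#' matrix N of reaction vectors (product minus reactant complex), satisfying
#' the exact integer identity N = Y %*% Ia.
#'
#' @param net a `reaction_network`.
#' @return integer-valued numeric matrix with dimnames.
#' @export
#' @examples
#' net <- parse_network("A -> B ; k1")
#' stoichiometric_matrix(net)
complex_matrix <- function(net) {
  Y <- vapply(seq_len(net$c), function(j) complex_vector(net, j),
              numeric(net$s))
  Y <- matrix(Y, nrow = net$s)
  dimnames(Y) <- list(net$species,
                      vapply(net$complexes, complex_to_string, character(1)))
  Y
}

#' @rdname complex_matrix
#' @export
incidence_matrix <- function(net) {
  Ia <- matrix(0, net$c, net$r)
  for (j in seq_len(net$r)) {
    Ia[net$reactions[[j]]$reactant, j] <- -1
    Ia[net$reactions[[j]]$product, j] <- 1
  }
  dimnames(Ia) <- list(vapply(net$complexes, complex_to_string, character(1)),
                       vapply(net$reactions, `[[`, character(1), "rate"))
  Ia
}

#' @rdname complex_matrix
#' @export
stoichiometric_matrix <- function(net) {
  N <- complex_matrix(net) %*% incidence_matrix(net)
  dimnames(N) <- list(net$species,
                      vapply(net$reactions, `[[`, character(1), "rate"))
  N
}

rate_labels <- function(net) vapply(net$reactions, `[[`, character(1), "rate")
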