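Package: crnsteady
Title: Analytical Steady-State Detection for Mass-Action Reaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds the polynomial steady-state system of a mass-action
    chemical reaction network from a plain-text reaction list, reduces it
    through exact-rational row reduction and conservation analysis, solves it
    by lexicographic Groebner-basis elimination with triangular
    back-substitution, classifies the stability of every steady state from
    the Jacobian spectrum restricted to the stoichiometric subspace, and maps
    multistationarity regions over conserved totals or rate constants.
    Ships the Edelstein autocatalytic network and a receptor-induced
    apoptosis network as worked fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
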