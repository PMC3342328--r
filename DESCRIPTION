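Package: tissueratchet
Title: Stochastic and Mean-Field Models of DNA Repair Decline in Fast-Turnover Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates a population of rapidly proliferating cells whose
    per-cell DNA repair probability is degraded by a fixed amount with every
    unrepaired damage, while apoptosis and compensatory division keep the
    cell number constant. Provides exact stochastic engines for well-mixed
    and lattice-structured tissue, the mean-field theory of the metastable
    steady state (negative-binomial occupancy over mutation levels,
    steady-state mean repair rate, expected cell lifetime, linear
    stability), and replicated in-silico studies: persistence-time
    estimation, parameter sweeps, system-size scaling, and
    theory-versus-simulation distribution comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
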