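Package: persisterdyn
Title: Population Dynamics of Drug-Tolerant Persister States in Glioma Chemotherapy Resistance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how glioma cell populations acquire resistance
    to pulsed temozolomide (TMZ) chemotherapy. Implements and contrasts two
    population-dynamics frameworks: clonal selection of a pre-existing
    resistant subpopulation, and adaptive acquisition through an
    age-structured, non-proliferating drug-tolerant persister ("transient")
    state that matures into stable resistance. Includes an MGMT expression
    observation model, treatment-schedule simulation, multi-start weighted
    least-squares fitting with practical-identifiability analysis via fit
    ensembles, AICc-based model discrimination on time-course data, a
    stochastic (agent-based) and an Erlang-chain cross-check of the
    age-structured solver, and a synthetic-data generator emulating the
    longitudinal experimental design (viable-cell counts and MGMT
    fold-change at discrete days under repeated dosing).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
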