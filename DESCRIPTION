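Package: regnasedyn
Title: Dynamical Models of Regnase-1 and 14-3-3 Control of Inflammatory mRNA Decay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two competing ordinary-differential-equation models of
    stimulus-induced Regnase-1 regulation of inflammatory mRNAs (Il6,
    Zc3h12a), differing in whether 14-3-3-bound Regnase-1 retains
    ribonuclease activity. Provides closed-form equilibria with an
    existence condition, an independent numerical root-finding oracle,
    stiff time integration under a pulsed stimulation signal, a
    matched-free-protein discrimination procedure that contrasts the two
    models against the qualitative observation of equal target mRNA
    between wild-type and S513A knock-in genotypes, a seeded synthetic
    time-course generator emulating immunoblot and RT-qPCR observables,
    and log-scale least-squares parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
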