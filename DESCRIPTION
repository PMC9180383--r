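Package: bpthia
Title: Benefit-per-Ton Health Impact Assessment for Dioxin Emission Reductions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the benefit-per-ton (BPT) valuation chain for
    reductions in emissions of dioxin-like compounds: lifetime average
    daily dose (LADD) times a cancer slope factor gives excess cancer
    risk, which is propagated through population counts and a cancer
    mortality risk to expected deaths, monetized with age-specific
    values of a statistical life (VSL), and divided by emission masses
    to obtain per-gram benefits under policy and baseline emission
    trajectories. Ships a compiled Taiwan 2020-2070 scenario built
    from published Taiwan EPA dispersion-simulation outputs, National
    Development Council population projections and a hedonic-wage VSL
    study, plus a synthetic-scenario generator, scenario validation,
    one-at-a-time uncertainty sweeps, and CSV/YAML scenario bundles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    readr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
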