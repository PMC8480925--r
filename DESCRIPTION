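Package: mobalance
Title: Monte Carlo Molybdenum Mass Balance for Archean Ocean Redox
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Steady-state molybdenum (Mo) ocean mass balance with Monte
    Carlo exploration of the parameter space permitted by the
    Archean-Paleoproterozoic black-shale record. Candidate ocean states
    are filtered against per-period seawater delta98Mo windows and
    maximum authigenic Mo enrichments, yielding record-consistent
    minimum riverine Mo inputs. These are converted, through pyrite
    oxidation stoichiometry and the modern riverine Mo/S ratio, into
    minimum O2 consumption fluxes by terrestrial sulfide oxidation and,
    through a two-regime oxidative-weathering curve, into minimum
    equivalent atmospheric PO2. Includes a synthetic shale-record
    generator for end-to-end parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
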