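Package: catfa
Title: Dynamic Cerebral Autoregulation Analysis via Mx and Transfer Function Analysis
Version: 0.1.0
Authors@R:
    person("catfa", "developers", email = "catfa@example.org", role = c("aut", "cre"))
Description: Analysis of dynamic cerebral autoregulation from paired arterial
    blood pressure (ABP) and transcranial Doppler cerebral blood-flow velocity
    (CBFV) recordings. Implements time-domain variability (coefficient of
    variation, band spectral power), the Mx pressure-flow correlation index,
    and transfer function analysis (Welch cross-spectral coherence, gain and
    phase in the very-low and low frequency bands) with a Monte-Carlo
    critical-coherence reliability gate. Includes a synthetic ABP/CBFV
    generator emulating low-variability baseline recordings and bed-tilting
    interventions, cohort-level paired statistics, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
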