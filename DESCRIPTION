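Package: wolbsim
Title: Individual-Based Simulation of Wolbachia Dynamics in Haplodiploid Hosts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time, individual-based simulation of Wolbachia infection
    dynamics in haplodiploid host populations (spider-mite life history), covering
    the two haplodiploid outcomes of cytoplasmic incompatibility (female mortality
    and male development), additive polygenic host suppression of CI, sex-allocation
    distortion, imperfect maternal transmission and fecundity effects of infection.
    Includes the companion deterministic recursions for infection frequencies,
    closed-form persistence thresholds for sex-allocation distortion, an experiment
    harness (invasion surfaces, CI-type contrasts, multi-year coevolution,
    persistence-time and fecundity-threshold analyses) and a small command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
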