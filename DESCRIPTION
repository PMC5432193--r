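Package: ntalign
Title: Nucleotide-Time Alignment for DNA Polymerase Molecular Recorders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of DNA-polymerase "ticker tape" molecular
    recorders, which encode intracellular calcium activity as misincorporation
    errors along a growing DNA strand. Provides a generative model of
    calcium-dependent polymerase errors and pause/extension kinetics, a
    row-parallelizable dynamic-time-warping variant that assigns incorporation
    times to each nucleotide by aligning a binary error strand to time-indexed
    calcium templates under a kinetic lag prior, maximum-likelihood template
    selection over neural-tuning ensembles, and downstream inference of neural
    tuning (stimulus slope, cosine preferred direction) from the time-aligned
    record. Includes synthetic stimulus and center-out reaching generators and
    reproducible experiment harnesses for polymerase parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
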