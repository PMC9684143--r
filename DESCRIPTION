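Package: locfuse
Title: Bayesian Grouping of Single-Molecule Localizations into Emitters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the number, positions and per-emitter blinking statistics of
    fluorescent emitters from single-molecule localization microscopy (SMLM)
    coordinate lists. Localizations from repeated blinking/binding events are
    grouped by Reversible-Jump Markov chain Monte Carlo over the number of
    emitters, their positions and per-emitter linear drifts, the allocation of
    localizations to emitters, and the mean number of localizations per emitter,
    yielding emitter position estimates with precision improving roughly as one
    over the square root of the number of grouped events. Includes pre-analysis
    outlier filters, subregion tiling and stitching, posterior and most-probable-
    model (MAPN) images and coordinate tables, DNA-PAINT and dSTORM (three-state
    Gillespie kinetics) simulators with ground truth, Hungarian-matched Jaccard
    index and RMSE evaluation, spatial point statistics (nearest-neighbor
    distributions, Hopkins' statistic), and Monte-Carlo rigid alignment of
    recovered structures to templates for particle averaging.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
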