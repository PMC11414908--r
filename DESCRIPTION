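Package: packetcode
Title: Packet Information Encoding Analysis for EOD-Aligned Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Analysis pipeline for spike trains of electrosensory-lobe neurons
    of pulse-type electric fish, which emit discrete electric organ discharges
    (EODs) and encode each self-generated image as a packet of spike count and
    spike timing.  Provides EOD-aligned cross-correlation and post-EOD
    histograms with artifact blanking, unsupervised classification of units
    into firing-pattern types (Ward clustering of normalized post-EOD
    histograms with Davies-Bouldin cluster-count selection), ordinal-EOD
    step-response statistics (replicated Friedman tests, triad-pooled timing
    distributions, a Jensen-Shannon divergence battery with one-sided
    sign-rank inference), position-resolved receptive-field rate profiles,
    and a calibrated point-process simulator of six EOD-locked unit
    archetypes with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'packetcode-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'archetypes.R'
    'synthetic-data.R'
    'events-io.R'
    'histograms.R'
    'stats-core.R'
    'classification.R'
    'step-response.R'
    'receptive-field.R'
    'pipeline.R'
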