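Package: paleoniche
Title: Phyloclimatic Modelling of Bioclimatic Envelopes on Dated Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for phyloclimatic modelling: fitting min-max (Bioclim-style)
    climate envelopes to species occurrence records, evaluating single-variable
    models by ROC AUC against sampled background, excluding correlated climate
    variables in favour of the better-discriminating member of each pair,
    reconstructing ancestral envelope bounds at the nodes of a dated phylogeny
    by maximum-likelihood Brownian motion, projecting extant and ancestral
    envelopes into present-day and paleoclimate grids, and quantifying niche
    overlap (Schoener's D, Hellinger-based I) and its relationship to
    divergence time. Includes a synthetic-data generator that simulates trees,
    evolving envelopes, spatially autocorrelated climate scenarios and
    occurrence records with known ground truth, so that the whole pipeline can
    be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'ascii-grid.R'
    'geodata.R'
    'bioclim.R'
    'evaluation.R'
    'varselect.R'
    'phylo.R'
    'ancestral.R'
    'niche-stats.R'
    'synthetic.R'
    'pipeline.R'
    'data-fixtures.R'
    'paleoniche-package.R'
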