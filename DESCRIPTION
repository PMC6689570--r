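Package: fossilsignal
Title: Congruence of Morphological and Molecular Phylogenies and the
    Phylogenetic Signal of Fossils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the topological congruence between
    parsimony trees inferred from morphology and DNA character matrices
    and an independent, well-corroborated reference phylogeny.  Provides
    a Fitch parsimony engine for unordered multistate characters
    (equal and implied weighting, acctran/deltran ancestral-state
    reconstruction, synthesis of hypothetical-ancestor terminals from a
    reference topology), quartet and Robinson-Foulds congruence metrics,
    character-matrix handling for mixed morphology + molecular data with
    missing and inapplicable states, site- and taxon-resampling
    experiments (incremental addition of fossils, hypothetical ancestors
    or extant taxa), and an Mk-model simulator that generates data sets
    with morphology-only, short-branched fossil terminals alongside
    long-branched extant taxa.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape (>= 5.0),
    dplyr,
    generics,
    ggplot2,
    phangorn,
    phytools,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
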