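Package: lwiscan
Title: Composition and Conservation of Membrane-Protein Lipid-Water-Interface Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of the lipid-water-interface (LWI) belts of
    polytopic membrane proteins from multi-species sequence alignments.
    Anchors transmembrane (TM) topology on a reference sequence, derives the
    five-residue flank regions on either side of each TM helix, and computes
    region-wise amino-acid frequencies, hydrophobic/hydrophilic and charge
    group totals and ratios, Kyte-Doolittle hydropathy, comparisons against a
    proteome-average background, Kullback-Leibler enrichment/depletion logos,
    and pairwise p-distance conservation scores with bootstrap variances and
    chi-square independence tests, stratified by vertebrate phylum. Includes a
    star-phylogeny sequence-family simulator with planted region-specific
    substitution rates and stationary compositions for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ggplot2,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
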