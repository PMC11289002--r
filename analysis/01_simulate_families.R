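#!/usr/bin/env Rscript
# Simulate the three study families and write their input bundles.
#
# catsper_like   : the reference conditions — 5 vertebrate phyla x 10 species,
#                  6-TM architecture, TM rate 0.05 < LWI 0.20 < loop 0.30,
#                  aromatic-enriched Cys-free inner interface, long His-rich
#                  mammalian N-tails.
# null_uniform   : no planted structure (uniform compositions, equal rates).
# high_divergence: the same compositions near substitution saturation.

suppressPackageStartupMessages(library(lwiscan))

out_root <- "results/data"
for (name in c("catsper_like", "null_uniform", "high_divergence")) {
  fam <- make_fixture(name)
  paths <- write_family_bundle(fam, file.path(out_root, name))
  message(sprintf("%-15s -> %s  (%d sequences, width %d)",
                  name, dirname(paths[["alignment"]]),
                  length(fam$alignment$seq), alignment_width(fam$alignment)))
}
message("done: three input bundles under ", out_root)
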