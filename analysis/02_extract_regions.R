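#!/usr/bin/env Rscript
# Map the reference TM topology into alignment space and derive the twelve
# lipid-water-interface flanks (5 residues on each side of each TM helix).

suppressPackageStartupMessages(library(lwiscan))

bundle <- "results/data/catsper_like"
aln <- read_labeled_alignment(file.path(bundle, "alignment.fasta"),
                              file.path(bundle, "metadata.tsv"))
topo <- read_topology(file.path(bundle, "topology.yml"))
seg <- extract_segments(aln, topo)

tab <- segment_table(seg)
dir.create("results/regions", recursive = TRUE, showWarnings = FALSE)
write.table(tab, "results/regions/segments.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

n_flanks <- sum(tab$membrane_side %in% c("inner", "outer"))
message(sprintf("%d TM segments, %d LWI flanks (%d inner / %d outer)",
                sum(tab$membrane_side == "membrane"), n_flanks,
                sum(tab$membrane_side == "inner"),
                sum(tab$membrane_side == "outer")))
ov <- tab[tab$overlap_length > 0, ]
if (nrow(ov)) {
  message("overlapping flanks (short loops, residues counted for both): ",
          paste(sprintf("%s(%d)", ov$name, ov$overlap_length), collapse = ", "))
}
message(sprintf("pooled columns: LWI_total %d, LWI_inner %d, LWI_outer %d, TM_total %d",
                length(pooled_columns(seg, "LWI_total")),
                length(pooled_columns(seg, "LWI_inner")),
                length(pooled_columns(seg, "LWI_outer")),
                length(pooled_columns(seg, "TM_total"))))
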