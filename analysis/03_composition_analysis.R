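#!/usr/bin/env Rscript
# Regional amino-acid composition versus natural abundance: per-letter
# frequencies, enrichment/depletion calls, grouped hydrophobic/charge totals
# and ratios, and the mammalian N-tail histidine content.

suppressPackageStartupMessages(library(lwiscan))

bundle <- "results/data/catsper_like"
aln <- read_labeled_alignment(file.path(bundle, "alignment.fasta"),
                              file.path(bundle, "metadata.tsv"))
topo <- read_topology(file.path(bundle, "topology.yml"))
seg <- extract_segments(aln, topo)
bg <- load_background("swissprot")
dir.create("results/composition", recursive = TRUE, showWarnings = FALSE)

strata <- c("all", unique(aln$metadata$phylum))
regions <- c("LWI_total", "LWI_inner", "LWI_outer", "TM_total", names(seg$flanks))
profiles <- list()
for (st in strata) for (rg in regions) {
  profiles[[paste(rg, st)]] <- region_frequencies(aln, pooled_columns(seg, rg),
                                                  st, region_name = rg)
}
write.table(composition_table(profiles, bg),
            "results/composition/frequencies_vs_background.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

ratios <- do.call(rbind, lapply(profiles, function(p) {
  g <- grouped_profile(p)
  data.frame(region = p$region_name, stratum = p$stratum,
             hydrophobic = g$group_totals[["hydrophobic"]],
             positive_to_negative = g$ratios[["positive_to_negative"]],
             hydrophobic_to_hydrophilic = g$ratios[["hydrophobic_to_hydrophilic"]],
             mean_hydropathy = g$mean_hydropathy)
}))
write.table(ratios, "results/composition/group_ratios.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

inner <- compare_to_background(profiles[["LWI_inner all"]], bg)
message("inner LWI, all species pooled:")
message("  Phe frequency ", round(inner$observed[inner$letter == "F"], 3),
        " vs background ", inner$expected[inner$letter == "F"],
        " -> ", inner$direction[inner$letter == "F"])
message("  Cys direction: ", inner$direction[inner$letter == "C"])
message("  hydrophobic total ",
        round(ratios$hydrophobic[ratios$region == "LWI_inner" & ratios$stratum == "all"], 3))

his <- region_residue_content(aln, seq_len(min(pooled_columns(seg, "N-TM1")) - 1L),
                              "H", "mammal")
message(sprintf("mammal N-tail His content: mean %.3f (range %.3f-%.3f, n = %d)",
                his$summary$mean, his$summary$min, his$summary$max, his$summary$n))
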