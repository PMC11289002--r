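#!/usr/bin/env Rscript
# Kullback-Leibler enrichment/depletion logos of the LWI flanks against
# natural abundance, plus the null-fixture comparison.

suppressPackageStartupMessages(library(lwiscan))

bundle <- "results/data/catsper_like"
aln <- read_labeled_alignment(file.path(bundle, "alignment.fasta"),
                              file.path(bundle, "metadata.tsv"))
topo <- read_topology(file.path(bundle, "topology.yml"))
seg <- extract_segments(aln, topo)
bg <- load_background("swissprot")
dir.create("results/logos", recursive = TRUE, showWarnings = FALSE)

tabs <- lapply(c("LWI_inner", "LWI_outer", names(seg$flanks)), function(rg)
  logo_table(kl_logo(aln, pooled_columns(seg, rg), "all", bg, region_name = rg)))
heights <- do.call(rbind, tabs)
write.table(heights, "results/logos/logo_heights.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

inner_logo <- kl_logo(aln, pooled_columns(seg, "LWI_inner"), "all", bg,
                      region_name = "LWI_inner")
grDevices::pdf("results/logos/inner_lwi_logo.pdf", width = 10, height = 5)
print(plot_logo(inner_logo))
grDevices::dev.off()

message(sprintf("inner LWI: mean per-position KL %.2f bits over %d positions",
                mean(inner_logo$kl), length(inner_logo$kl)))
top <- apply(inner_logo$heights, 1, function(h) names(h)[which.max(h)])
message("top enriched letters along the inner interface: ",
        paste(top, collapse = ""))

null_fam <- make_fixture("null_uniform")
null_seg <- extract_segments(null_fam$alignment, null_fam$topology)
null_logo <- kl_logo(null_fam$alignment, pooled_columns(null_seg, "LWI_total"),
                     "all", load_background("uniform"))
message(sprintf("null fixture mean KL %.2f bits (pure sampling/ancestry noise)",
                mean(null_logo$kl)))
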