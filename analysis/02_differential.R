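#!/usr/bin/env Rscript
# Normalize raw intensities to log2 ppm abundances and run the per-region
# APEX2+ vs control differential abundance comparisons; summarize replicate
# reproducibility.

library(proxcomp)

data_dir <- "results/data"
out <- "results"
inp <- read_intensity_table(file.path(data_dir, "intensities.tsv"),
                            file.path(data_dir, "annotations.tsv"))
la <- normalize_log2(inp$matrix)

for (r in c("VM", "MFB", "STR", "STR_SYN")) {
  de <- differential(la,
                     samples_where(inp$annotations, r, "APEX2"),
                     samples_where(inp$annotations, r, "CONTROL"))
  write.table(de, file.path(out, sprintf("de_%s_apex2_vs_control.tsv",
                                         tolower(r))),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%-8s %4d enriched / %4d depleted (FDR < 0.05)", r,
                  count_enriched(de, 0.05, "up"),
                  count_enriched(de, 0.05, "down")))
}

for (r in c("VM", "STR")) {
  apex <- samples_where(inp$annotations, r, "APEX2")
  rc <- replicate_correlations(la, apex)
  off <- rc[upper.tri(rc)]
  message(sprintf("%-4s APEX2+ replicate Pearson r: %.3f-%.3f", r,
                  min(off), max(off)))
}
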