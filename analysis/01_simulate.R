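#!/usr/bin/env Rscript
# Generate the synthetic study: an APEX2 proximity-labeling proteomics
# experiment over VM / MFB / STR slices plus striatal synaptosomes, and a
# droplet scRNA-seq reference with planted DA-neuron markers. Ground truth
# is written alongside so every later stage can be scored.

library(proxcomp)

seed <- 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sim <- gen_proteomics(proteomics_sim_config(seed = seed))

# plant the scRNA markers on the genes of axon-biased shared proteins, so
# the marker-localization analysis has a planted answer to find
marker_genes <- sim$truth$gene_symbol[sim$truth$bias == "STR"][1:20]
gene_order <- c(marker_genes, setdiff(sim$truth$gene_symbol, marker_genes))
sc <- gen_scrnaseq(sc_sim_config(seed = seed), gene_names = gene_order)

write_intensity_table(sim$matrix, file.path(out, "intensities.tsv"),
                      annotations = sim$annotations,
                      annotation_path = file.path(out, "annotations.tsv"))
write.table(sim$truth, file.path(out, "proteomics_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_umi_mtx(sc$umi, file.path(out, "umi"))
write.table(sc$truth, file.path(out, "sc_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

det <- colSums(sim$matrix > 0)
message(sprintf("proteomics: %d protein groups x %d samples", nrow(sim$matrix),
                ncol(sim$matrix)))
message(sprintf("  detected per APEX2+ sample: %d-%d; per control: %d-%d",
                min(det[grep("APEX2", names(det))]),
                max(det[grep("APEX2", names(det))]),
                min(det[grep("CTRL", names(det))]),
                max(det[grep("CTRL", names(det))])))
message(sprintf("scRNA-seq: %d genes x %d cells; %d planted markers",
                nrow(sc$umi$counts), ncol(sc$umi$counts),
                sum(sc$truth$is_marker)))
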