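#!/usr/bin/env Rscript
# Cross-compartment synthesis: marker-protein localization, slice vs
# synaptosome concordance, sample PCA and z-score clustering over the
# filtered union proteome.

library(proxcomp)

out <- "results"
inp <- read_intensity_table("results/data/intensities.tsv",
                            "results/data/annotations.tsv")
la <- normalize_log2(inp$matrix)
union_ids <- readLines(file.path(out, "filtered_union.txt"))
de_vs <- read.delim(file.path(out, "de_vm_vs_str.tsv"))
markers <- read.delim(file.path(out, "marker_genes.tsv"))

loc <- classify_marker_localization(markers$gene, union_ids, de_vs)
write.table(loc, file.path(out, "marker_localization.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("marker proteins: %d of %d in the filtered proteome; %d striatal, %d VM, %d unbiased",
                sum(loc$present_in_filtered), nrow(loc),
                sum(loc$compartment %in% "STR_enriched"),
                sum(loc$compartment %in% "VM_enriched"),
                sum(loc$compartment %in% "unbiased")))

str_trail <- read.delim(file.path(out, "filter_trail_str.tsv"))
de_syn <- read.delim(file.path(out, "de_str_syn_apex2_vs_control.tsv"))
str_pass <- str_trail$protein_id[str_trail$pass_str]
conc <- concordance_synaptosome(
  str_pass, de_syn,
  means_slice = rowMeans(unclass(la)[, samples_where(inp$annotations, "STR", "APEX2")]),
  means_syn = rowMeans(unclass(la)[, samples_where(inp$annotations, "STR_SYN", "APEX2")]))
message(sprintf("synaptosome concordance: %d of %d slice-filtered proteins (log2FC > 0, FDR < 0.15); Pearson r = %.3f",
                conc$n_concordant, conc$n_reference, conc$pearson_r))

pca <- pca_samples(subset_proteins(la, union_ids))
message(sprintf("PCA over the %d-protein union: PC1 %.1f%%, PC2 %.1f%% of variance",
                length(union_ids), 100 * pca$variance_fraction[1],
                100 * pca$variance_fraction[2]))
coords <- data.frame(sample_id = rownames(pca$coordinates),
                     pc1 = pca$coordinates[, 1], pc2 = pca$coordinates[, 2])
write.table(coords, file.path(out, "pca_samples.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# z-score clustering of the shared proteins across APEX2+ replicates
apex <- samples_where(inp$annotations, c("VM", "STR"), "APEX2")
both_ids <- intersect(union_ids, de_vs$protein_id[de_vs$q < 0.05])
if (length(both_ids) >= 2) {
  zc <- zscore_cluster(unclass(la)[both_ids, apex])
  ord <- data.frame(protein_id = rownames(zc$z)[zc$row_order],
                    position = seq_along(zc$row_order))
  write.table(ord, file.path(out, "heatmap_row_order.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("clustered %d compartment-biased proteins across %d APEX2+ samples",
                  nrow(zc$z), ncol(zc$z)))
}
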