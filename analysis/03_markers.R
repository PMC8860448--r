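#!/usr/bin/env Rscript
# Single-cell support computations: UMI filtering, the DA-neuron expression
# bounds, subsampling-equalized specificity differential expression against
# the rest of the midbrain, and marker-gene selection (log2FC > 3, FDR < 0.01).

library(proxcomp)

seed <- 1L
data_dir <- "results/data"
out <- "results"

umi <- read_umi_mtx(file.path(data_dir, "umi/matrix.mtx"),
                    file.path(data_dir, "umi/genes.tsv"),
                    file.path(data_dir, "umi/barcodes.tsv"),
                    file.path(data_dir, "umi/labels.tsv"))
umi <- filter_cells_min_umi(umi, 500)
message(sprintf("%d cells retained after the UMI floor", ncol(umi$counts)))

da <- names(umi$cell_labels)[umi$cell_labels == "DA"]
rest <- setdiff(colnames(umi$counts), da)
message(sprintf("%d DA-neuron profiles vs %d other midbrain cells",
                length(da), length(rest)))

da_umi <- umi_matrix(umi$counts[, da], umi$cell_labels[da])
bounds <- expression_bounds(da_umi)
write.table(data.frame(gene = names(bounds$means), mean_log2 = bounds$means),
            file.path(out, "da_expression_means.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("expression bounds (log2 normalized): lower %.3f upper %.3f",
                bounds$lower, bounds$upper))
message(sprintf("%.1f%% of detected genes clear the lower bound",
                100 * mean(bounds$means > bounds$lower)))

spec <- subsampled_de(umi, da, rest, seed = seed)
write.table(spec, file.path(out, "specificity_da_vs_midbrain.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

markers <- select_markers(spec)
write.table(markers, file.path(out, "marker_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
truth <- read.delim(file.path(data_dir, "sc_truth.tsv"))
message(sprintf("%d marker genes selected; %d of %d planted markers recovered",
                nrow(markers),
                sum(truth$gene[truth$is_marker] %in% markers$gene),
                sum(truth$is_marker)))
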