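#!/usr/bin/env Rscript
# Apply the VM and striatum filtering cascades, combine them into the union
# partition, and derive the region-enriched sets that feed ontology analysis.

library(proxcomp)

out <- "results"
read_de <- function(r) read.delim(file.path(out,
  sprintf("de_%s_apex2_vs_control.tsv", r)))
de_vm <- read_de("vm"); de_mfb <- read_de("mfb"); de_str <- read_de("str")
spec <- read.delim(file.path(out, "specificity_da_vs_midbrain.tsv"))
em <- read.delim(file.path(out, "da_expression_means.tsv"))
expr <- setNames(em$mean_log2, em$gene)
bounds <- list(lower = mean(expr) - sd(expr), upper = mean(expr) + sd(expr))

cfg <- filter_config()
vm_trail <- filter_vm(de_vm, de_mfb, de_str, expr, spec, bounds, cfg)
str_trail <- filter_str(de_vm, de_mfb, de_str, expr, spec, NULL, bounds, cfg)
write.table(vm_trail, file.path(out, "filter_trail_vm.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(str_trail, file.path(out, "filter_trail_str.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

partition <- combine_union(vm_trail, str_trail)
message(sprintf("union partition: %d VM-only, %d Str-only, %d both (%d total)",
                partition$counts[["vm_only"]], partition$counts[["str_only"]],
                partition$counts[["both"]], partition$counts[["union"]]))

inp <- read_intensity_table("results/data/intensities.tsv",
                            "results/data/annotations.tsv")
la <- subset_proteins(normalize_log2(inp$matrix), partition$union)
de_vs <- differential(la,
                      samples_where(inp$annotations, "VM", "APEX2"),
                      samples_where(inp$annotations, "STR", "APEX2"))
write.table(de_vs, file.path(out, "de_vm_vs_str.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

rs <- region_enriched_sets(partition, de_vs)
message(sprintf("shared-set differential: %d VM-enriched, %d Str-enriched",
                rs$counts[["vm_enriched"]], rs$counts[["str_enriched"]]))
message(sprintf("ontology inputs: VM %d = %d + %d; Str %d = %d + %d",
                rs$counts[["vm_go_input"]], length(partition$vm_only),
                rs$counts[["vm_enriched"]],
                rs$counts[["str_go_input"]], length(partition$str_only),
                rs$counts[["str_enriched"]]))
writeLines(rs$vm_go_input, file.path(out, "vm_go_input.txt"))
writeLines(rs$str_go_input, file.path(out, "str_go_input.txt"))
writeLines(partition$union, file.path(out, "filtered_union.txt"))

truth <- read.delim("results/data/proteomics_truth.tsv")
planted <- truth$protein_id[grepl("VM|STR", truth$enriched_in)]
message(sprintf("planted-truth recovery of the cascade: sensitivity %.3f, FDR %.3f",
                length(intersect(partition$union, planted)) / length(planted),
                length(setdiff(partition$union, planted)) /
                  length(partition$union)))
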