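# proxcomp

Compartment-resolved analysis of APEX2 proximity-labeling proteomics, for
labs mapping the subcellular proteomes of genetically targeted neuron
populations. Midbrain dopaminergic neurons keep their somata and dendrites
in the ventral midbrain (VM) and project axons through the medial forebrain
bundle (MFB) into the striatum (STR); APEX2 labeling followed by regional
dissection and streptavidin pulldown therefore yields somatodendritic vs
axonal proteomes, each anchored by no-enzyme controls.

The package implements the full downstream pipeline:

- **Normalization** — raw LFQ intensities to log2 ppm abundances,
  `a_i = log2(X_i / ΣX_n × 10^6 + 1)`, zeros (non-detections) preserved.
- **Differential abundance** — Welch's unequal-variance *t*-test with
  Welch–Satterthwaite df and Benjamini–Hochberg FDR across proteins;
  "enriched" = `q < 0.05` and `log2FC > 0`.
- **Filtering cascades** — the multi-rule VM and striatum filters that
  combine APEX2 enrichment across regions with single-cell RNA-seq
  expression bounds (mean ± SD of per-gene mean log expression in DA
  neurons) and specificity evidence; every rule is materialized as a
  boolean column in an auditable filter trail.
- **Single-cell support** — UMI cell filtering, binomial expression
  specificity, subsampling-equalized differential expression (equal cell
  numbers, binomially thinned to equal mean depth, size-factor normalized,
  Mann–Whitney U with BH), and marker selection at `log2FC > 3`,
  `FDR < 0.01` (>8-fold specificity).
- **Integration** — marker-protein localization calls from the VM-vs-STR
  comparison, slice/synaptosome concordance (`log2FC > 0`, `FDR < 0.15`),
  replicate correlations, z-score average-linkage clustering, sample PCA.
- **ORA** — hypergeometric over-representation of GMT gene sets,
  `P(X ≥ k)` for `X ~ Hypergeom(N, K, n)`, BH across terms.
- **Synthetic data** — generators for the full proteomics design (4+4
  replicates per region, synaptosomes, log-normal intensities, logistic
  detection dropout, planted APEX2-specific and compartment-biased
  proteins) and for droplet UMI counts with planted ≥8-fold markers, both
  with ground-truth tables.

## Worked example

The `analysis/` scripts run the whole study on synthetic data
(`Rscript analysis/01_simulate.R` through `06_enrichment.R`), writing
tables under `results/`. Condensed, the same flow in R:

```r
library(proxcomp)

sim <- gen_proteomics(proteomics_sim_config(seed = 1))
sc  <- gen_scrnaseq(sc_sim_config(seed = 1))
res <- run_pipeline(sim$matrix, sim$annotations, sc$umi,
                    da_label = "DA", seed = 1, min_umi = 500)
res$report$partition_counts
#  vm_only str_only     both    union
#      162      195      337      694
res$report$regional_counts
#  vm_enriched str_enriched  vm_go_input str_go_input
#           89           91          251          286
```

Reading the report: of 694 proteins passing either cascade, 162 passed only
the somatodendritic (VM) filter, 195 only the axonal (STR) filter and 337
both; among the shared 337, 89 are significantly more abundant in VM and 91
in STR APEX2+ samples, so the ontology inputs are 251 = 162 + 89 VM genes
and 286 = 195 + 91 striatal genes — the additive decomposition holds by
construction. Against the planted truth this run recovers the enriched set
with sensitivity 0.913 at FDR 0.013, and 17 of 20 planted axon-biased
marker proteins are called striatal (the rest unbiased, none
somatodendritic).

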