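#' Run the full compartment-proteomics analysis
#'
#' Composes the pipeline end to end: total-intensity normalization,
#' per-region APEX2+ vs control differential abundance, single-cell support
#' computations (UMI cell filtering, label exclusion, expression bounds,
#' subsampling-equalized specificity DE, marker selection), the VM and
#' striatum filtering cascades with union combination, VM-vs-STR region
#' enrichment, marker localization classification, slice/synaptosome
#' concordance (when synaptosome samples are present), and optional gene-set
#' over-representation analysis of the two compartment inputs.
#'
#' @param intensity An `intensity_matrix`.
#' @param annotations Sample annotation data frame covering its columns.
#' @param umi A `umi_matrix` of reference (e.g. midbrain) cells containing
#'   the target population.
#' @param da_label Cell label of the target (DA-neuron) population in `umi`.
#' @param umi_str Optional second `umi_matrix` of striatal reference cells
#'   (same gene axis); when supplied, a second specificity comparison of the
#'   target population against these cells feeds the striatal cascade.
#' @param exclude_labels Cell labels dropped from `umi` before analysis
#'   (e.g. a contaminating astrocyte-like subcluster).
#' @param cfg A [filter_config()].
#' @param min_umi Per-cell UMI floor (default 1000).
#' @param marker_lfc,marker_q Marker-selection thresholds (default 3, 0.01).
#' @param concordance_q Synaptosome concordance FDR threshold (default 0.15).
#' @param q_enrich_counts FDR for the per-region enriched counts (0.05).
#' @param gene_sets Optional `gene_set_collection` for ORA of the VM and STR
#'   inputs.
#' @param seed Integer seed for all subsampling randomness.
#' @param outdir Optional directory; when given, stage outputs are written
#'   as TSVs.
#' @return A list with a `report` (thresholds, seed and counts at every
#'   stage) and the stage objects (`log_abundance`, `de`, `bounds`,
#'   `spec_mid`, `spec_str`, `markers`, `vm_trail`, `str_trail`,
#'   `partition`, `regional`, `localization`, `concordance`, `ora`).
#' @export
run_pipeline <- function(intensity, annotations, umi, da_label,
                         umi_str = NULL, exclude_labels = character(0L),
                         cfg = filter_config(), min_umi = 1000L,
                         marker_lfc = 3, marker_q = 0.01,
                         concordance_q = 0.15, q_enrich_counts = 0.05,
                         gene_sets = NULL, seed = 1L, outdir = NULL) {
  annotations <- validate_annotations(annotations)
  missing <- setdiff(colnames(intensity), annotations$sample_id)
  if (length(missing) > 0L) {
    stop("stage 'annotation join' failed for sample(s): ",
         paste(missing, collapse = ", "))
  }

  la <- normalize_log2(intensity)

  de <- lapply(c(VM = "VM", MFB = "MFB", STR = "STR"), function(r) {
    differential(la,
                 samples_where(annotations, region = r, condition = "APEX2"),
                 samples_where(annotations, region = r, condition = "CONTROL"))
  })
  enriched_counts <- vapply(de, count_enriched, integer(1L),
                            q_max = q_enrich_counts, direction = "up")

  # single-cell support: bounds, specificity, markers
  if (length(exclude_labels) > 0L) umi <- exclude_cell_labels(umi, exclude_labels)
  umi <- filter_cells_min_umi(umi, min_umi)
  da_cells <- names(umi$cell_labels)[umi$cell_labels == da_label]
  other_cells <- setdiff(colnames(umi$counts), da_cells)
  if (length(da_cells) < 2L || length(other_cells) < 2L) {
    stop("stage 'single-cell' failed: need >= 2 cells in and outside '",
         da_label, "'")
  }
  da_umi <- umi_matrix(umi$counts[, da_cells, drop = FALSE],
                       umi$cell_labels[da_cells])
  bounds <- expression_bounds(da_umi)
  spec_mid <- subsampled_de(umi, da_cells, other_cells, seed = seed)
  spec_str <- NULL
  if (!is.null(umi_str)) {
    if (!identical(rownames(umi_str$counts), rownames(umi$counts))) {
      stop("stage 'single-cell' failed: striatal UMI gene axis differs")
    }
    joint <- umi_matrix(cbind(umi$counts[, da_cells, drop = FALSE],
                              umi_str$counts),
                        c(as.character(umi$cell_labels[da_cells]),
                          as.character(umi_str$cell_labels)))
    spec_str <- subsampled_de(joint, da_cells, colnames(umi_str$counts),
                              seed = seed + 1L)
  }
  markers <- select_markers(spec_mid, lfc_min = marker_lfc, q_max = marker_q)

  vm_trail <- filter_vm(de$VM, de$MFB, de$STR, expr = bounds$means,
                        spec_mid = spec_mid, bounds = bounds, cfg = cfg)
  str_trail <- filter_str(de$VM, de$MFB, de$STR, expr = bounds$means,
                          spec_mid = spec_mid, spec_str = spec_str,
                          bounds = bounds, cfg = cfg)
  partition <- combine_union(vm_trail, str_trail)

  # the compartment comparison is scoped to the filtered union proteome
  la_union <- if (length(partition$union) >= 2L) {
    subset_proteins(la, partition$union)
  } else la
  de_vm_vs_str <- differential(
    la_union,
    samples_where(annotations, region = "VM", condition = "APEX2"),
    samples_where(annotations, region = "STR", condition = "APEX2"))
  regional <- region_enriched_sets(partition, de_vm_vs_str,
                                   q_max = q_enrich_counts)

  localization <- classify_marker_localization(
    markers$gene, partition$union, de_vm_vs_str, q_max = q_enrich_counts)

  concordance <- NULL
  syn_apex <- samples_where(annotations, region = "STR_SYN", condition = "APEX2")
  syn_ctrl <- samples_where(annotations, region = "STR_SYN", condition = "CONTROL")
  if (length(syn_apex) >= 2L && length(syn_ctrl) >= 2L) {
    de_syn <- differential(la, syn_apex, syn_ctrl)
    str_apex <- samples_where(annotations, region = "STR", condition = "APEX2")
    str_pass <- str_trail$protein_id[str_trail$pass_str]
    concordance <- concordance_synaptosome(
      str_pass, de_syn,
      means_slice = rowMeans(unclass(la)[, str_apex, drop = FALSE]),
      means_syn = rowMeans(unclass(la)[, syn_apex, drop = FALSE]),
      q_max = concordance_q)
  }

  ora <- NULL
  if (!is.null(gene_sets)) {
    gs <- gene_symbols(la)
    universe <- unique(unname(gs[partition$union]))
    ora <- list(
      vm = hypergeom_ora(unique(unname(gs[regional$vm_go_input])), gene_sets,
                         universe),
      str = hypergeom_ora(unique(unname(gs[regional$str_go_input])), gene_sets,
                          universe))
  }

  report <- list(
    seed = seed,
    thresholds = list(q_enrich = cfg$q_enrich, lfc_mfb_vm = cfg$lfc_mfb_vm,
                      q_specificity = cfg$q_specificity,
                      lfc_flag_low = cfg$lfc_flag_low, min_umi = min_umi,
                      marker_lfc = marker_lfc, marker_q = marker_q,
                      concordance_q = concordance_q,
                      q_enrich_counts = q_enrich_counts),
    n_proteins = nrow(intensity),
    n_samples = ncol(intensity),
    n_cells_used = ncol(umi$counts),
    enriched_counts = enriched_counts,
    expression_bounds = c(lower = bounds$lower, upper = bounds$upper),
    n_markers = nrow(markers),
    partition_counts = partition$counts,
    regional_counts = regional$counts,
    localization_counts = c(
      present = sum(localization$present_in_filtered),
      vm = sum(localization$compartment %in% "VM_enriched"),
      str = sum(localization$compartment %in% "STR_enriched"),
      unbiased = sum(localization$compartment %in% "unbiased")),
    concordance = if (is.null(concordance)) NULL else
      c(n_reference = concordance$n_reference,
        n_concordant = concordance$n_concordant,
        pearson_r = concordance$pearson_r))

  result <- list(report = report, log_abundance = la, de = de,
                 de_vm_vs_str = de_vm_vs_str, bounds = bounds,
                 spec_mid = spec_mid, spec_str = spec_str, markers = markers,
                 vm_trail = vm_trail, str_trail = str_trail,
                 partition = partition, regional = regional,
                 localization = localization, concordance = concordance,
                 ora = ora)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) utils::write.table(
      x, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    for (r in names(de)) wt(de[[r]], sprintf("de_%s_apex2_vs_control.tsv", tolower(r)))
    wt(de_vm_vs_str, "de_vm_vs_str.tsv")
    wt(spec_mid, "specificity_da_vs_midbrain.tsv")
    if (!is.null(spec_str)) wt(spec_str, "specificity_da_vs_striatum.tsv")
    wt(markers, "marker_genes.tsv")
    wt(vm_trail, "filter_trail_vm.tsv")
    wt(str_trail, "filter_trail_str.tsv")
    wt(localization, "marker_localization.tsv")
    if (!is.null(ora)) {
      wt(ora$vm, "ora_vm.tsv"); wt(ora$str, "ora_str.tsv")
    }
  }
  result
}
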