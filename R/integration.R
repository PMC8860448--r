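#' Classify the subcellular localization of marker-encoded proteins
#'
#' Intersects a marker-gene set with the filtered proteome and assigns each
#' present protein a compartment from the VM-vs-STR differential comparison:
#' `VM_enriched` (q < `q_max`, log2fc > 0, with log2fc computed as VM minus
#' STR), `STR_enriched` (q < `q_max`, log2fc < 0) or `unbiased`.
#'
#' @param marker_genes Character vector of marker gene symbols.
#' @param filtered_ids Protein ids of the filtered (union) proteome.
#' @param de_vm_vs_str `differential_result` of VM APEX2+ vs STR APEX2+.
#' @param q_max FDR threshold (default 0.05).
#' @return Data frame with one row per marker gene: `gene`,
#'   `present_in_filtered`, `compartment`, `q_vm_vs_str`, `log2fc_vm_vs_str`.
#' @export
classify_marker_localization <- function(marker_genes, filtered_ids,
                                         de_vm_vs_str, q_max = 0.05) {
  if (length(marker_genes) == 0L) {
    return(data.frame(gene = character(0L), present_in_filtered = logical(0L),
                      compartment = character(0L), q_vm_vs_str = numeric(0L),
                      log2fc_vm_vs_str = numeric(0L)))
  }
  de <- de_vm_vs_str[de_vm_vs_str$protein_id %in% filtered_ids, ]
  idx <- match(marker_genes, de$gene_symbol)
  present <- !is.na(idx)
  q <- ifelse(present, de$q[idx], NA_real_)
  lfc <- ifelse(present, de$log2fc[idx], NA_real_)
  compartment <- rep("unbiased", length(marker_genes))
  compartment[present & q < q_max & lfc > 0] <- "VM_enriched"
  compartment[present & q < q_max & lfc < 0] <- "STR_enriched"
  compartment[!present] <- NA_character_
  data.frame(gene = marker_genes, present_in_filtered = present,
             compartment = compartment, q_vm_vs_str = q,
             log2fc_vm_vs_str = lfc, row.names = NULL)
}

#' Slice / synaptosome concordance of the filtered axonal proteome
#'
#' Counts how many slice-filtered striatal proteins show concordant APEX2+
#' enrichment in the synaptosome preparation (log2fc > 0 and q < `q_max` in
#' the synaptosome APEX2+ vs control comparison; proteins absent from that
#' comparison count as non-concordant) and reports the Pearson correlation
#' of mean log2 abundances over the reference set.
#'
#' @param str_filtered Protein ids passing the striatal slice filter.
#' @param de_syn `differential_result` of STR_SYN APEX2+ vs control.
#' @param means_slice,means_syn Named numeric vectors of mean APEX2+ log2
#'   abundances (slice and synaptosome), keyed by protein id.
#' @param q_max Concordance FDR threshold (default 0.15).
#' @return List with `n_reference`, `n_concordant`, `concordant_ids`,
#'   `pearson_r`.
#' @export
concordance_synaptosome <- function(str_filtered, de_syn, means_slice,
                                    means_syn, q_max = 0.15) {
  idx <- match(str_filtered, de_syn$protein_id)
  conc <- !is.na(idx) & de_syn$log2fc[idx] > 0 & de_syn$q[idx] < q_max
  common <- str_filtered[str_filtered %in% names(means_slice) &
                           str_filtered %in% names(means_syn)]
  r <- if (length(common) >= 3L) {
    stats::cor(means_slice[common], means_syn[common], method = "pearson")
  } else NA_real_
  list(n_reference = length(str_filtered),
       n_concordant = sum(conc),
       concordant_ids = str_filtered[conc],
       pearson_r = r)
}

#' Pairwise Pearson correlations between samples
#'
#' @param m A `log_abundance_matrix` (or plain matrix, proteins x samples).
#' @param samples Optional sample ids to restrict to (>= 2).
#' @return Symmetric correlation matrix with unit diagonal; zero-variance
#'   columns yield `NA` entries with a warning.
#' @export
replicate_correlations <- function(m, samples = NULL) {
  x <- unclass(m)
  if (!is.null(samples)) x <- x[, samples, drop = FALSE]
  if (ncol(x) < 2L) stop("need >= 2 samples")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance sample(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
  }
  suppressWarnings(stats::cor(x, method = "pearson"))
}

#' Z-score rows and cluster rows and columns
#'
#' Rows are standardized to mean 0, SD 1; rows and columns are then
#' agglomerated by average linkage under Euclidean distance. Zero-variance
#' rows are excluded with a warning. Ties in the merge sequence follow the
#' deterministic lowest-index convention of the agglomeration routine.
#'
#' @param m Numeric matrix (proteins x samples), >= 2 columns.
#' @return List with `z` (the z-scored matrix), `row_order`, `col_order`,
#'   and `hclust` objects `row_tree`, `col_tree` (`NULL` when only one row).
#' @export
zscore_cluster <- function(m) {
  x <- unclass(m)
  if (ncol(x) < 2L) stop("need >= 2 columns")
  rsd <- apply(x, 1L, stats::sd)
  if (any(rsd == 0)) {
    warning("excluding zero-variance row(s): ",
            paste(rownames(x)[rsd == 0], collapse = ", "))
    x <- x[rsd > 0, , drop = FALSE]
  }
  z <- t(scale(t(x)))
  if (nrow(z) < 2L) {
    return(list(z = z, row_order = seq_len(nrow(z)),
                col_order = seq_len(ncol(z)), row_tree = NULL,
                col_tree = NULL))
  }
  row_tree <- stats::hclust(stats::dist(z, method = "euclidean"),
                            method = "average")
  col_tree <- stats::hclust(stats::dist(t(z), method = "euclidean"),
                            method = "average")
  list(z = z, row_order = row_tree$order, col_order = col_tree$order,
       row_tree = row_tree, col_tree = col_tree)
}

#' Principal component analysis over samples
#'
#' Centered (unscaled) PCA with samples as observations and proteins as
#' variables.
#'
#' @param m Numeric matrix (proteins x samples), >= 3 samples.
#' @return List with `coordinates` (samples x PCs), `variance_fraction`
#'   (non-increasing, sums to <= 1) and the `prcomp` fit.
#' @export
pca_samples <- function(m) {
  x <- t(unclass(m))
  if (nrow(x) < 3L) stop("need >= 3 samples")
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  vf <- fit$sdev^2 / sum(fit$sdev^2)
  list(coordinates = fit$x, variance_fraction = vf, fit = fit)
}
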