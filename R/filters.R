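#' Filtering cascade configuration
#'
#' Thresholds governing the ventral-midbrain (VM) and striatum (STR)
#' compartment filtering cascades.
#'
#' @param q_enrich FDR threshold for "significantly enriched APEX2+ vs
#'   control" rules (default 0.05).
#' @param lfc_mfb_vm log2 fold-change threshold for the striatum rescue rule
#'   requiring sub-significant but substantial enrichment in both VM and MFB
#'   (default 1).
#' @param q_specificity FDR threshold applied to the single-cell specificity
#'   differential expression when judging a gene "mDA-neuron specific"
#'   (default 0.05).
#' @param lfc_flag_low log2 fold-change at or below which a significant
#'   specificity result counts as "very low mDA specificity" and removes the
#'   protein (default -1, i.e. at least 2-fold higher in the reference
#'   population).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(q_enrich = 0.05, lfc_mfb_vm = 1,
                          q_specificity = 0.05, lfc_flag_low = -1) {
  stopifnot(q_enrich > 0, q_enrich < 1, q_specificity > 0, q_specificity < 1)
  structure(list(q_enrich = q_enrich, lfc_mfb_vm = lfc_mfb_vm,
                 q_specificity = q_specificity, lfc_flag_low = lfc_flag_low),
            class = "filter_config")
}

# enrichment verdict per protein: significant AND directionally up
.enriched_up <- function(de, q_max) {
  stats::setNames(de$q < q_max & de$log2fc > 0, de$protein_id)
}

# gene-keyed lookups from a specificity DE table (positive log2fc = higher in
# the DA-neuron population)
.spec_flag_low <- function(spec, cfg) {
  if (is.null(spec) || nrow(spec) == 0L) return(character(0L))
  spec$gene[spec$q < cfg$q_specificity & spec$log2fc <= cfg$lfc_flag_low]
}

.spec_specific <- function(spec, cfg) {
  if (is.null(spec) || nrow(spec) == 0L) return(character(0L))
  spec$gene[spec$q < cfg$q_specificity & spec$log2fc > 0]
}

.align_de <- function(de_vm, de_mfb, de_str) {
  ids <- de_vm$protein_id
  if (!setequal(ids, de_mfb$protein_id) || !setequal(ids, de_str$protein_id)) {
    stop("differential tables must share one protein universe")
  }
  list(vm = de_vm[match(ids, de_vm$protein_id), ],
       mfb = de_mfb[match(ids, de_mfb$protein_id), ],
       str = de_str[match(ids, de_str$protein_id), ],
       ids = ids)
}

#' Ventral-midbrain filtering cascade
#'
#' A protein passes the somatodendritic (VM) filter when it is (1)
#' significantly enriched in VM APEX2+ vs control, AND (2a) its gene's mean
#' mDA-neuron expression lies above the single-cell lower bound OR (2b) it is
#' significantly enriched in all three regions, AND (3) it is not flagged as
#' having very low mDA-neuron specificity in the single-cell comparison
#' against all other midbrain cells. Genes absent from the expression table
#' are treated as below the bound (they can still pass via rule 2b).
#'
#' @param de_vm,de_mfb,de_str `differential_result` tables (APEX2+ vs
#'   control per region) over one shared protein universe.
#' @param expr Named numeric vector: per-gene mean DA-neuron expression.
#' @param spec_mid Specificity DE table (columns `gene`, `log2fc`, `q`; DA
#'   neurons vs all other midbrain cells, positive log2fc = higher in DA).
#' @param bounds An `expression_bounds` object (or list with `lower`,
#'   `upper`).
#' @param cfg A [filter_config()].
#' @return A `filter_trail` data frame with per-rule booleans and `pass_vm`.
#' @export
filter_vm <- function(de_vm, de_mfb, de_str, expr, spec_mid, bounds,
                      cfg = filter_config()) {
  d <- .align_de(de_vm, de_mfb, de_str)
  genes <- d$vm$gene_symbol
  e_vm <- .enriched_up(d$vm, cfg$q_enrich)
  e_all <- e_vm & .enriched_up(d$mfb, cfg$q_enrich) & .enriched_up(d$str, cfg$q_enrich)
  expr_val <- unname(expr[genes])
  rule2a <- !is.na(expr_val) & expr_val >= bounds$lower
  flagged <- genes %in% .spec_flag_low(spec_mid, cfg)
  trail <- data.frame(protein_id = d$ids, gene_symbol = genes,
                      vm_rule1 = unname(e_vm),
                      vm_rule2a = rule2a,
                      vm_rule2b = unname(e_all),
                      vm_rule3_removed = flagged,
                      row.names = NULL)
  trail$pass_vm <- trail$vm_rule1 & (trail$vm_rule2a | trail$vm_rule2b) &
    !trail$vm_rule3_removed
  class(trail) <- c("filter_trail", "data.frame")
  trail
}

#' Striatum filtering cascade
#'
#' A protein passes the axonal (striatum) filter when it is (1) significantly
#' enriched in STR APEX2+ vs control, AND passes at least one of (2a)
#' significant enrichment in VM or MFB, (2b) log2 fold change above
#' `lfc_mfb_vm` in both VM and MFB, (2c) high mean mDA-neuron expression
#' (above the upper bound) together with mDA specificity against midbrain or
#' striatal reference cells, AND at least one of (3a) gene expression above
#' the lower bound, (3b) significant enrichment in all three regions, AND (4)
#' is not flagged very-low-specificity against either reference population.
#'
#' @inheritParams filter_vm
#' @param spec_str Specificity DE table of DA neurons vs all striatal cells
#'   (same columns as `spec_mid`).
#' @return A `filter_trail` data frame with per-rule booleans and `pass_str`.
#' @export
filter_str <- function(de_vm, de_mfb, de_str, expr, spec_mid, spec_str,
                       bounds, cfg = filter_config()) {
  d <- .align_de(de_vm, de_mfb, de_str)
  genes <- d$str$gene_symbol
  e_vm <- .enriched_up(d$vm, cfg$q_enrich)
  e_mfb <- .enriched_up(d$mfb, cfg$q_enrich)
  e_str <- .enriched_up(d$str, cfg$q_enrich)
  expr_val <- unname(expr[genes])
  specific <- genes %in% union(.spec_specific(spec_mid, cfg),
                               .spec_specific(spec_str, cfg))
  flagged <- genes %in% union(.spec_flag_low(spec_mid, cfg),
                              .spec_flag_low(spec_str, cfg))
  trail <- data.frame(
    protein_id = d$ids, gene_symbol = genes,
    str_rule1 = unname(e_str),
    str_rule2a = unname(e_vm | e_mfb),
    str_rule2b = unname(d$vm$log2fc > cfg$lfc_mfb_vm & d$mfb$log2fc > cfg$lfc_mfb_vm),
    str_rule2c = !is.na(expr_val) & expr_val >= bounds$upper & specific,
    str_rule3a = !is.na(expr_val) & expr_val >= bounds$lower,
    str_rule3b = unname(e_vm & e_mfb & e_str),
    str_rule4_removed = flagged,
    row.names = NULL)
  trail$pass_str <- trail$str_rule1 &
    (trail$str_rule2a | trail$str_rule2b | trail$str_rule2c) &
    (trail$str_rule3a | trail$str_rule3b) &
    !trail$str_rule4_removed
  class(trail) <- c("filter_trail", "data.frame")
  trail
}

#' Combine VM and striatum filter verdicts into a union partition
#'
#' @param vm_trail,str_trail `filter_trail` tables over the same protein
#'   universe (from [filter_vm()] and [filter_str()]).
#' @return A list with disjoint id vectors `vm_only`, `str_only`, `both`,
#'   their union `union`, and a named `counts` vector.
#' @export
combine_union <- function(vm_trail, str_trail) {
  if (!setequal(vm_trail$protein_id, str_trail$protein_id)) {
    stop("filter trails must share one protein universe")
  }
  str_trail <- str_trail[match(vm_trail$protein_id, str_trail$protein_id), ]
  vm <- vm_trail$protein_id[vm_trail$pass_vm]
  st <- str_trail$protein_id[str_trail$pass_str]
  out <- list(vm_only = setdiff(vm, st),
              str_only = setdiff(st, vm),
              both = intersect(vm, st),
              union = union(vm, st))
  out$counts <- c(vm_only = length(out$vm_only),
                  str_only = length(out$str_only),
                  both = length(out$both),
                  union = length(out$union))
  out
}

#' Region-enriched sets and ontology-analysis inputs
#'
#' Among proteins passing both filters, those with a significant VM-vs-STR
#' differential (FDR below `q_max`) are assigned to the compartment their
#' fold change favours. The per-region over-representation input is the
#' region-only set plus that region's enriched shared proteins; since the
#' two parts are disjoint the input sizes decompose additively.
#'
#' @param partition Output of [combine_union()].
#' @param de_vm_vs_str `differential_result` of VM APEX2+ vs STR APEX2+
#'   (positive log2fc = higher in VM), computed on (at least) the shared set.
#' @param q_max FDR threshold (default 0.05).
#' @return A list with `vm_enriched`, `str_enriched` (shared proteins biased
#'   to each compartment), `vm_go_input`, `str_go_input`, and `counts`.
#' @export
region_enriched_sets <- function(partition, de_vm_vs_str, q_max = 0.05) {
  de <- de_vm_vs_str[de_vm_vs_str$protein_id %in% partition$both, ]
  vm_enr <- de$protein_id[de$q < q_max & de$log2fc > 0]
  str_enr <- de$protein_id[de$q < q_max & de$log2fc < 0]
  out <- list(vm_enriched = vm_enr, str_enriched = str_enr,
              vm_go_input = union(partition$vm_only, vm_enr),
              str_go_input = union(partition$str_only, str_enr))
  out$counts <- c(vm_enriched = length(vm_enr), str_enriched = length(str_enr),
                  vm_go_input = length(out$vm_go_input),
                  str_go_input = length(out$str_go_input))
  out
}
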