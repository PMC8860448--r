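# small in-code fixtures shared across test files

make_intensity <- function(values, genes = NULL) {
  if (is.null(genes)) genes <- paste0("G", seq_len(nrow(values)))
  if (is.null(rownames(values))) rownames(values) <- paste0("P", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("s", seq_len(ncol(values)))
  intensity_matrix(values, genes)
}

random_intensity <- function(n_prot = 10, n_samp = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(round(2^rnorm(n_prot * n_samp, 18, 2), 3), n_prot, n_samp)
  m[sample(length(m), n_prot)] <- 0
  make_intensity(m)
}

# a minimal differential_result-shaped table for the filter cascades
fake_de <- function(ids, q, lfc, genes = ids) {
  data.frame(protein_id = ids, gene_symbol = genes,
             mean_a = 0, mean_b = 0, log2fc = lfc, t_stat = 0, df = 1,
             p = q, q = q, n_a = 4, n_b = 4)
}

make_umi <- function(counts, labels) {
  if (is.null(rownames(counts))) rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("c", seq_len(ncol(counts)))
  umi_matrix(counts, labels)
}
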