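#' Configuration for the proteomics experiment simulator
#'
#' Defaults emulate the design of a per-region APEX2 proximity-labeling
#' experiment: three regions (VM, MFB, STR) with 4 APEX2+ and 4 control
#' replicates each, an optional striatal synaptosome preparation (2 APEX2+,
#' 4 control), log-normal protein intensities, abundant non-enriched
#' background binders (endogenously biotinylated carboxylases and other
#' nonspecific binders), a planted APEX2-specific protein set with
#' region-biased abundance, and logistic detection dropout toward low
#' intensities.
#'
#' @param n_proteins Total protein groups (default 2000).
#' @param n_background Abundant non-enriched background binders (default 100).
#' @param n_enriched Named counts of planted APEX2-specific proteins:
#'   `VM`, `MFB`, `STR` (enriched in that region only) and `shared`
#'   (enriched in all three regions).
#' @param n_shared_biased Named counts (`VM`, `STR`) of shared proteins that
#'   additionally carry a compartment bias between VM and STR APEX2+ samples.
#' @param n_reps APEX2+ and control replicates per region (default 4).
#' @param syn_reps Synaptosome replicates, `c(apex2 = 2, control = 4)`; set
#'   to `NULL` to omit the synaptosome samples.
#' @param effect log2 APEX2-vs-control enrichment of planted proteins
#'   (default 3, i.e. eightfold).
#' @param region_bias log2 compartment bias of the biased shared proteins
#'   (default 2, i.e. fourfold).
#' @param base_mean,base_sd Mean and SD of the per-protein base log2
#'   intensity (log-normal intensities).
#' @param enriched_base_mean,enriched_base_sd Base (control-side) log2
#'   intensity distribution of the planted APEX2-specific proteins: their
#'   nonspecific capture without the enzyme is weak, sitting near the
#'   detection limit, while their APEX2+ abundance is `effect` log2 units
#'   higher.
#' @param background_shift log2 abundance surplus of background binders
#'   (default 3).
#' @param noise_sd Replicate noise SD on the log2 scale (default 0.5).
#' @param dropout_mid,dropout_slope Logistic detection model: a measurement
#'   at log2 intensity `x` is detected with probability
#'   `plogis((x - dropout_mid) / dropout_slope)`.
#' @param seed Integer seed.
#' @return A list of class `proteomics_sim_config`.
#' @export
proteomics_sim_config <- function(n_proteins = 2000L,
                                  n_background = 100L,
                                  n_enriched = c(VM = 150L, MFB = 50L,
                                                 STR = 200L, shared = 400L),
                                  n_shared_biased = c(VM = 100L, STR = 100L),
                                  n_reps = 4L,
                                  syn_reps = c(apex2 = 2L, control = 4L),
                                  effect = 3,
                                  region_bias = 2,
                                  base_mean = 18, base_sd = 2,
                                  enriched_base_mean = 12,
                                  enriched_base_sd = 0.5,
                                  background_shift = 3,
                                  noise_sd = 0.5,
                                  dropout_mid = 13.5, dropout_slope = 0.15,
                                  seed = 1L) {
  stopifnot(n_proteins > 0, n_background >= 0,
            sum(n_enriched) + n_background <= n_proteins,
            sum(n_shared_biased) <= n_enriched[["shared"]],
            n_reps >= 2, noise_sd >= 0, dropout_slope > 0)
  structure(as.list(environment()), class = "proteomics_sim_config")
}

#' Simulate an APEX2 proximity-labeling proteomics experiment
#'
#' Planted APEX2-specific proteins receive a `+effect` log2 shift in APEX2+
#' samples of their region(s) (biased shared proteins an extra
#' `+region_bias` in their favoured compartment); background binders are
#' equally abundant in APEX2+ and control samples; all other proteins are
#' low-level nonspecific binders. Dropout sets undetected measurements to 0.
#' Synaptosome samples (region `STR_SYN`) reuse the striatal effects.
#'
#' @param cfg A [proteomics_sim_config()].
#' @param gene_names Optional character vector (length `n_proteins`) of gene
#'   symbols, letting callers align the proteome with a simulated
#'   transcriptome; defaults to `g0001, g0002, ...`, the same namespace as
#'   [gen_scrnaseq()].
#' @return List with `matrix` (an `intensity_matrix`), `annotations` (sample
#'   annotation data frame) and `truth` (per-protein `enriched_in`,
#'   `bias`, `is_background`).
#' @export
gen_proteomics <- function(cfg = proteomics_sim_config(), gene_names = NULL) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  np <- cfg$n_proteins
  ids <- sprintf("P%04d", seq_len(np))
  genes <- if (is.null(gene_names)) sprintf("g%04d", seq_len(np)) else {
    stopifnot(length(gene_names) == np)
    gene_names
  }

  role <- rep("other", np)
  i <- 0L
  take <- function(n) {
    idx <- (i + 1L):(i + n); i <<- i + n; idx
  }
  bg_idx <- take(cfg$n_background)
  role[bg_idx] <- "background"
  enr_region <- vector("list", np)
  for (r in c("VM", "MFB", "STR")) {
    idx <- take(cfg$n_enriched[[r]])
    role[idx] <- "enriched"
    # striatal (axonal) proteins also label in the MFB their axons traverse
    enr_region[idx] <- if (r == "STR") list(c("MFB", "STR")) else r
  }
  shared_idx <- take(cfg$n_enriched[["shared"]])
  role[shared_idx] <- "enriched"
  enr_region[shared_idx] <- list(c("VM", "MFB", "STR"))
  bias <- rep("", np)
  bias[shared_idx[seq_len(cfg$n_shared_biased[["VM"]])]] <- "VM"
  bias[shared_idx[cfg$n_shared_biased[["VM"]] +
                    seq_len(cfg$n_shared_biased[["STR"]])]] <- "STR"

  base <- stats::rnorm(np, cfg$base_mean, cfg$base_sd)
  base[bg_idx] <- base[bg_idx] + cfg$background_shift
  enr_idx <- which(role == "enriched")
  base[enr_idx] <- stats::rnorm(length(enr_idx), cfg$enriched_base_mean,
                                cfg$enriched_base_sd)

  ann <- do.call(rbind, lapply(c("VM", "MFB", "STR"), function(r) {
    data.frame(sample_id = c(sprintf("%s_APEX2_%d", r, seq_len(cfg$n_reps)),
                             sprintf("%s_CTRL_%d", r, seq_len(cfg$n_reps))),
               region = r,
               condition = rep(c("APEX2", "CONTROL"), each = cfg$n_reps),
               replicate = rep(seq_len(cfg$n_reps), 2L),
               prep = "slice", stringsAsFactors = FALSE)
  }))
  if (!is.null(cfg$syn_reps)) {
    ann <- rbind(ann, data.frame(
      sample_id = c(sprintf("STR_SYN_APEX2_%d", seq_len(cfg$syn_reps[["apex2"]])),
                    sprintf("STR_SYN_CTRL_%d", seq_len(cfg$syn_reps[["control"]]))),
      region = "STR_SYN",
      condition = rep(c("APEX2", "CONTROL"),
                      c(cfg$syn_reps[["apex2"]], cfg$syn_reps[["control"]])),
      replicate = c(seq_len(cfg$syn_reps[["apex2"]]),
                    seq_len(cfg$syn_reps[["control"]])),
      prep = "synaptosome", stringsAsFactors = FALSE))
  }
  rownames(ann) <- NULL

  effect_region <- function(region) {
    # STR_SYN samples inherit the striatal enrichment structure
    r <- if (region == "STR_SYN") "STR" else region
    shift <- vapply(seq_len(np), function(p) {
      if (role[p] != "enriched" || !(r %in% enr_region[[p]])) return(0)
      cfg$effect + if (bias[p] == r) cfg$region_bias else 0
    }, numeric(1L))
    shift
  }
  shifts <- vapply(unique(ann$region), effect_region, numeric(np))

  vals <- matrix(0, np, nrow(ann), dimnames = list(ids, ann$sample_id))
  for (s in seq_len(nrow(ann))) {
    lg <- base + stats::rnorm(np, 0, cfg$noise_sd)
    if (ann$condition[s] == "APEX2") lg <- lg + shifts[, ann$region[s]]
    detected <- stats::runif(np) <
      stats::plogis((lg - cfg$dropout_mid) / cfg$dropout_slope)
    vals[, s] <- ifelse(detected, 2^lg, 0)
  }

  truth <- data.frame(
    protein_id = ids, gene_symbol = genes,
    enriched_in = vapply(enr_region, function(x)
      if (is.null(x)) "" else paste(x, collapse = ","), character(1L)),
    bias = bias,
    is_background = role == "background",
    row.names = NULL)

  list(matrix = intensity_matrix(vals, genes), annotations = ann,
       truth = truth)
}

#' Configuration for the droplet scRNA-seq simulator
#'
#' Cells are multinomially sampled from type-specific gene-probability
#' vectors; planted marker genes carry at least eightfold (default
#' sixteenfold) probability in their target type.
#'
#' @param n_genes Number of genes (default 2000).
#' @param cell_types Named type proportions summing to 1 (default one
#'   DA-neuron type among four).
#' @param n_cells Number of cells (default 600).
#' @param n_markers Planted markers (default 20, for the first listed type).
#' @param marker_fold Fold elevation of each marker gene's sampling
#'   probability in the target type relative to every other type (default
#'   16; the fold is exact on the probability scale).
#' @param marker_mass Total sampling-probability mass of the marker genes in
#'   non-target types (default 0.025; markers are moderately expressed genes,
#'   and in the target type their mass is `marker_fold` times larger).
#' @param depth_meanlog,depth_sdlog Per-cell depth: `round(rlnorm())`
#'   (defaults give a median near 2500 UMIs).
#' @param seed Integer seed.
#' @return A list of class `sc_sim_config`.
#' @export
sc_sim_config <- function(n_genes = 2000L,
                          cell_types = c(DA = 0.25, Glut = 0.3, GABA = 0.3,
                                         Astro = 0.15),
                          n_cells = 600L,
                          n_markers = 20L,
                          marker_fold = 16,
                          marker_mass = 0.025,
                          depth_meanlog = log(2500), depth_sdlog = 0.35,
                          seed = 1L) {
  stopifnot(abs(sum(cell_types) - 1) < 1e-8, n_genes > n_markers,
            marker_fold >= 8, n_cells >= 4,
            marker_fold * marker_mass < 1)
  structure(as.list(environment()), class = "sc_sim_config")
}

#' Simulate a UMI count matrix with planted marker genes
#'
#' @param cfg An [sc_sim_config()].
#' @param gene_names Optional character vector (length `n_genes`); markers
#'   are planted on the first `n_markers` entries, so permuting this vector
#'   controls which genes carry the planted specificity. Defaults to
#'   `g0001, g0002, ...`.
#' @return List with `umi` (a `umi_matrix` with cell-type labels), `truth`
#'   (per-gene `is_marker`, `marker_type`, `marker_fold`) and `depths` (the
#'   drawn per-cell totals; column sums of the counts equal these exactly).
#' @export
gen_scrnaseq <- function(cfg = sc_sim_config(), gene_names = NULL) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  genes <- if (is.null(gene_names)) sprintf("g%04d", seq_len(cfg$n_genes)) else {
    stopifnot(length(gene_names) == cfg$n_genes)
    gene_names
  }
  types <- names(cfg$cell_types)
  marker_idx <- seq_len(cfg$n_markers)

  # marker probabilities are pinned so the planted fold is exact on the
  # probability scale: markers hold `marker_mass` of the library in
  # non-target types and marker_fold times that in the target type, with
  # non-marker genes rescaled to fill the remainder
  m <- 0.5 + stats::runif(cfg$n_markers)
  m <- m / sum(m) * cfg$marker_mass
  base_w <- stats::rgamma(cfg$n_genes - cfg$n_markers, shape = 0.7, rate = 1) + 1e-4
  base_p <- base_w / sum(base_w)
  probs <- vapply(types, function(ty) {
    mm <- if (ty == types[[1L]]) cfg$marker_fold * m else m
    p <- numeric(cfg$n_genes)
    p[marker_idx] <- mm
    p[-marker_idx] <- base_p * (1 - sum(mm))
    p
  }, numeric(cfg$n_genes))

  labels <- sample(types, cfg$n_cells, replace = TRUE,
                   prob = unname(cfg$cell_types))
  depths <- pmax(1L, as.integer(round(stats::rlnorm(cfg$n_cells,
                                                    cfg$depth_meanlog,
                                                    cfg$depth_sdlog))))
  counts <- vapply(seq_len(cfg$n_cells), function(j) {
    stats::rmultinom(1L, depths[j], probs[, labels[j]])[, 1L]
  }, integer(cfg$n_genes))
  dimnames(counts) <- list(genes, sprintf("cell%04d", seq_len(cfg$n_cells)))

  truth <- data.frame(gene = genes,
                      is_marker = seq_len(cfg$n_genes) %in% marker_idx,
                      marker_type = ifelse(seq_len(cfg$n_genes) %in% marker_idx,
                                           types[[1L]], ""),
                      marker_fold = ifelse(seq_len(cfg$n_genes) %in% marker_idx,
                                           cfg$marker_fold, 1),
                      row.names = NULL)
  list(umi = umi_matrix(counts, labels), truth = truth,
       depths = stats::setNames(depths, colnames(counts)))
}
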