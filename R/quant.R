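#' Total-intensity normalization to log2 abundances
#'
#' Converts raw intensities to log2 total-intensity-normalized abundances:
#' `a_i = log2(X_i / sum(X) * 1e6 + 1)` within each sample, i.e. parts-per-
#' million scaling followed by a log2(x + 1) transform. Raw zeros (not
#' detected) map to 0. By construction `sum(2^a - 1) == 1e6` for every
#' sample with nonzero total intensity.
#'
#' @param m An `intensity_matrix`.
#' @return A `log_abundance_matrix` with the same axes and attributes.
#' @export
normalize_log2 <- function(m) {
  totals <- colSums(m)
  if (any(totals <= 0)) {
    stop("sample(s) with zero total intensity: ",
         paste(colnames(m)[totals <= 0], collapse = ", "))
  }
  a <- log2(sweep(unclass(m), 2L, totals, "/") * 1e6 + 1)
  structure(a,
            gene_map = attr(m, "gene_map"),
            gene_symbols = attr(m, "gene_symbols"),
            class = c("log_abundance_matrix", "matrix", "array"))
}

#' @export
print.log_abundance_matrix <- function(x, ...) {
  cat(sprintf("log_abundance_matrix: %d protein groups x %d samples (log2 ppm + 1)\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch test with Welch-Satterthwaite degrees of freedom. The
#' degenerate cases are resolved by convention: both groups constant with
#' equal means gives `t = 0, p = 1`; both constant with unequal means gives
#' `p = 0` with a warning.
#'
#' @param a,b Numeric vectors of log2 abundances, each of length >= 2.
#' @return A list with `t`, `df` and two-sided `p`.
#' @export
welch_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 observations")
  va <- stats::var(a); vb <- stats::var(b)
  sea2 <- va / length(a); seb2 <- vb / length(b)
  if (sea2 + seb2 == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = NA_real_, p = 1))
    warning("zero variance with unequal means: p set to 0")
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_, p = 0))
  }
  t <- (mean(a) - mean(b)) / sqrt(sea2 + seb2)
  df <- (sea2 + seb2)^2 / (sea2^2 / (length(a) - 1L) + seb2^2 / (length(b) - 1L))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (q-values) controlling the false discovery rate.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Two-group differential abundance across a matrix
#'
#' Runs [welch_test()] per protein between two disjoint sample groups and
#' adjusts all p-values with Benjamini-Hochberg across every protein of the
#' matrix. Zeros (non-detections) enter the test as 0 log-abundance.
#'
#' @param m A `log_abundance_matrix`.
#' @param group_a,group_b Character vectors of sample ids; disjoint, each of
#'   size >= 2, all present as columns of `m`.
#' @return A data frame (`differential_result`) with one row per protein:
#'   `protein_id`, `gene_symbol`, `mean_a`, `mean_b`, `log2fc`
#'   (`mean_a - mean_b`), `t_stat`, `df`, `p`, `q`, `n_a`, `n_b`.
#' @export
differential <- function(m, group_a, group_b) {
  missing <- setdiff(c(group_a, group_b), colnames(m))
  if (length(missing) > 0L) {
    stop("sample id(s) not in matrix: ", paste(missing, collapse = ", "))
  }
  if (length(intersect(group_a, group_b)) > 0L) stop("groups must be disjoint")
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs >= 2 samples")
  }
  A <- unclass(m)[, group_a, drop = FALSE]
  B <- unclass(m)[, group_b, drop = FALSE]
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- apply(A, 1L, stats::var); vb <- apply(B, 1L, stats::var)
  sea2 <- va / na; seb2 <- vb / nb
  se2 <- sea2 + seb2
  t <- ifelse(se2 > 0, (ma - mb) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / (sea2^2 / (na - 1L) + seb2^2 / (nb - 1L)),
               NA_real_)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(t), df), ifelse(ma == mb, 1, 0))
  if (any(se2 == 0 & ma != mb)) {
    warning("zero-variance protein(s) with unequal means: p set to 0")
    t[se2 == 0 & ma != mb] <- sign(ma - mb)[se2 == 0 & ma != mb] * Inf
  }
  res <- data.frame(protein_id = rownames(m),
                    gene_symbol = if (is.null(gene_symbols(m))) rownames(m)
                                  else unname(gene_symbols(m)),
                    mean_a = ma, mean_b = mb, log2fc = ma - mb,
                    t_stat = t, df = df, p = p, q = bh_adjust(p),
                    n_a = na, n_b = nb,
                    row.names = NULL)
  class(res) <- c("differential_result", "data.frame")
  res
}

#' Count enriched (or depleted) proteins
#'
#' @param d A `differential_result` data frame.
#' @param q_max FDR threshold (proteins with `q < q_max` are counted).
#' @param direction `"up"` (log2fc > 0), `"down"` (log2fc < 0) or `"any"`.
#' @return Integer count.
#' @export
count_enriched <- function(d, q_max = 0.05, direction = c("up", "down", "any")) {
  direction <- match.arg(direction)
  keep <- d$q < q_max
  keep <- switch(direction,
                 up = keep & d$log2fc > 0,
                 down = keep & d$log2fc < 0,
                 any = keep)
  sum(keep)
}

#' Restrict a matrix to a protein subset, preserving metadata
#'
#' @param m An `intensity_matrix` or `log_abundance_matrix`.
#' @param ids Protein ids to keep (order preserved).
#' @return The row-subset matrix with its class and gene annotations intact.
#' @export
subset_proteins <- function(m, ids) {
  missing <- setdiff(ids, rownames(m))
  if (length(missing) > 0L) {
    stop("unknown protein id(s): ", paste(utils::head(missing, 5L), collapse = ", "))
  }
  out <- unclass(m)[ids, , drop = FALSE]
  structure(out,
            gene_map = attr(m, "gene_map")[ids],
            gene_symbols = attr(m, "gene_symbols")[ids],
            class = class(m))
}

#' Select samples by annotation fields
#'
#' Convenience selector used throughout the analysis drivers.
#'
#' @param annotations Sample annotation data frame.
#' @param region,condition,prep Optional filters; `NULL` means no constraint.
#' @return Character vector of matching sample ids.
#' @export
samples_where <- function(annotations, region = NULL, condition = NULL,
                          prep = NULL) {
  keep <- rep(TRUE, nrow(annotations))
  if (!is.null(region)) keep <- keep & annotations$region %in% region
  if (!is.null(condition)) keep <- keep & annotations$condition %in% condition
  if (!is.null(prep)) keep <- keep & annotations$prep %in% prep
  annotations$sample_id[keep]
}
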