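#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the query list overlaps it more than
#' expected under random draws from the universe: with `N` the universe
#' size, `K` the (universe-intersected) set size, `n` the query size and `k`
#' the overlap, `p = P(X >= k)` for `X ~ Hypergeom(N, K, n)`; p-values are
#' Benjamini-Hochberg adjusted across the tested sets. Query and sets are
#' deduplicated (isoforms collapse to one gene before calling).
#'
#' @param query Character vector of query gene symbols, a subset of
#'   `universe`.
#' @param sets Named list of gene-symbol vectors (a `gene_set_collection`).
#' @param universe Character vector: the background gene list.
#' @return Data frame with one row per set: `term`, `k`, `K`, `n`, `N`, `p`,
#'   `q`, `overlap` (comma-separated overlap genes), sorted by `p`.
#' @export
hypergeom_ora <- function(query, sets, universe) {
  query <- unique(query)
  universe <- unique(universe)
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    stop("query gene(s) outside the universe: ",
         paste(outside, collapse = ", "))
  }
  n <- length(query)
  N <- length(universe)
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(unique(sets[[nm]]), universe)
    K <- length(set)
    ov <- intersect(query, set)
    k <- length(ov)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = nm, k = k, K = K, n = n, N = N, p = p,
               overlap = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$term), c("term", "k", "K", "n", "N", "p", "q",
                                       "overlap")]
  rownames(out) <- NULL
  out
}
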