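#' Read a protein-group intensity table and its sample annotations
#'
#' Reads a tab-separated intensity table (first column protein-group id,
#' second column gene symbol(s), remaining columns one per sample) together
#' with a sample annotation table. Cells that are empty, `NA`, `"NaN"` or the
#' literal token `"Filtered"` are encoded as intensity 0, the convention for
#' "not detected in this sample".
#'
#' @param path Path to the tab-separated intensity table.
#' @param annotation_path Path to the tab-separated annotation table with
#'   columns `sample_id`, `region`, `condition`, `replicate`, `prep`.
#' @return A list with elements `matrix` (an `intensity_matrix`) and
#'   `annotations` (a data frame, one row per sample column).
#' @export
read_intensity_table <- function(path, annotation_path) {
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           na.strings = c("NA", "NaN", ""))
  if (ncol(raw) < 3L) {
    stop("intensity table needs protein id, gene symbol and >=1 sample column")
  }
  annotations <- read_sample_annotations(annotation_path)
  sample_ids <- colnames(raw)[-(1:2)]
  missing_ann <- setdiff(sample_ids, annotations$sample_id)
  if (length(missing_ann) > 0L) {
    stop("sample columns without annotation: ", paste(missing_ann, collapse = ", "))
  }
  vals <- raw[, -(1:2), drop = FALSE]
  vals[vals == "Filtered"] <- NA
  m <- vapply(vals, function(x) suppressWarnings(as.numeric(x)), numeric(nrow(raw)))
  m <- matrix(m, nrow = nrow(raw), dimnames = list(raw[[1L]], sample_ids))
  m[is.na(m)] <- 0
  im <- intensity_matrix(m, gene_symbols = raw[[2L]])
  ann <- annotations[match(sample_ids, annotations$sample_id), , drop = FALSE]
  rownames(ann) <- NULL
  list(matrix = im, annotations = ann)
}

#' Construct an intensity matrix
#'
#' A numeric protein-groups x samples matrix of raw nonnegative quantification
#' intensities; a value of exactly 0 means the protein was not detected in
#' that sample. Multi-gene protein groups (semicolon-separated symbols) are
#' reduced to their first listed symbol, with the full mapping retained.
#'
#' @param values Numeric matrix with protein-group rownames and sample-id
#'   colnames.
#' @param gene_symbols Character vector of gene symbol(s) per protein group
#'   (entries may be semicolon-separated lists).
#' @return An object of class `intensity_matrix`.
#' @export
intensity_matrix <- function(values, gene_symbols) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("protein-group row identifiers must be present and unique")
  }
  if (is.null(colnames(values))) stop("sample column identifiers required")
  if (any(values < 0)) stop("negative intensity encountered")
  if (length(gene_symbols) != nrow(values)) {
    stop("one gene-symbol entry per protein group required")
  }
  structure(values,
            gene_map = stats::setNames(as.character(gene_symbols), rownames(values)),
            gene_symbols = stats::setNames(
              vapply(as.character(gene_symbols), resolve_gene_symbol, character(1L),
                     USE.NAMES = FALSE),
              rownames(values)),
            class = c("intensity_matrix", "matrix", "array"))
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d protein groups x %d samples\n",
              nrow(x), ncol(x)))
  cat(sprintf("  detected (nonzero) fraction: %.3f\n", mean(x > 0)))
  invisible(x)
}

#' Gene symbols of an intensity or log-abundance matrix
#'
#' @param m An `intensity_matrix` or `log_abundance_matrix`.
#' @return Named character vector, one representative symbol per protein group.
#' @export
gene_symbols <- function(m) attr(m, "gene_symbols")

#' Read a sample annotation table
#'
#' @param path Tab-separated file with columns `sample_id`, `region`,
#'   `condition`, `replicate`, `prep`.
#' @return Data frame with validated columns.
#' @export
read_sample_annotations <- function(path) {
  ann <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("sample_id", "region", "condition", "replicate", "prep")
  missing <- setdiff(required, colnames(ann))
  if (length(missing) > 0L) {
    stop("annotation table missing columns: ", paste(missing, collapse = ", "))
  }
  validate_annotations(ann)
}

validate_annotations <- function(ann) {
  if (anyDuplicated(ann$sample_id)) stop("duplicate sample_id in annotations")
  bad_region <- setdiff(unique(ann$region), c("VM", "MFB", "STR", "STR_SYN"))
  if (length(bad_region) > 0L) {
    stop("unknown region(s): ", paste(bad_region, collapse = ", "))
  }
  bad_cond <- setdiff(unique(ann$condition), c("APEX2", "CONTROL", "BULK"))
  if (length(bad_cond) > 0L) {
    stop("unknown condition(s): ", paste(bad_cond, collapse = ", "))
  }
  bad_prep <- setdiff(unique(ann$prep), c("slice", "synaptosome", "bulk"))
  if (length(bad_prep) > 0L) {
    stop("unknown prep(s): ", paste(bad_prep, collapse = ", "))
  }
  if (any(ann$replicate < 1) || any(ann$replicate != round(ann$replicate))) {
    stop("replicate must be a positive integer")
  }
  ann
}

#' Write an intensity table (and optionally annotations) to TSV
#'
#' @param m An `intensity_matrix`.
#' @param path Output path for the intensity table.
#' @param annotations Optional annotation data frame.
#' @param annotation_path Output path for the annotation table (required when
#'   `annotations` is given).
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(m, path, annotations = NULL,
                                  annotation_path = NULL) {
  df <- data.frame(protein_id = rownames(m),
                   gene_symbol = attr(m, "gene_map"),
                   as.data.frame(unclass(m)[, , drop = FALSE]),
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotations)) {
    if (is.null(annotation_path)) stop("annotation_path required with annotations")
    utils::write.table(annotations, annotation_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Reduce a protein-group gene mapping to its representative symbol
#'
#' Protein groups mapped to several homologous genes carry a
#' semicolon-separated symbol list; the first listed entry is used as the
#' representative gene throughout the analysis.
#'
#' @param protein_group Character scalar: one or more gene symbols, separated
#'   by `;`.
#' @return The first listed gene symbol.
#' @export
#' @examples
#' resolve_gene_symbol("Hist1h2bc;Hist1h2be;Hist1h2bg")
resolve_gene_symbol <- function(protein_group) {
  if (length(protein_group) != 1L || is.na(protein_group)) {
    stop("`protein_group` must be a single non-missing string")
  }
  first <- strsplit(protein_group, ";", fixed = TRUE)[[1L]][1L]
  if (is.null(first) || is.na(first) || !nzchar(trimws(first))) {
    stop("protein group has no mapped gene symbol")
  }
  trimws(first)
}

#' Read a gene-set collection in GMT format
#'
#' Standard GMT dialect: one set per line, `name TAB description TAB gene...`.
#' Duplicate gene entries within a set are collapsed.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`: named list of unique gene-symbol vectors,
#'   with per-set descriptions in attribute `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1L)) < 3L
  if (any(short)) {
    stop("GMT line(s) with fewer than 3 tab-separated fields: ",
         paste(which(short), collapse = ", "))
  }
  nm <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set name(s): ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  if (any(lengths(sets) == 0L)) stop("empty gene set(s) in GMT")
  structure(stats::setNames(sets, nm),
            descriptions = stats::setNames(vapply(fields, `[[`, character(1L), 2L), nm),
            class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#'
#' @param sets Named list of gene-symbol vectors (or a `gene_set_collection`).
#' @param path Output path.
#' @param descriptions Optional per-set description vector.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "descriptions")
    if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  }
  lines <- mapply(function(nm, desc, genes) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}
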