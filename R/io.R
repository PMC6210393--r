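#' Read an omics matrix from TSV
#'
#' Expects genes in rows and samples in columns, a header row of sample IDs
#' and gene IDs in the first column. Duplicate gene IDs are an error.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_omics_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop_validation("duplicate gene identifiers in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' @rdname read_omics_tsv
#' @param m numeric matrix (genes x samples) with dimnames.
#' @export
write_omics_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-interaction edge list (TSV or SIF)
#'
#' TSV files carry one undirected edge per line as two tab-separated gene
#' identifiers (no header). SIF files (`*.sif`) carry
#' `node1 relation node2`; the relation column is ignored. Self-loops are
#' dropped and duplicate (unordered) edges collapsed.
#'
#' @param path file path; dialect chosen by extension (`.sif` vs anything
#'   else) unless `format` is given.
#' @param format `"tsv"`, `"sif"`, or `NULL` to infer from the extension.
#' @return data frame with columns `from`, `to`.
#' @export
read_edge_list <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   sep = "", colClasses = "character")
  if (format == "sif") {
    if (ncol(df) < 3) stop_validation("SIF file needs 3 columns: ", path)
    df <- df[, c(1, 3)]
  } else {
    if (ncol(df) < 2) stop_validation("edge list needs 2 columns: ", path)
    df <- df[, 1:2]
  }
  names(df) <- c("from", "to")
  canonical_edges(df)
}

# drop self-loops, collapse duplicate undirected edges, canonical order
canonical_edges <- function(df) {
  df <- df[df$from != df$to, , drop = FALSE]
  lo <- pmin(df$from, df$to)
  hi <- pmax(df$from, df$to)
  keep <- !duplicated(paste(lo, hi, sep = "\r"))
  out <- data.frame(from = lo[keep], to = hi[keep],
                    stringsAsFactors = FALSE)
  out[order(out$from, out$to), , drop = FALSE]
}

#' @rdname read_edge_list
#' @param edges data frame with columns `from`, `to`.
#' @export
write_edge_list <- function(edges, path) {
  write.table(edges[, c("from", "to")], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Accepts either a precomputed `label` column (values `good`/`poor`) or
#' `survival_days` + `vital_status` columns, in which case labels are derived
#' via [label_samples()] using `threshold`.
#'
#' @param path TSV with a `sample_id` column.
#' @param threshold days; required when labels must be derived.
#' @param deceased_policy passed to [label_samples()].
#' @return named factor of labels (levels `good`/`poor`), possibly with NAs
#'   for excluded samples.
#' @export
read_clinical <- function(path, threshold = NULL,
                          deceased_policy = "exclude") {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop_validation("clinical table needs a 'sample_id' column: ", path)
  if ("label" %in% names(df)) {
    bad <- setdiff(unique(df$label), c("good", "poor"))
    if (length(bad))
      stop_validation("clinical labels must be good/poor; found: ",
                      paste(bad, collapse = ", "))
    lab <- factor(df$label, levels = c("good", "poor"))
  } else if (all(c("survival_days", "vital_status") %in% names(df))) {
    if (is.null(threshold))
      stop_validation("threshold required to derive labels from survival")
    lab <- label_samples(df$survival_days, df$vital_status, threshold,
                         deceased_policy)
  } else {
    stop_validation("clinical table needs 'label' or ",
                    "'survival_days'+'vital_status' columns: ", path)
  }
  names(lab) <- df$sample_id
  lab
}
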