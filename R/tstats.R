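#' Z-score normalize an omics matrix
#'
#' Centers and scales to unit variance along the chosen axis using the
#' sample standard deviation (n-1 denominator, the same weighting the pooled
#' t-statistic uses). The default axis `"gene"` standardizes each gene across
#' samples, which makes t-statistics comparable across genes; `"sample"`
#' standardizes each sample across genes. Zero-variance rows (or columns) map
#' to all zeros.
#'
#' @param m numeric matrix, genes x samples.
#' @param axis `"gene"` (rows) or `"sample"` (columns).
#' @return matrix of the same shape with attributes `center` and `scale`
#'   (per-unit mean and sd along the chosen axis) for reuse on new data.
#' @examples
#' zscore_normalize(matrix(1:6, 2, 3, dimnames = list(c("a", "b"), NULL)))
#' @export
zscore_normalize <- function(m, axis = c("gene", "sample")) {
  axis <- match.arg(axis)
  if (length(m) == 0L) stop_validation("empty matrix")
  if (axis == "sample") {
    inner <- zscore_normalize(t(m), axis = "gene")
    return(structure(t(inner), center = attr(inner, "center"),
                     scale = attr(inner, "scale"), axis = "sample"))
  }
  if (ncol(m) < 2L)
    stop_validation("need at least 2 values along the normalization axis")
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1L))
  z <- (m - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  structure(z, center = mu, scale = s, axis = "gene")
}

#' Pooled two-sample t-statistics per gene
#'
#' For each gene computes the equal-variance two-sample t-statistic between
#' the poor and good prognosis groups,
#' \deqn{t_i = (\bar x_{i,p} - \bar x_{i,g}) / (s_i \sqrt{1/n_p + 1/n_g}),}
#' with the pooled standard deviation
#' \deqn{s_i = \sqrt{((n_p-1) S_{x_{i,p}}^2 + (n_g-1) S_{x_{i,g}}^2)/(n_p+n_g-2)}.}
#' The sign convention is poor mean minus good mean. Genes with zero pooled
#' variance get `t = NA` and are excluded from top-N ranking; genes with any
#' missing value are dropped beforehand (see `na_policy`).
#'
#' @param m numeric matrix, genes x samples.
#' @param labels factor/character per sample with values `good`/`poor`
#'   (extra levels rejected); must align with `colnames(m)` when both are
#'   named, otherwise positionally.
#' @param na_policy `"drop"` removes genes with any NA from the result;
#'   `"impute_mean"` replaces NAs by the gene's observed mean first.
#' @return data frame with columns `gene`, `t`, `abs_t`, `mean_poor`,
#'   `mean_good`, `n_poor`, `n_good`, `pooled_sd`.
#' @export
pooled_t_stat <- function(m, labels,
                          na_policy = c("drop", "impute_mean")) {
  na_policy <- match.arg(na_policy)
  labels <- align_labels(m, labels)
  keep <- !is.na(labels)
  m <- m[, keep, drop = FALSE]
  labels <- labels[keep]
  np <- sum(labels == "poor")
  ng <- sum(labels == "good")
  if (np < 2L || ng < 2L)
    stop_validation("each prognosis group needs at least 2 samples ",
                    "(got ", np, " poor, ", ng, " good)")
  if (anyNA(m)) {
    if (na_policy == "impute_mean") {
      mu <- rowMeans(m, na.rm = TRUE)
      idx <- which(is.na(m), arr.ind = TRUE)
      m[idx] <- mu[idx[, 1]]
    } else {
      m <- m[!apply(is.na(m), 1, any), , drop = FALSE]
    }
  }
  xp <- m[, labels == "poor", drop = FALSE]
  xg <- m[, labels == "good", drop = FALSE]
  mp <- rowMeans(xp)
  mg <- rowMeans(xg)
  vp <- rowSums((xp - mp)^2) / (np - 1L)
  vg <- rowSums((xg - mg)^2) / (ng - 1L)
  s <- sqrt(((np - 1L) * vp + (ng - 1L) * vg) / (np + ng - 2L))
  tt <- ifelse(s > 0, (mp - mg) / (s * sqrt(1 / np + 1 / ng)), NA_real_)
  data.frame(gene = rownames(m), t = tt, abs_t = abs(tt),
             mean_poor = mp, mean_good = mg,
             n_poor = np, n_good = ng, pooled_sd = s,
             row.names = NULL, stringsAsFactors = FALSE)
}

align_labels <- function(m, labels) {
  lv <- as.character(labels)
  bad <- setdiff(unique(lv[!is.na(lv)]), c("good", "poor"))
  if (length(bad))
    stop_validation("labels must be good/poor; found: ",
                    paste(bad, collapse = ", "))
  if (!is.null(names(labels)) && !is.null(colnames(m))) {
    if (!all(colnames(m) %in% names(labels)))
      stop_validation("labels missing for some samples")
    lv <- lv[match(colnames(m), names(labels))]
  } else if (length(labels) != ncol(m)) {
    stop_validation("labels length does not match sample count")
  }
  factor(lv, levels = c("good", "poor"))
}

#' Select the top genes of a layer by absolute t-statistic
#'
#' Ties are broken deterministically: descending `|t|`, then ascending gene
#' identifier. Genes with undefined t (zero pooled variance) never rank.
#'
#' @param tstats data frame from [pooled_t_stat()].
#' @param n_top number of genes to keep; if the layer holds fewer rankable
#'   genes, all of them are returned.
#' @return character vector of gene identifiers.
#' @export
select_top_genes <- function(tstats, n_top) {
  if (!is.numeric(n_top) || n_top < 1L)
    stop_validation("n_top must be >= 1")
  ok <- tstats[!is.na(tstats$t), , drop = FALSE]
  ord <- order(-ok$abs_t, ok$gene)
  head(ok$gene[ord], n_top)
}

#' Layer-wise top gene sets and their union
#'
#' Runs [pooled_t_stat()] and [select_top_genes()] on every supplied layer
#' and forms the union U of the per-layer sets (M, C, T, S for mRNA, CNV,
#' DNA methylation and SNP layers respectively).
#'
#' @param layers named list of genes x samples matrices (names are layer
#'   tags).
#' @param labels per-sample `good`/`poor` labels.
#' @param n_top per-layer cutoff (the same N for every layer).
#' @param na_policy passed to [pooled_t_stat()].
#' @return object of class `gene_set_quartet`: list with `sets` (named list
#'   of per-layer gene sets), `U` (their union), `n_top`, and `tstats`
#'   (named list of per-layer t-statistic tables).
#' @export
gene_set_quartet <- function(layers, labels, n_top = 400,
                             na_policy = "drop") {
  stopifnot(is.list(layers), length(layers) >= 1L, !is.null(names(layers)))
  tst <- lapply(layers, pooled_t_stat, labels = labels,
                na_policy = na_policy)
  sets <- lapply(tst, select_top_genes, n_top = n_top)
  structure(list(sets = sets, U = sort(unique(unlist(sets, use.names = FALSE))),
                 n_top = n_top, tstats = tst),
            class = "gene_set_quartet")
}

#' @export
print.gene_set_quartet <- function(x, ...) {
  cat("Top-gene quartet (N =", x$n_top, "per layer)\n")
  for (tag in names(x$sets))
    cat(sprintf("  %-12s %d genes\n", tag, length(x$sets[[tag]])))
  cat("  union U:", length(x$U), "genes\n")
  invisible(x)
}
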