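#' Reconstruct the functional-interaction network around the top genes
#'
#' Keeps every edge of the input interaction network with at least one
#' endpoint in the union U of the layer-wise top gene sets. The node set of
#' the reconstructed network is the set of genes incident to a retained edge,
#' so non-U neighbours of U genes stay in (the neighbour-vote feature
#' assignment relies on them). The symmetric 0/1 adjacency matrix is built
#' over the retained nodes.
#'
#' @param edges data frame with columns `from`, `to` (undirected edges).
#' @param quartet a [gene_set_quartet()] or a character vector taken as U.
#' @return object of class `fis_network`: list with `nodes` (ordered gene
#'   ids), `edges` (retained edge data frame), `A` (dense symmetric 0/1
#'   adjacency with zero diagonal, dimnames = nodes) and `U`.
#' @export
reconstruct_network <- function(edges, quartet) {
  U <- if (inherits(quartet, "gene_set_quartet")) quartet$U
       else as.character(quartet)
  if (length(U) == 0L) stop_validation("U is empty")
  edges <- canonical_edges(edges[, c("from", "to")])
  keep <- edges$from %in% U | edges$to %in% U
  if (!any(keep))
    stop_validation("no network edge touches the selected gene union U; ",
                    "the reconstructed network would be empty")
  kept <- edges[keep, , drop = FALSE]
  nodes <- sort(unique(c(kept$from, kept$to)))
  n <- length(nodes)
  A <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  i <- match(kept$from, nodes)
  j <- match(kept$to, nodes)
  A[cbind(i, j)] <- 1L
  A[cbind(j, i)] <- 1L
  structure(list(nodes = nodes, edges = kept, A = A,
                 U = intersect(U, nodes)),
            class = "fis_network")
}

#' @export
print.fis_network <- function(x, ...) {
  cat(sprintf("Reconstructed FI network: %d genes, %d edges (%d in U)\n",
              length(x$nodes), nrow(x$edges), length(x$U)))
  invisible(x)
}

#' Build per-sample real vectors for adversarial training
#'
#' For every gene of the reconstructed network, the gene's values are taken
#' from the omics layer where its absolute t-statistic is largest (among the
#' layers that contain the gene); the per-sample rows of the resulting
#' samples x genes matrix are the "real" examples the discriminator sees.
#' Layer ties and genes with no defined t fall back to the fixed layer
#' priority mRNA > CNV > methylation > SNP.
#'
#' @param layers named list of normalized genes x samples matrices.
#' @param quartet a [gene_set_quartet()] holding per-layer t-statistics
#'   (or a compatible named list of t tables in `$tstats`).
#' @param network a [reconstruct_network()] result.
#' @return samples x genes numeric matrix, columns ordered like
#'   `network$nodes`, with attribute `source_layer` (named character vector
#'   giving the chosen layer per gene).
#' @export
build_real_vectors <- function(layers, quartet, network) {
  stopifnot(inherits(network, "fis_network"))
  tst <- quartet$tstats
  tags <- order_tags(names(layers))
  samples <- colnames(layers[[1]])
  for (tag in tags)
    if (!identical(colnames(layers[[tag]]), samples))
      stop_validation("layers disagree on sample ordering")
  # |t| per gene per layer (NA where gene absent or t undefined)
  abs_t <- sapply(tags, function(tag) {
    v <- setNames(tst[[tag]]$abs_t, tst[[tag]]$gene)
    unname(v[network$nodes])
  })
  abs_t <- matrix(abs_t, nrow = length(network$nodes),
                  dimnames = list(network$nodes, tags))
  present <- sapply(tags, function(tag) network$nodes %in%
                      rownames(layers[[tag]]))
  present <- matrix(present, nrow = length(network$nodes),
                    dimnames = list(network$nodes, tags))
  if (any(rowSums(present) == 0L))
    stop_validation("genes absent from every layer: ",
                    paste(head(network$nodes[rowSums(present) == 0L], 5),
                          collapse = ", "))
  src <- vapply(seq_along(network$nodes), function(i) {
    cand <- tags[present[i, ]]
    tv <- abs_t[i, cand]
    if (all(is.na(tv))) return(cand[1L])  # priority-ordered fallback
    best <- max(tv, na.rm = TRUE)
    cand[which(!is.na(tv) & tv == best)][1L]
  }, character(1))
  names(src) <- network$nodes
  out <- matrix(NA_real_, length(samples), length(network$nodes),
                dimnames = list(samples, network$nodes))
  for (tag in unique(src)) {
    g <- network$nodes[src == tag]
    out[, g] <- t(layers[[tag]][g, samples, drop = FALSE])
  }
  structure(out, source_layer = src)
}

# order layer tags canonically (priority order), unknown tags last as given
order_tags <- function(tags) {
  c(intersect(LAYER_TAGS, tags), setdiff(tags, LAYER_TAGS))
}
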