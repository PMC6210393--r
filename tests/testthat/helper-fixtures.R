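# shared fixture builders (everything generated in code, seeded)

# hand-built quartet over explicit sets; t tables only carry what the
# assignment fallback needs
make_quartet <- function(sets, tstats = NULL, n_top = 10L) {
  if (is.null(tstats))
    tstats <- lapply(sets, function(s)
      data.frame(gene = s, t = rep(1, length(s)), abs_t = rep(1, length(s)),
                 stringsAsFactors = FALSE))
  structure(list(sets = sets,
                 U = sort(unique(unlist(sets, use.names = FALSE))),
                 n_top = n_top, tstats = tstats),
            class = "gene_set_quartet")
}

make_network <- function(from, to) {
  reconstruct_network(data.frame(from = from, to = to,
                                 stringsAsFactors = FALSE),
                      unique(c(from, to)))
}

random_edges <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  ids <- sprintf("n%03d", seq_len(n_nodes))
  from <- sample(ids, n_edges * 2, replace = TRUE)
  to <- sample(ids, n_edges * 2, replace = TRUE)
  keep <- from != to
  df <- data.frame(from = from[keep], to = to[keep],
                   stringsAsFactors = FALSE)
  head(df[!duplicated(paste(pmin(df$from, df$to), pmax(df$from, df$to))), ],
       n_edges)
}

small_cohort <- function(seed = 1, ...) {
  args <- modifyList(list(n_genes = 80L, n_samples_good = 15L,
                          n_samples_poor = 15L, n_layers = 2L,
                          planted_genes = 8L, effect_size = 2,
                          seed = seed), list(...))
  simulate_cohort(do.call(sim_config, args))
}
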