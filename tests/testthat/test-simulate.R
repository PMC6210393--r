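test_that("two-gene network is the single possible edge", {
  net <- generate_network(sim_config(n_genes = 2, pa_m = 1,
                                     planted_genes = 1, seed = 1))
  expect_equal(nrow(net), 1L)
  expect_setequal(unlist(net[1, ]), c("g0001", "g0002"))
})

test_that("generated networks are simple, connected and right-skewed", {
  for (s in c(3, 17)) {
    cfg <- sim_config(n_genes = 100, pa_m = 2, seed = s)
    net <- generate_network(cfg)
    expect_true(all(net$from != net$to))
    key <- paste(pmin(net$from, net$to), pmax(net$from, net$to))
    expect_false(any(duplicated(key)))
    g <- igraph::graph_from_data_frame(net, directed = FALSE)
    expect_true(igraph::is_connected(g))
    expect_equal(igraph::vcount(g), 100)
    deg <- igraph::degree(g)
    expect_gt(mean(deg > mean(deg) * 3), 0)  # a few hubs exist
  }
})

test_that("preferential attachment yields (n - 1 - (m - 1)) * m + (m - 1) edges", {
  # growth bookkeeping for the chosen variant: node 2 attaches 1 edge,
  # every later node attaches m = 2, so 1 + 2 * 98 = 197 for n = 100
  net <- generate_network(sim_config(n_genes = 100, pa_m = 2, seed = 7))
  expect_equal(nrow(net), 197L)
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- sim_config(n_genes = 100, seed = 7, n_layers = 2)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$network, b$network)
  expect_identical(a$layers, b$layers)
  expect_identical(a$truth, b$truth)
})

test_that("cohort structure honours the configuration", {
  coh <- small_cohort(seed = 4, n_layers = 3L)
  expect_named(coh$layers, c("mRNA", "CNV", "methylation"))
  expect_equal(table(coh$labels)[["good"]], 15)
  expect_equal(table(coh$labels)[["poor"]], 15)
  net_genes <- unique(c(coh$network$from, coh$network$to))
  expect_true(all(coh$truth$gene %in% net_genes))
  for (m in coh$layers) expect_identical(colnames(m), names(coh$labels))
  # planted module is connected when planted_mode = "module"
  g <- igraph::graph_from_data_frame(coh$network, directed = FALSE)
  sub <- igraph::induced_subgraph(g, coh$truth$gene)
  expect_true(igraph::is_connected(sub))
})

test_that("null cohorts are calibrated: |t| follows Student's t", {
  cfg <- sim_config(n_genes = 6000, n_samples_good = 20, n_samples_poor = 20,
                    n_layers = 1, planted_genes = 1, effect_size = 0,
                    seed = 42)
  coh <- simulate_cohort(cfg)
  tt <- pooled_t_stat(coh$layers$mRNA, coh$labels)
  df <- 38
  expect_equal(mean(abs(tt$t) > qt(0.975, df)), 0.05, tolerance = 0.2)
  ks <- suppressWarnings(ks.test(tt$t, pt, df = df))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted genes dominate |t| in their signal layer at effect size 2", {
  hits <- 0; total <- 0
  for (s in 1:3) {
    coh <- simulate_cohort(sim_config(n_genes = 500, planted_genes = 20,
                                      n_layers = 1, effect_size = 2,
                                      seed = s))
    tt <- pooled_t_stat(coh$layers$mRNA, coh$labels)
    decile <- quantile(tt$abs_t, 0.9)
    hits <- hits + sum(tt$abs_t[tt$gene %in% coh$truth$gene] >= decile)
    total <- total + nrow(coh$truth)
  }
  # two-sample power at d = 2, n = 20+20 makes top-decile membership
  # near-certain
  expect_gte(hits / total, 0.95)
})

test_that("planted-gene rank improves monotonically with effect size", {
  mean_rank <- sapply(c(0, 1, 2), function(es) {
    ranks <- sapply(1:3, function(s) {
      coh <- simulate_cohort(sim_config(n_genes = 300, planted_genes = 15,
                                        n_layers = 1, effect_size = es,
                                        seed = s))
      tt <- pooled_t_stat(coh$layers$mRNA, coh$labels)
      mean(rank(-tt$abs_t)[tt$gene %in% coh$truth$gene])
    })
    mean(ranks)
  })
  expect_true(all(diff(mean_rank) < 0))
})

test_that("survival labelling follows the alive/threshold rule", {
  expect_equal(as.character(label_samples(c(400, 300), c("alive", "alive"),
                                          threshold = 365)),
               c("good", "poor"))
  # boundary: exactly the criterion counts as good
  expect_equal(as.character(label_samples(rep(365, 3), rep("alive", 3), 365)),
               rep("good", 3))
  expect_length(label_samples(numeric(0), character(0), 365), 0)
  expect_error(label_samples(c(-1, 10), c("alive", "alive"), 365),
               "negative")
  # deceased handling is policy-driven
  lab <- label_samples(c(100, 400), c("dead", "dead"), 365)
  expect_true(all(is.na(lab)))
  lab <- label_samples(c(100, 400), c("dead", "dead"), 365,
                       deceased_policy = "poor_if_short")
  expect_equal(as.character(lab), c("poor", "good"))
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(n_genes = 1), class = "omnirank_config_error")
  expect_error(sim_config(planted_genes = 300, n_genes = 100),
               class = "omnirank_config_error")
  expect_error(sim_config(effect_size = -1), class = "omnirank_config_error")
  expect_error(sim_config(n_layers = 5), class = "omnirank_config_error")
})

test_that("cohorts round-trip through the on-disk formats", {
  coh <- small_cohort(seed = 9)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  m <- read_omics_tsv(file.path(dir, "mRNA.tsv"))
  expect_equal(m, coh$layers$mRNA, tolerance = 1e-12, ignore_attr = TRUE)
  net <- read_edge_list(file.path(dir, "network.tsv"))
  expect_setequal(paste(net$from, net$to),
                  paste(pmin(coh$network$from, coh$network$to),
                        pmax(coh$network$from, coh$network$to)))
  lab <- read_clinical(file.path(dir, "clinical.tsv"))
  expect_equal(as.character(lab), as.character(coh$labels))
})
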