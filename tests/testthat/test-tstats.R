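test_that("z-scores center and scale each gene (sample-sd convention)", {
  m <- matrix(c(1, 2, 3), 1, 3, dimnames = list("g1", paste0("s", 1:3)))
  expect_equal(as.vector(zscore_normalize(m)), c(-1, 0, 1))
  m2 <- matrix(5, 1, 3, dimnames = list("g1", paste0("s", 1:3)))
  expect_equal(as.vector(zscore_normalize(m2)), c(0, 0, 0))
  set.seed(1)
  r <- matrix(rnorm(1000, 3, 2), 50, 20)
  z <- zscore_normalize(r)
  expect_lt(max(abs(rowMeans(z))), 1e-10)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-10)
  # per-sample axis standardizes columns instead
  zs <- zscore_normalize(r, axis = "sample")
  expect_lt(max(abs(colMeans(zs))), 1e-10)
  expect_lt(max(abs(apply(zs, 2, sd) - 1)), 1e-10)
  expect_error(zscore_normalize(matrix(numeric(0), 0, 0)),
               class = "omnirank_validation_error")
})

test_that("pooled t-statistic matches the closed-form example", {
  m <- matrix(c(1, 2, 3, 3, 4, 5), 1, 6,
              dimnames = list("g1", paste0("s", 1:6)))
  lab <- setNames(factor(rep(c("good", "poor"), each = 3)), colnames(m))
  tt <- pooled_t_stat(m, lab)
  # means 4 vs 2, pooled sd 1, factor sqrt(1/3 + 1/3) -> t = sqrt(6)
  expect_equal(tt$t, sqrt(6), tolerance = 1e-12)
  expect_equal(tt$pooled_sd, 1)
  # equal group means give t = 0; swapping labels negates t
  m0 <- matrix(c(1, 2, 3, 3, 2, 1), 1, 6,
               dimnames = list("g1", paste0("s", 1:6)))
  expect_equal(pooled_t_stat(m0, lab)$t, 0)
  swapped <- setNames(factor(c("poor", "poor", "poor", "good", "good",
                               "good"), levels = c("good", "poor")),
                      colnames(m))
  expect_equal(pooled_t_stat(m, swapped)$t, -tt$t)
})

test_that("pooled t equals the classical equal-variance t on random genes", {
  set.seed(7)
  np <- 13; ng <- 9
  m <- matrix(rnorm(1000 * (np + ng)), 1000,
              dimnames = list(sprintf("g%04d", 1:1000),
                              sprintf("s%02d", 1:(np + ng))))
  lab <- setNames(factor(rep(c("poor", "good"), c(np, ng)),
                         levels = c("good", "poor")), colnames(m))
  tt <- pooled_t_stat(m, lab)
  oracle <- apply(m, 1, function(x)
    unname(t.test(x[lab == "poor"], x[lab == "good"],
                  var.equal = TRUE)$statistic))
  expect_lt(max(abs(tt$t - oracle)), 1e-10)
})

test_that("degenerate inputs are handled per the documented conventions", {
  m <- matrix(1, 3, 6, dimnames = list(paste0("g", 1:3), paste0("s", 1:6)))
  m[2, ] <- rnorm(6)
  lab <- setNames(factor(rep(c("good", "poor"), each = 3)), colnames(m))
  tt <- pooled_t_stat(m, lab)
  expect_true(is.na(tt$t[tt$gene == "g1"]))   # zero variance -> undefined
  expect_false(is.na(tt$t[tt$gene == "g2"]))
  expect_error(pooled_t_stat(m[, 1:3], lab[1:3]),
               class = "omnirank_validation_error")
  # NA genes are dropped by default, imputed on request
  m[3, 2] <- NA
  expect_false("g3" %in% pooled_t_stat(m, lab)$gene)
  expect_true("g3" %in% pooled_t_stat(m, lab, na_policy = "impute_mean")$gene)
})

test_that("top-gene selection is an order statistic with stable ties", {
  tt <- data.frame(gene = c("g1", "g2", "g3"), t = c(3, -1, 2),
                   abs_t = c(3, 1, 2))
  expect_setequal(select_top_genes(tt, 2), c("g1", "g3"))
  expect_setequal(select_top_genes(tt, 10), tt$gene)
  # brute-force sort oracle on a random vector
  set.seed(3)
  tt2 <- data.frame(gene = sprintf("g%03d", 1:200),
                    t = rnorm(200))
  tt2$abs_t <- abs(tt2$t)
  expect_equal(sort(select_top_genes(tt2, 50)),
               sort(tt2$gene[order(-tt2$abs_t)][1:50]))
  # ties break by ascending gene id
  tie <- data.frame(gene = c("gB", "gA", "gC"), t = c(1, 1, 2),
                    abs_t = c(1, 1, 2))
  expect_equal(select_top_genes(tie, 2), c("gC", "gA"))
})

test_that("layer quartet takes the same N everywhere and unions the sets", {
  coh <- small_cohort(seed = 5)
  lay <- lapply(coh$layers, zscore_normalize)
  q <- gene_set_quartet(lay, coh$labels, n_top = 10)
  expect_named(q$sets, c("mRNA", "CNV"))
  expect_true(all(lengths(q$sets) <= 10))
  expect_setequal(q$U, unique(unlist(q$sets)))
})

test_that("planted genes are captured by their layer's top set", {
  # N = 2 x planted count; capture should be near the noncentral-t rate
  hits <- 0; total <- 0
  for (s in 1:3) {
    coh <- small_cohort(seed = s, n_genes = 200L, planted_genes = 10L)
    lay <- lapply(coh$layers, zscore_normalize)
    q <- gene_set_quartet(lay, coh$labels, n_top = 20)
    for (i in seq_len(nrow(coh$truth)))
      hits <- hits + (coh$truth$gene[i] %in% q$sets[[coh$truth$layer[i]]])
    total <- total + nrow(coh$truth)
  }
  expect_gte(hits / total, 0.95)
})
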