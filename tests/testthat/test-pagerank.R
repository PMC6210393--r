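# dense linear-solve oracle: PR = (1-d)/n 1 + d M PR with M the
# column-normalized weight matrix (dangling columns uniform)
pagerank_solve <- function(G, d) {
  G <- abs(G)
  n <- nrow(G)
  cs <- colSums(G)
  M <- G
  for (j in seq_len(n)) M[, j] <- if (cs[j] > 0) G[, j] / cs[j] else 1 / n
  as.vector(solve(diag(n) - d * M, rep((1 - d) / n, n)))
}

test_that("symmetric two-node network splits the score evenly", {
  G <- matrix(c(0, 0.7, 0.7, 0), 2, 2, dimnames = list(c("a", "b"),
                                                       c("a", "b")))
  pr <- weighted_pagerank(G, d = 0.85, tol = 1e-12, max_iter = 10000)
  expect_equal(unname(pr$scores), c(0.5, 0.5), tolerance = 1e-10)
})

test_that("vanishing damping collapses to the uniform distribution", {
  set.seed(1)
  G <- matrix(runif(25), 5, 5); G <- G + t(G); diag(G) <- 0
  dimnames(G) <- list(letters[1:5], letters[1:5])
  pr <- weighted_pagerank(G, d = 1e-8, tol = 1e-14, max_iter = 100)
  expect_equal(unname(pr$scores), rep(0.2, 5), tolerance = 1e-6)
})

test_that("fixed point matches the dense linear solve on random graphs", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(5:50, 1)
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, 0.2)
    A <- A + t(A)
    G <- A * matrix(runif(n * n, 0.1, 2), n, n)
    G <- (G + t(G)) / 2
    dimnames(G) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
    pr <- weighted_pagerank(G, d = 0.85, tol = 1e-12, max_iter = 100000)
    expect_lt(max(abs(pr$scores - pagerank_solve(G, 0.85))), 1e-8)
  }
})

test_that("scores sum to one at every iteration", {
  set.seed(42)
  n <- 30
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, 0.15)
  A <- A + t(A)
  G <- A * matrix(runif(n * n), n, n); G <- (G + t(G)) / 2
  dimnames(G) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  # isolate a node so the dangling redistribution path is exercised
  G[, 1] <- 0; G[1, ] <- 0
  for (k in 1:5) {
    pr <- suppressWarnings(weighted_pagerank(G, tol = 1e-16, max_iter = k))
    expect_equal(sum(pr$scores), 1, tolerance = 1e-9)
  }
  full <- suppressWarnings(weighted_pagerank(G, tol = 1e-12,
                                             max_iter = 100000))
  expect_equal(sum(full$scores), 1, tolerance = 1e-9)
  expect_true(all(full$scores >= (1 - 0.85) / n - 1e-12))
})

test_that("equal weights reproduce unweighted PageRank (igraph oracle)", {
  for (s in 1:5) {
    edges <- random_edges(30, 60, seed = s)
    net <- reconstruct_network(edges, unique(c(edges$from, edges$to)))
    G <- net$A * 0.37   # any constant weight
    pr <- weighted_pagerank(G, d = 0.85, tol = 1e-13, max_iter = 100000)
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes)
    ig <- igraph::page_rank(g, damping = 0.85)$vector
    expect_lt(max(abs(pr$scores[net$nodes] - ig[net$nodes])), 1e-8)
  }
})

test_that("a strongly weighted leaf outranks its uniform-weight self", {
  # star network: hub h with leaves l1..l6; boosting one leaf edge must
  # promote that leaf (hub moderation)
  nodes <- c("h", paste0("l", 1:6))
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  A["h", paste0("l", 1:6)] <- 1
  A[paste0("l", 1:6), "h"] <- 1
  unif <- weighted_pagerank(A * 1.0, tol = 1e-12, max_iter = 10000)$scores
  W <- A * 1.0
  W["h", "l1"] <- W["l1", "h"] <- 10
  boosted <- weighted_pagerank(W, tol = 1e-12, max_iter = 10000)$scores
  expect_lt(rank(-boosted)[["l1"]], rank(-unif)[["l1"]])
  expect_gt(boosted[["l1"]], unif[["l1"]])
  # raising a leaf's incident weight never lowers its score
  W2 <- A * 1.0
  for (mult in c(2, 5, 10)) {
    W2["h", "l2"] <- W2["l2", "h"] <- mult
    sc <- weighted_pagerank(W2, tol = 1e-12, max_iter = 10000)$scores
    expect_gte(sc[["l2"]], unif[["l2"]] - 1e-12)
    unif <- sc
  }
})

test_that("stability selection counts run appearances inclusively", {
  runs <- list(c("a", "b"), c("a", "c"), c("a", "b"))
  sel <- stability_select(runs, b = 2)
  expect_setequal(sel$selected, c("a", "b"))
  expect_equal(unname(sel$counts["a"]), 3L)
  # boundary behaviours: union at b = 1, persistent core at b = t
  expect_setequal(stability_select(runs, 1)$selected, c("a", "b", "c"))
  expect_equal(stability_select(runs, 3)$selected, "a")
  expect_error(stability_select(runs, 4),
               class = "omnirank_validation_error")
})

test_that("selection equals a brute-force counter on random runs", {
  set.seed(6)
  genes <- sprintf("g%03d", 1:200)
  runs <- lapply(1:50, function(i) sample(genes, 30))
  sel <- stability_select(runs, b = 30)
  cnt <- table(unlist(runs))
  expect_setequal(sel$selected, names(cnt)[cnt >= 30])
})

test_that("degenerate PageRank inputs are rejected", {
  G <- matrix(1, 2, 2)
  expect_error(weighted_pagerank(G, d = 1.5),
               class = "omnirank_validation_error")
  expect_error(weighted_pagerank(G, tol = 0),
               class = "omnirank_validation_error")
  expect_error(weighted_pagerank(matrix(numeric(0), 0, 0)),
               class = "omnirank_validation_error")
  # an asymmetric weighted path cannot converge in one sweep
  P <- matrix(c(0, 1, 0, 1, 0, 5, 0, 5, 0), 3, 3)
  expect_warning(weighted_pagerank(P, tol = 1e-16, max_iter = 1),
                 "did not reach")
})
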