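path_graph <- function(n) {
  g <- igraph::make_ring(n, circular = FALSE)
  igraph::V(g)$name <- paste0("v", seq_len(n))
  g
}

test_that("module diameter matches canonical path-graph cases", {
  g5 <- path_graph(5)
  expect_equal(module_diameter(g5, c("v2", "v3")), 1)
  expect_equal(module_diameter(g5, c("v1", "v5")), 4)
  expect_error(module_diameter(g5, "v1"), "at least 2")
})

test_that("distances agree with an independent BFS oracle", {
  sim <- simulate_interactome(15, attachment = 2, seed = 3)
  g <- sim$graph
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  D <- bfs_all_pairs(A)
  set.seed(4)
  for (i in 1:20) {
    idx <- sample(15, sample(2:5, 1))
    expect_equal(module_diameter(g, igraph::V(g)$name[idx]),
                 oracle_ds_mean(D, idx))
  }
})

test_that("Glass' Delta is centred at zero for the null's own modules", {
  sim <- simulate_interactome(40, seed = 5)
  g <- sim$graph
  set.seed(6)
  deltas <- vapply(1:30, function(i) {
    targets <- sample(igraph::V(g)$name, 4)
    glass_delta(g, targets, n_random = 300)$delta
  }, numeric(1))
  expect_lt(abs(mean(deltas)), 0.5)
})

test_that("sampled and exhaustive nulls agree on a small graph", {
  sim <- simulate_interactome(12, seed = 7)
  g <- sim$graph
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  D <- bfs_all_pairs(A)
  combs <- combn(12, 3)
  exh <- apply(combs, 2, function(s) oracle_ds_mean(D, s))
  res <- glass_delta(g, igraph::V(g)$name[c(1, 5, 9)],
                     n_random = 10000, seed = 8)
  expect_equal(res$mu_random, mean(exh), tolerance = 0.01)
  expect_equal(res$sigma_random, sd(exh), tolerance = 0.01)
  obs <- oracle_ds_mean(D, c(1, 5, 9))
  expect_equal(res$delta, (obs - res$mu_random) / res$sigma_random)
})

test_that("degree-matched null sampling runs and stays centred", {
  sim <- simulate_interactome(40, seed = 9)
  g <- sim$graph
  res <- glass_delta(g, igraph::V(g)$name[1:4], n_random = 200, seed = 10,
                     degree_matched = TRUE)
  expect_true(is.finite(res$delta))
  expect_equal(res$n_random, 200)
})

test_that("separation reproduces the 10-path worked example", {
  g <- path_graph(10)
  sep <- interactome_separation(g, c("v1", "v2"), c("v9", "v10"))
  # nearest-other-set distances: 7, 8 from A and 7, 8 from B
  expect_equal(sep$d_ab, 7.5)
  expect_equal(sep$d_aa, 1)
  expect_equal(sep$d_bb, 1)
  expect_equal(sep$s_ab, 6.5)
  expect_gt(sep$s_ab, 0)
  expect_equal(sep$d_min_ab, 7)
  expect_equal(sep$d_mean_ab, mean(c(8, 9, 7, 8)))
})

test_that("identical modules overlap maximally", {
  g <- path_graph(6)
  A <- c("v2", "v4")
  sep <- interactome_separation(g, A, A)
  expect_equal(sep$d_ab, 0)
  expect_equal(sep$s_ab, -module_diameter(g, A))
  expect_lte(sep$s_ab, 0)
})

test_that("separation is symmetric and signs follow planted overlap", {
  sim <- simulate_interactome(
    200, seed = 12,
    modules = list(list(size = 8, lambda = 1),
                   list(size = 8, lambda = 1, share_with = 1, omega = 0.75)))
  g <- sim$graph
  s12 <- interactome_separation(g, sim$targets[[1]], sim$targets[[2]])
  s21 <- interactome_separation(g, sim$targets[[2]], sim$targets[[1]])
  expect_equal(s12$s_ab, s21$s_ab)
  # three quarters shared proteins: overlapping modules
  expect_lt(s12$s_ab, 0)
})

test_that("annotation similarity follows the shared-term specificity rule", {
  ann <- data.frame(
    term = c("t1", "t1", "t2", "t2", "t2", "t2", "t3", rep("t4", 10)),
    protein = c("a", "b", "a", "b", "c", "d", "e",
                c("a", "b", paste0("x", 1:8))),
    stringsAsFactors = FALSE)
  # smallest shared term has 2 members -> similarity 1
  expect_equal(annotation_similarity(ann, "a", "b"), 1)
  # only shared terms of sizes 4 and 10 -> 2/4
  ann2 <- ann[ann$term != "t1", ]
  expect_equal(annotation_similarity(ann2, "a", "b"), 0.5)
  expect_equal(annotation_similarity(ann, "a", "e"), 0)
  expect_equal(annotation_similarity(ann, "a", "unseen"), 0)
  # set similarity averages over unordered pairs
  expect_equal(annotation_set_similarity(ann, c("a", "b", "e")),
               mean(c(1, 0, 0)))
})

test_that("similarity is bounded and non-increasing in shared-term size", {
  sizes <- c(2, 5, 20, 100)
  vals <- 2 / sizes
  expect_true(all(vals <= 1 & vals >= 0))
  expect_true(all(diff(vals) < 0))
})

test_that("tanimoto counts set bits of intersection over union", {
  expect_equal(tanimoto("1011", "1011"), 1)
  expect_equal(tanimoto("1100", "0011"), 0)
  expect_equal(tanimoto("1011", "1001"), 2 / 3)
  expect_equal(tanimoto(c(1, 0, 1, 1), c(1, 0, 0, 1)), 2 / 3)
  expect_error(tanimoto("101", "10"), "length")
  expect_warning(z <- tanimoto("000", "000"), "empty")
  expect_equal(z, 0)
})

test_that("interactome files round-trip through the readers", {
  el <- data.frame(a = c("p1", "p2", "p3", "p5"),
                   b = c("p2", "p3", "p1", "p6"))
  f <- tempfile()
  write.table(el, f, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  g <- read_interactome(f)
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 4)
  g_lcc <- read_interactome(f, lcc = TRUE)
  expect_equal(igraph::vcount(g_lcc), 3)
  ts <- data.frame(drug = c("d1", "d1", "d2"),
                   protein = c("p1", "p9", "p2"))
  f2 <- tempfile()
  write.table(ts, f2, sep = "\t", row.names = FALSE, quote = FALSE)
  sets <- read_target_sets(f2, graph = g)
  expect_equal(sets$d1, "p1")
  expect_equal(unname(attr(sets, "dropped")["d1"]), 1L)
})
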