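# brute-force count of admissible typed links among labelled nodes
oracle_max_links <- function(s, w) {
  strong <- c(rep(TRUE, s), rep(FALSE, w))
  n <- length(strong)
  if (n < 2) return(0)
  total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    total <- total + 1 +                      # emergent always possible
      (strong[i]) + (strong[j])               # one directed slot per strong end
  }
  total
}

test_that("the maximum-links formula reproduces the screen-scale count", {
  expect_equal(max_possible_links(28, 214), 35909)
  expect_equal(max_possible_links(0, 2), 1)
  expect_equal(max_possible_links(2, 2), 12)
  expect_equal(max_possible_links(2, 2), oracle_max_links(2, 2))
  expect_error(max_possible_links(-1, 3), "non-negative")
})

test_that("the formula equals brute-force enumeration for all small s, w", {
  for (s in 0:6) for (w in 0:6)
    expect_equal(max_possible_links(s, w), oracle_max_links(s, w))
})

test_that("sparseness is observed over admissible links", {
  expect_equal(network_sparseness(1832, s = 28, w = 214), 1832 / 35909)
  expect_equal(round(100 * network_sparseness(1832, s = 28, w = 214)), 5)
  expect_equal(network_sparseness(0, s = 5, w = 10), 0)
  expect_warning(val <- network_sparseness(0, s = 0, w = 1), "undefined")
  expect_true(is.nan(val))
})

test_that("a saturated admissible edge set has sparseness one", {
  strong <- c(s1 = TRUE, w1 = FALSE, w2 = FALSE)
  edges <- data.frame(
    from = c("w1", "w1", "w1", "w2", "w2"),
    to = c("w2", "s1", "s1", "s1", "s1"),
    type = c("emergent", "emergent", "positive", "emergent", "negative"),
    stringsAsFactors = FALSE)
  net <- assemble_perturbome(edges, strong)
  expect_equal(nrow(net$edges), 5)
  expect_equal(network_sparseness(net), 1)
})

test_that("assembly enforces typed-edge admissibility", {
  strong <- c(a = TRUE, b = FALSE, c = FALSE)
  # no calls: edgeless network over all drugs
  empty <- assemble_perturbome(
    data.frame(from = character(), to = character(), type = character()),
    strong)
  expect_equal(nrow(empty$nodes), 3)
  expect_equal(nrow(empty$edges), 0)
  # one uni-directional negative call
  one <- assemble_perturbome(
    data.frame(from = "b", to = "a", type = "negative"), strong)
  expect_equal(nrow(one$edges), 1)
  expect_equal(unname(one$counts["negative"]), 1L)
  # directed edge at a weak drug is inadmissible; emergent is fine
  mixed <- assemble_perturbome(
    data.frame(from = c("a", "a"), to = c("b", "b"),
               type = c("positive", "emergent")), strong)
  expect_equal(mixed$edges$type, "emergent")
  dropped <- attr(mixed, "dropped")
  expect_equal(dropped$reason, "directed edge at weak drug")
  # unknown drug rejected with diagnostic
  unk <- assemble_perturbome(
    data.frame(from = "zz", to = "a", type = "negative"), strong)
  expect_equal(nrow(unk$edges), 0)
  expect_match(attr(unk, "dropped")$reason, "unknown")
})

test_that("a planted edge list is reassembled verbatim", {
  set.seed(1)
  drugs <- sprintf("d%02d", 1:10)
  strong <- stats::setNames(rep(c(TRUE, FALSE), c(4, 6)), drugs)
  planted <- data.frame(
    from = c("d05", "d06", "d01", "d02", "d07"),
    to = c("d01", "d02", "d02", "d09", "d08"),
    type = c("negative", "positive", "negative", "emergent", "emergent"),
    stringsAsFactors = FALSE)
  net <- assemble_perturbome(planted, strong)
  expect_equal(net$edges[order(net$edges$from), ],
               planted[order(planted$from), ], ignore_attr = TRUE)
})

test_that("degree profiles split incoming, outgoing and emergent degree", {
  strong <- c(a = TRUE, b = TRUE, c = FALSE)
  net <- assemble_perturbome(
    data.frame(from = c("b", "a"), to = c("a", "c"),
               type = c("negative", "emergent")), strong)
  prof <- degree_profiles(net)$per_node
  expect_equal(prof$in_degree[prof$drug == "a"], 1)
  expect_equal(prof$out_degree[prof$drug == "b"], 1)
  expect_equal(prof$emergent_degree[prof$drug == "a"], 1)
  expect_equal(prof$emergent_degree[prof$drug == "c"], 1)
  expect_equal(prof$in_degree[prof$drug == "c"], 0)

  # hub fixture: 20 weak drugs all modulating one strong hub
  weak <- sprintf("w%02d", 1:20)
  strong2 <- stats::setNames(c(TRUE, rep(FALSE, 20)), c("hub", weak))
  hubnet <- assemble_perturbome(
    data.frame(from = weak, to = "hub", type = "negative"), strong2)
  prof2 <- degree_profiles(hubnet)$per_node
  expect_equal(prof2$in_degree[prof2$drug == "hub"], 20)
  expect_equal(prof2$out_degree[prof2$drug == "hub"], 0)
  expect_true(all(prof2$out_degree[prof2$drug != "hub"] == 1))
})

test_that("network export writes SIF and GraphML", {
  strong <- c(a = TRUE, b = FALSE)
  net <- assemble_perturbome(
    data.frame(from = "b", to = "a", type = "negative"), strong)
  sif <- tempfile(fileext = ".sif")
  write_network_sif(net, sif)
  expect_equal(readLines(sif), "b negative a")
  gml <- tempfile(fileext = ".graphml")
  write_network_graphml(net, gml)
  expect_true(any(grepl("graphml", readLines(gml, n = 3))))
})

test_that("label-swap remaps never include the combination's own drugs", {
  singles <- sprintf("d%d", 1:6)
  combos <- list(list(id = "d1+d2", drug_a = "d1", drug_b = "d2"),
                 list(id = "d3+d4", drug_a = "d3", drug_b = "d4"))
  set.seed(2)
  for (i in 1:20) {
    remap <- perturbome:::.remap_pairs(combos, singles)
    expect_false(any(c("d1", "d2") %in% remap[["d1+d2"]]))
    expect_false(any(c("d3", "d4") %in% remap[["d3+d4"]]))
    expect_equal(length(unique(remap[["d1+d2"]])), 2)
  }
})

test_that("randomization is seed-reproducible and directionally sound", {
  sim <- simulate_screen(screen_config(
    n_drugs = 8, n_strong = 8, n_features = 10, strong_magnitude = 0.3,
    plate_effect_sd = 0, controls_per_plate = 32, seed = 31))
  wt <- aggregate_wells(sim$cells, sim$meta)
  vec <- perturbation_vectors(wt)
  r1 <- randomize_perturbome(vec, n_iter = 8, seed = 99)
  r2 <- randomize_perturbome(vec, n_iter = 8, seed = 99)
  expect_identical(attr(r1, "null_counts"), attr(r2, "null_counts"))
  expect_error(randomize_perturbome(vec, n_iter = 1, seed = 1), "at least 2")
  # all combinations are exact superpositions: comparing them against
  # unrelated singles inflates negative and emergent calls
  expect_gt(r1$null_mean[r1$type == "negative"],
            r1$observed[r1$type == "negative"])
  expect_gt(r1$null_mean[r1$type == "emergent"],
            r1$observed[r1$type == "emergent"])
  # z is negative whenever the null varies at all; a saturated null
  # (every iteration producing the identical count) has no s.d.
  z_neg <- r1$z[r1$type == "negative"]
  z_em <- r1$z[r1$type == "emergent"]
  expect_true(is.na(z_neg) || z_neg < 0)
  expect_true(is.na(z_em) || z_em < 0)
})
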