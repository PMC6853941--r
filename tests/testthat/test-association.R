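test_that("Cohen's d matches hand computations and is antisymmetric", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  # pooled s = 1 -> d = (2 - 5) / 1 = -3
  expect_equal(cohens_d(c(1, 2, 3), c(4, 5, 6)), -3)
  set.seed(1)
  x <- rnorm(20); y <- rnorm(20, 1)
  expect_equal(cohens_d(x, y), -cohens_d(y, x))
  expect_warning(d <- cohens_d(c(1, 1), c(2, 2)), "undefined")
  expect_true(is.na(d))
  expect_error(cohens_d(1, 1:3), "at least 2")
})

test_that("bootstrap means are seed-reproducible with the documented default", {
  expect_equal(formals(bootstrap_means)$n_boot, 10000L)
  b1 <- bootstrap_means(c(1, 2, 3, 4), n_boot = 50, seed = 7)
  b2 <- bootstrap_means(c(1, 2, 3, 4), n_boot = 50, seed = 7)
  expect_identical(b1$means, b2$means)
  bc <- bootstrap_means(rep(2.5, 10), n_boot = 30, seed = 1)
  expect_true(all(bc$means == 2.5))
  expect_equal(unname(bc$ci), c(2.5, 2.5))
})

test_that("the bootstrap spread matches the CLT oracle", {
  set.seed(2)
  x <- rnorm(100, 5, 2)
  b <- bootstrap_means(x, n_boot = 4000, seed = 3)
  # s.d. of resampled means ~ sample s.d. / sqrt(n)
  expect_equal(sd(b$means), sd(x) / sqrt(100), tolerance = 0.1)
  expect_equal(b$mean, mean(x), tolerance = 0.1)
})

test_that("binary feature association matches the hypergeometric oracle", {
  tab <- data.frame(
    label = rep(c("negative", "none"), each = 10),
    shared = c(rep(1, 10), rep(0, 10)))
  res <- feature_association(tab, "shared", "negative")
  # both one-sided extremes of the 10/10 margin table
  p_oracle <- 2 * dhyper(10, 10, 10, 10)
  expect_equal(res$p, p_oracle)
  expect_equal(res$direction, "enriched")
  expect_equal(res$test, "fisher")
})

test_that("planted enrichment and shifts are detected, null data are not", {
  set.seed(4)
  tab <- data.frame(
    label = rep(c("negative", "none"), each = 100),
    shared = c(rbinom(100, 1, 0.8), rbinom(100, 1, 0.2)),
    dist = c(rnorm(100, 2), rnorm(100, 2)))
  bin <- feature_association(tab, "shared", "negative")
  expect_true(bin$significant)
  expect_equal(bin$direction, "enriched")
  num <- feature_association(tab, "dist", "negative")
  expect_equal(num$test, "mann-whitney")
  expect_equal(num$direction, "none")
})

test_that("association p-values are calibrated under label permutation", {
  set.seed(5)
  x <- rnorm(100)
  hits <- vapply(1:300, function(i) {
    lab <- sample(rep(c("emergent", "none"), each = 50))
    feature_association(data.frame(label = lab, f = x), "f",
                        "emergent")$p <= 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.01)
  expect_lt(mean(hits), 0.12)
})

test_that("fingerprints recover planted type-specific shifts", {
  set.seed(6)
  n <- 120
  tab <- data.frame(
    label = rep(c("positive", "negative", "emergent", "none"), each = n),
    flat = rnorm(4 * n),
    marker = rnorm(4 * n))
  # shift the marker by one pooled s.d. in emergent pairs only
  tab$marker[tab$label == "emergent"] <-
    tab$marker[tab$label == "emergent"] + 1
  prof <- interaction_fingerprint(tab)
  expect_equal(dim(prof), c(3L, 2L))
  # identically distributed feature: profile near zero everywhere
  expect_lt(max(abs(prof[, "flat"])), 0.25)
  # the emergent group is one third of all interactions: the planted
  # one-sigma shift is diluted by the complement share
  expect_gt(prof["emergent", "marker"], 0.5)
  expect_lt(prof["positive", "marker"], 0)
})

test_that("a group profiled against itself is exactly zero", {
  set.seed(7)
  tab <- data.frame(label = rep("negative", 50), f = rnorm(50))
  prof <- interaction_fingerprint(tab)
  expect_equal(unname(prof["negative", "f"]), 0)
})
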