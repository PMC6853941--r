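test_that("exact superposition decomposes to the non-interaction point", {
  set.seed(1)
  a <- rnorm(8); b <- rnorm(8)
  dec <- decompose_pair(a, b, a + b)
  expect_equal(dec$alpha, 1)
  expect_equal(dec$beta, 1)
  expect_equal(dec$gamma, 0)
  expect_equal(dec$n_hat, rep(0, 8))
})

test_that("a pure out-of-plane combination is all gamma", {
  dec <- decompose_pair(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(dec$alpha, 0)
  expect_equal(dec$beta, 0)
  expect_equal(dec$gamma, 1)
  expect_equal(dec$n_hat, c(0, 0, 1))
})

test_that("the linear solve matches a direct numeric minimizer", {
  set.seed(2)
  for (i in 1:25) {
    a <- rnorm(10); b <- rnorm(10); cc <- rnorm(10)
    dec <- decompose_pair(a, b, cc)
    fr <- function(p) sum((p[1] * a + p[2] * b - cc)^2)
    opt <- optim(c(0, 0), fr, method = "BFGS",
                 control = list(reltol = 1e-14))
    expect_lt(max(abs(c(dec$alpha, dec$beta) - opt$par)), 1e-6)
    expect_lt(abs(dec$gamma - sqrt(opt$value)), 1e-6)
    # reconstruction identity and orthogonality of the residual direction
    recon <- dec$alpha * a + dec$beta * b + dec$gamma * dec$n_hat
    expect_lt(sqrt(sum((cc - recon)^2)), 1e-8 * sqrt(sum(cc^2)))
    expect_lt(abs(sum(dec$n_hat * a)), 1e-8)
    expect_lt(abs(sum(dec$n_hat * b)), 1e-8)
    expect_gte(dec$gamma, 0)
  }
})

test_that("decomposition swaps symmetrically and rescales covariantly", {
  set.seed(3)
  a <- rnorm(7); b <- rnorm(7); cc <- rnorm(7)
  d1 <- decompose_pair(a, b, cc)
  d2 <- decompose_pair(b, a, cc)
  expect_equal(d1$alpha, d2$beta)
  expect_equal(d1$beta, d2$alpha)
  expect_equal(d1$gamma, d2$gamma)
  lambda <- 2.5
  d3 <- decompose_pair(lambda * a, b, cc)
  expect_equal(d3$alpha, d1$alpha / lambda)
  expect_equal(d3$beta, d1$beta)
  expect_equal(d3$gamma, d1$gamma)
})

test_that("degenerate geometries are rejected with diagnostics", {
  a <- c(1, 2, 3)
  expect_error(decompose_pair(a, 2 * a, c(1, 0, 0)),
               class = "perturbome_degenerate")
  cond <- tryCatch(decompose_pair(a, 2 * a, c(1, 0, 0)),
                   perturbome_degenerate = function(e) e)
  expect_equal(cond$projection_1d, sum(a * c(1, 0, 0)) / sum(a * a))
  expect_error(decompose_pair(c(0, 0, 0), a, a), "zero")
})

test_that("the taxonomy enumerates 27 subspaces merging into 18 classes", {
  tax <- enumerate_interaction_classes()
  expect_equal(nrow(tax$subspaces), 27)
  expect_equal(unname(as.vector(tax$dimension_histogram)), c(1, 6, 12, 8))
  expect_equal(nrow(tax$classes), 18)
  expect_equal(length(unique(tax$classes$label)), 18)
  expect_equal(as.integer(tax$category_counts[c(
    "undirected", "uni-directional", "bi-directional")]), c(2L, 8L, 8L))
})

test_that("effect thresholds follow the MAD band and max-gamma rules", {
  pairs <- data.frame(
    drug_a = "X", drug_b = sprintf("p%d", 1:5),
    alpha = c(0.8, 0.9, 1.0, 1.1, 1.2), beta = 1,
    gamma = c(0.02, 0.05, 0.01, 0.04, 0.03),
    significant = FALSE)
  thr <- derive_effect_thresholds(pairs, mad_k = 2, min_pairs = 5)
  x <- thr[thr$drug == "X", ]
  expect_equal(x$center, 1.0)
  expect_equal(x$mad, 0.1)
  expect_equal(c(x$lo, x$hi), c(0.8, 1.2))
  expect_equal(x$t_gamma, 0.05)
  expect_false(x$fallback)
  # degenerate spread: any deviation exceeds the band
  pairs2 <- pairs
  pairs2$alpha <- 1
  thr2 <- derive_effect_thresholds(pairs2, min_pairs = 5)
  x2 <- thr2[thr2$drug == "X", ]
  expect_equal(x2$mad, 0)
  expect_equal(c(x2$lo, x2$hi), c(1, 1))
  # too few pairs per drug: global fallback, flagged
  thr3 <- derive_effect_thresholds(pairs, min_pairs = 6)
  expect_true(all(thr3$fallback))
})

test_that("classification matches a region-membership oracle on a grid", {
  thr <- data.frame(drug = "A", lo = 0.9, hi = 1.1, t_gamma = 0.1)
  grid <- expand.grid(alpha = c(0.5, 1.0, 1.5), beta = c(0.5, 1.0, 1.5),
                      gamma = c(0, 0.3))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    call <- classify_interaction(as.list(g), d_i = 10, thr, thr,
                                 "A", "B", di_cutoff = 3)
    sa <- if (g$alpha < 0.9) -1L else if (g$alpha > 1.1) 1L else 0L
    sb <- if (g$beta < 0.9) -1L else if (g$beta > 1.1) 1L else 0L
    em <- g$gamma > 0.1
    expect_equal(call$state_a, sa)
    expect_equal(call$state_b, sb)
    expect_equal(call$emergent, em)
    n_dir <- (sa != 0) + (sb != 0)
    expect_equal(nrow(call$edges), n_dir + em)
    if (sa == 0 && sb == 0 && !em)
      expect_equal(call$class, "A:unchanged|B:unchanged|emergent:absent")
  }
})

test_that("calls below the significance cutoff are non-interactions", {
  thr <- data.frame(drug = "A", lo = 0.9, hi = 1.1, t_gamma = 0.1)
  call <- classify_interaction(list(alpha = 0.2, beta = 1, gamma = 0.5),
                               d_i = 2.9, thr, thr, "A", "B")
  expect_false(call$significant)
  expect_equal(call$class, "A:unchanged|B:unchanged|emergent:absent")
  expect_equal(nrow(call$edges), 0)
})

test_that("a suppressed contribution yields a negative edge at the modulated drug", {
  thr <- data.frame(drug = "A", lo = 0.9, hi = 1.1, t_gamma = 0.1)
  call <- classify_interaction(list(alpha = 0.2, beta = 1.0, gamma = 0),
                               d_i = 8, thr, thr, "A", "B")
  expect_equal(call$category, "uni-directional")
  expect_equal(call$edges,
               data.frame(from = "B", to = "A", type = "negative",
                          stringsAsFactors = FALSE))
})
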