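test_that("treatments at the control centroid give the zero vector", {
  vals <- matrix(0.5, 12, 3)
  wt <- make_wt(vals, role = c(rep("control", 8), rep("single", 4)),
                drug_a = c(rep(NA, 8), rep("d1", 4)), replicate = c(1:8, 1:4))
  vec <- perturbation_vectors(wt)
  expect_equal(unname(vec$treatments$d1$mean), rep(0, 3))
  expect_equal(vec$treatments$d1$norm, 0)
})

test_that("a single replicate is its own mean vector", {
  set.seed(1)
  vals <- rbind(matrix(rnorm(30, 0.5, 0.01), 10), runif(3))
  wt <- make_wt(vals, role = c(rep("control", 10), "single"),
                drug_a = c(rep(NA, 10), "d1"), replicate = c(1:10, 1))
  vec <- perturbation_vectors(wt)
  expect_equal(vec$treatments$d1$mean,
               vec$treatments$d1$replicates[1, ])
})

test_that("a planted displacement is recovered within noise tolerance", {
  set.seed(2)
  d <- 6; n_ctrl <- 40; n_rep <- 8; sigma <- 0.01
  delta <- c(0.3, -0.2, 0.1, 0, 0.25, -0.15)
  vals <- rbind(matrix(rnorm(n_ctrl * d, 0.5, sigma), n_ctrl),
                sweep(matrix(rnorm(n_rep * d, 0.5, sigma), n_rep), 2,
                      delta, "+"))
  wt <- make_wt(vals, role = c(rep("control", n_ctrl), rep("single", n_rep)),
                drug_a = c(rep(NA, n_ctrl), rep("d1", n_rep)),
                replicate = c(seq_len(n_ctrl), seq_len(n_rep)))
  vec <- perturbation_vectors(wt)
  tol <- 4 * sigma * (1 / sqrt(n_rep) + 1 / sqrt(n_ctrl))
  expect_lt(max(abs(vec$treatments$d1$mean - delta)), tol)
})

test_that("D_P vanishes at the control mean and reduces to |z| in 1-D", {
  set.seed(3)
  y <- rnorm(60, 0.4, 0.05)
  t_val <- 0.55
  vals <- matrix(c(y, mean(y), t_val), ncol = 1)
  wt <- make_wt(vals, role = c(rep("control", 60), "single", "single"),
                drug_a = c(rep(NA, 60), "at_center", "off"),
                replicate = c(1:60, 1, 1))
  vec <- perturbation_vectors(wt)
  st <- perturbation_strength(vec, ridge = 0)
  expect_equal(st$dp[st$id == "at_center"], 0, tolerance = 1e-8)
  expect_equal(st$dp[st$id == "off"], abs(t_val - mean(y)) / sd(y),
               tolerance = 1e-6)
  expect_equal(st$n_components[1], 1L)
})

test_that("D_P^2 of null treatments follows the chi-square law", {
  set.seed(4)
  d <- 5; n_ctrl <- 500; n_trt <- 300
  vals <- matrix(rnorm((n_ctrl + n_trt) * d, 0.5, 0.04), n_ctrl + n_trt)
  wt <- make_wt(vals,
                role = c(rep("control", n_ctrl), rep("single", n_trt)),
                drug_a = c(rep(NA, n_ctrl), sprintf("t%03d", 1:n_trt)),
                replicate = 1L)
  vec <- perturbation_vectors(wt)
  st <- perturbation_strength(vec)
  k <- st$n_components[1]
  ks <- ks.test(st$dp^2, pchisq, df = k)
  expect_gt(ks$p.value, 0.01)
})

test_that("D_P is invariant under axis-wise affine rescaling", {
  set.seed(5)
  d <- 4; n_ctrl <- 120
  vals <- rbind(matrix(rnorm(n_ctrl * d, 0.5, 0.05), n_ctrl),
                runif(d))
  roles <- c(rep("control", n_ctrl), "single")
  drugs <- c(rep(NA, n_ctrl), "d1")
  wt1 <- make_wt(vals, role = roles, drug_a = drugs,
                 replicate = c(1:n_ctrl, 1))
  scale_by <- c(2, 0.5, 7, 0.1)
  shift_by <- c(-1, 3, 0, 10)
  wt2 <- make_wt(sweep(sweep(vals, 2, scale_by, "*"), 2, shift_by, "+"),
                 role = roles, drug_a = drugs, replicate = c(1:n_ctrl, 1))
  dp1 <- perturbation_strength(perturbation_vectors(wt1),
                               n_components = 4, ridge = 0)
  dp2 <- perturbation_strength(perturbation_vectors(wt2),
                               n_components = 4, ridge = 0)
  expect_equal(dp1$dp[dp1$id == "d1"], dp2$dp[dp2$id == "d1"],
               tolerance = 1e-6)
})

test_that("strength calls recover the planted strong/weak partition", {
  sim <- simulate_screen(screen_config(seed = 21))
  wt <- normalize_wells(aggregate_wells(sim$cells, sim$meta))
  vec <- perturbation_vectors(wt)
  st <- perturbation_strength(vec)
  by_drug <- attr(st, "by_drug")
  expect_equal(unname(by_drug[names(sim$truth$strong)]),
               unname(sim$truth$strong))
})

test_that("cosine similarity behaves on the canonical examples", {
  expect_equal(cosine_similarity(c(3, 1, 2), c(3, 1, 2)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), 1 / sqrt(2))
  v <- rnorm(5)
  expect_equal(cosine_similarity(v, 2.5 * v), 1)
  expect_equal(cosine_similarity(v, -0.3 * v), -1)
  expect_warning(s <- cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
  expect_true(is.na(s))
  expect_error(cosine_similarity(1:3, 1:4), "dimension")
})

test_that("norm filter keeps vectors beyond mean + k sd of control norms", {
  set.seed(6)
  ctrl <- matrix(rnorm(200 * 4), 200, 4)
  ctrl <- ctrl / sqrt(rowSums(ctrl^2)) * rnorm(200, 1, 0.1)
  norms <- sqrt(rowSums(ctrl^2))
  thr_oracle <- mean(norms) + 2 * sd(norms)
  mk <- function(id, norm) list(id = id, role = "single", batch = 1L,
                                norm = norm)
  vecs <- structure(list(
    treatments = list(below = mk("below", thr_oracle - 1e-3),
                      above = mk("above", thr_oracle + 1e-3),
                      way_up = mk("way_up", thr_oracle + 1)),
    controls = list("1" = ctrl)), class = "perturbation_vectors")
  kept <- norm_filter(vecs, k_sd = 2)
  expect_setequal(as.character(kept), c("above", "way_up"))
  expect_equal(unname(attr(kept, "threshold")["1"]), thr_oracle)
})
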