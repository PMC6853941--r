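# hand-rolled all-pairs BFS, independent oracle for graph distances
bfs_all_pairs <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (u in which(adj[v, ] > 0)) {
        if (!is.finite(dist[u])) {
          dist[u] <- dist[v] + 1
          q <- c(q, u)
        }
      }
    }
    D[s, ] <- dist
  }
  D
}

# nearest-same-set mean distance from a BFS distance matrix
oracle_ds_mean <- function(D, idx) {
  M <- D[idx, idx, drop = FALSE]
  diag(M) <- Inf
  d <- apply(M, 1, min)
  mean(d[is.finite(d)])
}

# type-7 quantile computed by hand (sort + linear interpolation)
oracle_quantile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  xs[lo] + (h - lo) * (xs[min(lo + 1, n)] - xs[lo])
}

# quick well_table from a values matrix and minimal metadata
make_wt <- function(values, role, drug_a = NA_character_,
                    drug_b = NA_character_, replicate = 1L,
                    plate = "p1", batch = 1L, cell_count = 100L,
                    t_order = NULL) {
  n <- nrow(values)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("f%02d", seq_len(ncol(values)))
  meta <- data.frame(
    plate = rep_len(plate, n), well = sprintf("w%03d", seq_len(n)),
    row = rep(seq_len(16), length.out = n),
    col = rep(seq_len(24), each = 16, length.out = n),
    batch = rep_len(batch, n), role = rep_len(role, n),
    drug_a = rep_len(drug_a, n), drug_b = rep_len(drug_b, n),
    replicate = rep_len(replicate, n),
    cell_count = rep_len(cell_count, n),
    stringsAsFactors = FALSE)
  meta$t_order <- if (is.null(t_order)) meta$replicate
                  else rep_len(t_order, n)
  rownames(values) <- paste(meta$plate, meta$well, sep = ":")
  well_table(values, meta)
}

# 30-feature fixture with planted keep/remove structure for the filter
# cascade: 10 clean, 5 noisy (controls too variable), 5 non-reproducible,
# 5 inert (constant), 5 redundant (correlated copies with smaller effect)
filter_fixture <- function(seed = 1) {
  set.seed(seed)
  n_drugs <- 8; n_reps <- 3; n_ctrl <- 8
  drugs <- sprintf("d%02d", seq_len(n_drugs))
  shift <- matrix(rnorm(n_drugs * 10), n_drugs, 10) * 0.3
  meta <- list(); vals <- list()
  add <- function(plate, role, drug, rep) {
    meta[[length(meta) + 1]] <<- data.frame(
      plate = plate, role = role, drug_a = drug, replicate = rep,
      stringsAsFactors = FALSE)
  }
  for (p in c("p1", "p2")) for (j in seq_len(n_ctrl)) add(p, "control", NA, j)
  for (d in seq_len(n_drugs)) for (r in seq_len(n_reps))
    add(if (d <= n_drugs / 2) "p1" else "p2", "single", drugs[d], r)
  meta <- do.call(rbind, meta)
  n <- nrow(meta)
  is_ctrl <- meta$role == "control"
  didx <- match(meta$drug_a, drugs)

  clean <- sapply(seq_len(10), function(j) {
    v <- 0.5 + rnorm(n, 0, 0.005)
    v[!is_ctrl] <- v[!is_ctrl] + shift[didx[!is_ctrl], j]
    v
  })
  noisy <- sapply(seq_len(5), function(j) 0.5 + rnorm(n, 0, 0.2))
  # replicate 1 and 2 carry opposite drug responses, replicate 3 a
  # shuffled one: reproducibility across replicates is zero by design
  nonrep <- sapply(seq_len(5), function(j) {
    pat <- rnorm(n_drugs) * 0.3
    perm <- sample(n_drugs)
    v <- 0.5 + rnorm(n, 0, 0.005)
    tr <- which(!is_ctrl)
    sgn <- c(1, -1, 0)[meta$replicate[tr]]
    v[tr] <- v[tr] + ifelse(sgn != 0, sgn * pat[didx[tr]],
                            pat[perm[didx[tr]]])
    v
  })
  inert <- matrix(0.5, n, 5)
  redundant <- sapply(seq_len(5), function(j) {
    v <- 0.5 + rnorm(n, 0, 0.005)
    v[!is_ctrl] <- v[!is_ctrl] + 0.6 * shift[didx[!is_ctrl], j]
    v
  })
  values <- cbind(clean, noisy, nonrep, inert, redundant)
  colnames(values) <- c(sprintf("keep%02d", 1:10), sprintf("noisy%02d", 1:5),
                        sprintf("nonrep%02d", 1:5), sprintf("inert%02d", 1:5),
                        sprintf("redund%02d", 1:5))
  wellid <- sprintf("w%03d", seq_len(n))
  full_meta <- data.frame(
    plate = meta$plate, well = wellid,
    row = rep(seq_len(16), length.out = n),
    col = rep(seq_len(24), each = 16, length.out = n),
    batch = 1L, role = meta$role, drug_a = meta$drug_a,
    drug_b = NA_character_, replicate = meta$replicate,
    t_order = meta$replicate, cell_count = 100L,
    stringsAsFactors = FALSE)
  rownames(values) <- paste(full_meta$plate, wellid, sep = ":")
  well_table(values, full_meta)
}

# planted-interaction screen used by the recovery experiments: every drug
# has the same effect magnitude, 100 pairs carry planted coefficients
# drawn from a 10-archetype catalogue, the remaining pairs are planted
# non-interactions that calibrate the effect-size thresholds
recovery_screen <- function(seed, cell_noise_sd = 0.08) {
  set.seed(seed)
  drugs <- sprintf("drug%02d", 1:22)
  cmb <- t(combn(drugs, 2))
  archetypes <- rbind(
    c(0.4, 1.0, 0.0), c(1.6, 1.0, 0.0), c(1.0, 0.4, 0.0), c(1.0, 1.6, 0.0),
    c(0.4, 0.4, 0.0), c(1.6, 1.6, 0.0), c(0.4, 1.6, 0.0),
    c(1.0, 1.0, 0.3), c(0.4, 1.0, 0.3), c(1.6, 1.0, 0.3))
  sel <- sample(nrow(cmb), 100)
  ints <- data.frame(drug_a = cmb[sel, 1], drug_b = cmb[sel, 2],
                     alpha = archetypes[rep(1:10, each = 10), 1],
                     beta = archetypes[rep(1:10, each = 10), 2],
                     gamma = archetypes[rep(1:10, each = 10), 3],
                     stringsAsFactors = FALSE)
  screen_config(n_drugs = 22, n_strong = 22, n_features = 15,
                strong_magnitude = 0.3, plate_effect_sd = 0,
                cell_noise_sd = cell_noise_sd,
                interactions = ints, seed = seed + 1L)
}

# sign of a planted coefficient relative to the non-interaction point
planted_sign <- function(x, tol = 1e-9) {
  ifelse(x < 1 - tol, -1L, ifelse(x > 1 + tol, 1L, 0L))
}
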