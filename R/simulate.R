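#' Configuration for a synthetic perturbation screen
#'
#' Defines every generative parameter of [simulate_screen()].  Defaults
#' describe a desk-scale screen: a single batch of 384-well plates (16 x
#' 24), six replicate wells per single drug plated in temporal order, 16
#' DMSO control wells per plate, isotropic Gaussian cell-level noise
#' around well means and additive plate row/column artifacts.
#'
#' @param n_drugs number of drugs.
#' @param n_strong how many of them carry a strong morphological effect.
#' @param n_features feature-space dimension (>= 3 required for planted
#'   emergent components).
#' @param n_replicates replicate wells per single drug; the replicate
#'   index doubles as the temporal plating order.
#' @param controls_per_plate DMSO wells per plate.
#' @param plate_rows,plate_cols plate grid.
#' @param cells_per_well mean cell count (Poisson).
#' @param cell_noise_sd s.d. of per-cell feature noise around the well
#'   mean.
#' @param plate_effect_sd s.d. of the additive row and column effects.
#' @param baseline unperturbed feature level.
#' @param strong_magnitude,weak_magnitude norms of the single-drug effect
#'   vectors.
#' @param combinations `"all"` (every unordered drug pair gets one
#'   combination well), `"planted"` (only pairs listed in `interactions`)
#'   or `"none"`.
#' @param interactions optional data.frame with columns `drug_a`,
#'   `drug_b`, `alpha`, `beta`, `gamma` planting interaction coefficients;
#'   unlisted pairs default to non-interaction (1, 1, 0).
#' @param drifting_drugs drug ids whose cell counts drift across the
#'   temporal replicates (exercises the stability filter).
#' @param drift_rate per-replicate relative cell-count drift of those
#'   drugs.
#' @param heavy_tails use t(3)-scaled instead of Gaussian cell noise.
#' @param seed RNG seed; identical seeds give byte-identical screens.
#' @return a `screen_config` list.
#' @export
screen_config <- function(n_drugs = 12L, n_strong = 3L, n_features = 20L,
                          n_replicates = 6L, controls_per_plate = 64L,
                          plate_rows = 16L, plate_cols = 24L,
                          cells_per_well = 60, cell_noise_sd = 0.08,
                          plate_effect_sd = 0.01, baseline = 0.5,
                          strong_magnitude = 0.5, weak_magnitude = 0.03,
                          combinations = c("all", "planted", "none"),
                          interactions = NULL,
                          drifting_drugs = character(),
                          drift_rate = 0.12,
                          heavy_tails = FALSE, seed = NULL) {
  combinations <- match.arg(combinations)
  cfg <- as.list(environment())
  counts <- c(n_drugs, n_features, n_replicates, controls_per_plate,
              plate_rows, plate_cols, cells_per_well)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (n_strong < 0 || n_strong > n_drugs)
    stop("n_strong must lie in [0, n_drugs]")
  if (!is.null(interactions) && any(interactions$gamma != 0) &&
      n_features < 3)
    stop("planted emergent components need at least 3 feature dimensions")
  class(cfg) <- "screen_config"
  cfg
}

# internal: unit vector orthogonal to span(a, b), uniform on that sphere
.orth_unit <- function(a, b) {
  d <- length(a)
  z <- rnorm(d)
  z <- z - sum(z * a) / sum(a * a) * a
  b_perp <- b - sum(b * a) / sum(a * a) * a
  if (sum(b_perp^2) > 1e-24)
    z <- z - sum(z * b_perp) / sum(b_perp^2) * b_perp
  n <- sqrt(sum(z^2))
  if (n < 1e-12) return(.orth_unit(a, b))
  z / n
}

#' Simulate a perturbation screen with planted ground truth
#'
#' Generates a per-cell feature table, plate map and ground truth
#' according to the generative model: control wells fluctuate around the
#' baseline plus additive row/column plate effects; single-drug wells add
#' the drug's effect vector; combination wells realize
#' `c = alpha a + beta b + gamma n` with the emergent direction `n` drawn
#' uniformly from the orthogonal complement of the two single effects;
#' per-cell values are drawn around the well mean.
#'
#' @param cfg a [screen_config()].
#' @return An object of class `screen_sim`: list with `cells` (wide
#'   per-cell data.frame), `meta` (plate map) and `truth` (per-drug effect
#'   vectors and strong flags, per-pair planted coefficients and class
#'   labels, plate effects, config).
#' @export
simulate_screen <- function(cfg) {
  stopifnot(inherits(cfg, "screen_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  d <- cfg$n_features
  drugs <- sprintf("drug%02d", seq_len(cfg$n_drugs))
  strong <- stats::setNames(seq_len(cfg$n_drugs) <= cfg$n_strong, drugs)
  mags <- ifelse(strong, cfg$strong_magnitude, cfg$weak_magnitude)
  effects <- t(vapply(seq_along(drugs), function(i) {
    v <- rnorm(d); v / sqrt(sum(v^2)) * mags[i]
  }, numeric(d)))
  rownames(effects) <- drugs

  # planted interaction table
  if (cfg$combinations == "none") {
    pairs <- data.frame(drug_a = character(), drug_b = character(),
                        alpha = numeric(), beta = numeric(),
                        gamma = numeric(), stringsAsFactors = FALSE)
  } else if (cfg$combinations == "all") {
    cmb <- combn(drugs, 2)
    pairs <- data.frame(drug_a = cmb[1, ], drug_b = cmb[2, ],
                        alpha = 1, beta = 1, gamma = 0,
                        stringsAsFactors = FALSE)
    if (!is.null(cfg$interactions)) {
      for (i in seq_len(nrow(cfg$interactions))) {
        pi_ <- cfg$interactions[i, ]
        hit <- (pairs$drug_a == pi_$drug_a & pairs$drug_b == pi_$drug_b) |
               (pairs$drug_a == pi_$drug_b & pairs$drug_b == pi_$drug_a)
        pairs[hit, c("alpha", "beta", "gamma")] <-
          pi_[, c("alpha", "beta", "gamma")]
      }
    }
  } else {
    if (is.null(cfg$interactions))
      stop("combinations = 'planted' needs an interactions table")
    pairs <- cfg$interactions[, c("drug_a", "drug_b", "alpha", "beta",
                                  "gamma")]
  }
  if (nrow(pairs)) {
    tol <- 1e-12
    pairs$class <- .class_label(
      ifelse(pairs$alpha < 1 - tol, -1L, ifelse(pairs$alpha > 1 + tol, 1L, 0L)),
      ifelse(pairs$beta < 1 - tol, -1L, ifelse(pairs$beta > 1 + tol, 1L, 0L)),
      pairs$gamma > tol)
  } else pairs$class <- character(0)

  # well roster
  roster <- list()
  for (dr in drugs)
    for (r in seq_len(cfg$n_replicates))
      roster[[length(roster) + 1]] <- list(role = "single", drug_a = dr,
                                           drug_b = NA, replicate = r)
  if (nrow(pairs))
    for (i in seq_len(nrow(pairs)))
      roster[[length(roster) + 1]] <- list(role = "combination",
                                           drug_a = pairs$drug_a[i],
                                           drug_b = pairs$drug_b[i],
                                           replicate = 1L)
  cap <- cfg$plate_rows * cfg$plate_cols - cfg$controls_per_plate
  n_plates <- max(1L, ceiling(length(roster) / cap))
  per_plate <- cfg$plate_rows * cfg$plate_cols

  meta <- list()
  plate_row_eff <- plate_col_eff <- list()
  slot <- 0L
  add_well <- function(plate, pos, role, drug_a, drug_b, replicate) {
    r <- (pos - 1L) %% cfg$plate_rows + 1L
    cl <- (pos - 1L) %/% cfg$plate_rows + 1L
    list(plate = sprintf("plate%02d", plate),
         well = sprintf("%s%02d", LETTERS[(r - 1L) %% 26 + 1L], cl),
         row = r, col = cl, batch = 1L, role = role, drug_a = drug_a,
         drug_b = drug_b, replicate = replicate, t_order = replicate)
  }
  k <- 0L
  for (p in seq_len(n_plates)) {
    plate_row_eff[[p]] <- rnorm(cfg$plate_rows, 0, cfg$plate_effect_sd)
    plate_col_eff[[p]] <- rnorm(cfg$plate_cols, 0, cfg$plate_effect_sd)
    positions <- sample.int(per_plate, per_plate)
    used <- 0L
    for (j in seq_len(cfg$controls_per_plate)) {
      used <- used + 1L
      meta[[length(meta) + 1]] <-
        add_well(p, positions[used], "control", NA, NA, j)
    }
    while (used < per_plate && k < length(roster)) {
      k <- k + 1L; used <- used + 1L
      w <- roster[[k]]
      meta[[length(meta) + 1]] <-
        add_well(p, positions[used], w$role, w$drug_a, w$drug_b, w$replicate)
    }
  }
  meta <- do.call(rbind, lapply(meta, function(m)
    as.data.frame(m, stringsAsFactors = FALSE)))

  # well mean vectors
  n_hats <- vector("list", nrow(pairs))
  well_mean <- matrix(NA_real_, nrow(meta), d)
  for (i in seq_len(nrow(meta))) {
    p <- as.integer(sub("plate", "", meta$plate[i]))
    base <- cfg$baseline + plate_row_eff[[p]][meta$row[i]] +
      plate_col_eff[[p]][meta$col[i]]
    eff <- 0
    if (meta$role[i] == "single") {
      eff <- effects[meta$drug_a[i], ]
    } else if (meta$role[i] == "combination") {
      j <- which(pairs$drug_a == meta$drug_a[i] &
                   pairs$drug_b == meta$drug_b[i])[1]
      a <- effects[pairs$drug_a[j], ]; b <- effects[pairs$drug_b[j], ]
      eff <- pairs$alpha[j] * a + pairs$beta[j] * b
      if (pairs$gamma[j] != 0) {
        if (is.null(n_hats[[j]])) n_hats[[j]] <- .orth_unit(a, b)
        eff <- eff + pairs$gamma[j] * n_hats[[j]]
      }
    }
    well_mean[i, ] <- base + eff
  }

  # cell counts, with optional temporal drift
  lambda <- rep(cfg$cells_per_well, nrow(meta))
  drift <- meta$role == "single" & meta$drug_a %in% cfg$drifting_drugs
  lambda[drift] <- lambda[drift] *
    (1 + cfg$drift_rate * (meta$t_order[drift] - 1))
  counts <- pmax(1L, rpois(nrow(meta), lambda))

  cells <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    n <- counts[i]
    noise <- if (cfg$heavy_tails)
      matrix(rt(n * d, df = 3) * cfg$cell_noise_sd / sqrt(3), n, d)
    else matrix(rnorm(n * d, 0, cfg$cell_noise_sd), n, d)
    vals <- sweep(noise, 2, well_mean[i, ], "+")
    colnames(vals) <- sprintf("f%03d", seq_len(d))
    cells[[i]] <- data.frame(plate = meta$plate[i], well = meta$well[i],
                             cell = seq_len(n), vals,
                             stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL

  structure(list(
    cells = cells, meta = meta,
    truth = list(effects = effects, strong = strong,
                 interactions = pairs, n_hats = n_hats,
                 plate_row_effects = plate_row_eff,
                 plate_col_effects = plate_col_eff,
                 config = cfg)),
    class = "screen_sim")
}

#' @export
print.screen_sim <- function(x, ...) {
  cat("Synthetic screen:", nrow(x$meta), "wells,",
      nrow(x$cells), "cells,", x$truth$config$n_features, "features\n")
  cat("  drugs:", x$truth$config$n_drugs,
      "( strong:", sum(x$truth$strong), "),",
      "combinations:", sum(x$meta$role == "combination"), "\n")
  invisible(x)
}

#' Simulate a toy interactome with planted target modules
#'
#' Grows a scale-free-like background graph (preferential attachment) and
#' plants target modules of controlled localization: each module starts at
#' a random anchor and is grown one protein at a time, taking a random
#' network neighbour of the current module with probability `lambda`
#' (localized growth) and a uniform random outside protein otherwise.
#' `lambda = 1` gives a connected module, `lambda = 0` a uniform random
#' set.  A module spec may name an earlier module (`share_with`) and an
#' overlap fraction `omega` to share that fraction of its proteins.
#'
#' @param n_nodes background graph size.
#' @param attachment edges added per new node in the preferential
#'   attachment process (default 2).
#' @param modules list of module specs: each a list with `size`, `lambda`
#'   and optionally `share_with` (index of an earlier module) and `omega`.
#' @param seed optional RNG seed.
#' @return list with `graph` (igraph; nodes named `P0001`...) and
#'   `targets` (list of protein sets, one per module).
#' @export
simulate_interactome <- function(n_nodes = 200L, attachment = 2L,
                                 modules = list(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- sample_pa(n_nodes, m = attachment, directed = FALSE)
  V(g)$name <- sprintf("P%04d", seq_len(n_nodes))
  nodes <- V(g)$name
  grow <- function(size, lambda, start = character()) {
    if (size >= n_nodes) stop("module size must be below the node count")
    mod <- start
    if (!length(mod)) mod <- sample(nodes, 1)
    while (length(mod) < size) {
      nb <- setdiff(unique(unlist(lapply(mod, function(v)
        names(neighbors(g, v))))), mod)
      pick_local <- runif(1) < lambda && length(nb) > 0
      cand <- if (pick_local) nb else setdiff(nodes, mod)
      mod <- c(mod, sample(cand, 1))
    }
    mod
  }
  targets <- list()
  for (i in seq_along(modules)) {
    spec <- modules[[i]]
    start <- character()
    if (!is.null(spec$share_with)) {
      src <- targets[[spec$share_with]]
      n_share <- round(spec$omega * spec$size)
      if (n_share > length(src) || n_share > spec$size)
        stop("infeasible overlap for module ", i)
      start <- sample(src, n_share)
    }
    targets[[i]] <- grow(spec$size, spec$lambda, start)
  }
  list(graph = g, targets = targets)
}
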