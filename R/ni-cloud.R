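#' Non-interaction point cloud for a drug pair
#'
#' The expected phenotype of a non-interacting combination is the
#' superposition of the two single-drug vectors.  To carry the measurement
#' variability into that expectation, all pairwise sums of the two drugs'
#' replicate vectors are formed and each sum is perturbed once per control
#' well of the combination's plate, so the cloud inherits both replicate
#' and intra-plate variation.  Cloud size is therefore exactly
#' `nrow(reps_a) * nrow(reps_b) * nrow(controls)`.
#'
#' Two control-perturbation variants are provided.  `"multiplicative"`
#' (default) multiplies each sum element-wise by the control well's
#' profile expressed as a ratio to the plate control median (ratios close
#' to 1); `"additive"` adds the control well's deviation from the plate
#' control mean.
#'
#' @param reps_a,reps_b matrices of replicate displacement vectors (one
#'   row per replicate) for the two drugs.
#' @param controls matrix of raw control well profiles of the combination's
#'   plate (one row per control well, same feature space).
#' @param mode `"multiplicative"` or `"additive"`.
#'
#' @return An object of class `ni_cloud`: list with `points` (the cloud),
#'   `mean`, `n_a`, `n_b`, `n_controls` and `mode`.
#' @export
ni_cloud <- function(reps_a, reps_b, controls,
                     mode = c("multiplicative", "additive")) {
  mode <- match.arg(mode)
  reps_a <- rbind(reps_a); reps_b <- rbind(reps_b)
  controls <- rbind(controls)
  if (!nrow(controls))
    stop("no control wells on the combination's plate; ",
         "fall back to batch-level controls")
  if (!nrow(reps_a) || !nrow(reps_b))
    stop("each drug needs at least one replicate vector")
  na <- nrow(reps_a); nb <- nrow(reps_b); nk <- nrow(controls)
  d <- ncol(reps_a)
  sums <- reps_a[rep(seq_len(na), times = nb), , drop = FALSE] +
          reps_b[rep(seq_len(nb), each = na), , drop = FALSE]
  if (mode == "multiplicative") {
    m <- apply(controls, 2, median)
    safe <- abs(m) > 1e-8
    ratio <- controls
    ratio[, safe] <- sweep(controls[, safe, drop = FALSE], 2, m[safe], "/")
    ratio[, !safe] <- 1
    pts <- matrix(NA_real_, na * nb * nk, d)
    for (k in seq_len(nk))
      pts[(k - 1) * na * nb + seq_len(na * nb), ] <-
        sweep(sums, 2, ratio[k, ], "*")
  } else {
    dev <- sweep(controls, 2, colMeans(controls))
    pts <- matrix(NA_real_, na * nb * nk, d)
    for (k in seq_len(nk))
      pts[(k - 1) * na * nb + seq_len(na * nb), ] <-
        sweep(sums, 2, dev[k, ], "+")
  }
  colnames(pts) <- colnames(reps_a)
  structure(list(points = pts, mean = colMeans(pts),
                 n_a = na, n_b = nb, n_controls = nk, mode = mode),
            class = "ni_cloud")
}

#' @export
print.ni_cloud <- function(x, ...) {
  cat(sprintf("Non-interaction cloud: %d points (%d x %d x %d, %s mode)\n",
              nrow(x$points), x$n_a, x$n_b, x$n_controls, x$mode))
  invisible(x)
}

#' Interaction significance against the non-interaction cloud
#'
#' Mahalanobis distance D_I of the observed combination vector(s) from the
#' non-interaction cloud, measured in the cloud's PCA space reduced to the
#' smallest number of components explaining `variance_target` of its
#' variance.  D_I above the cutoff (default 3) flags the combination as
#' deviating beyond what replicate and intra-plate fluctuations explain.
#'
#' @param c_obs observed combination vector, or a matrix of one vector per
#'   row (all distances returned).
#' @param cloud an [ni_cloud()].
#' @param variance_target explained-variance target for the PCA reduction
#'   (default 0.90).
#' @param ridge diagonal ridge for a degenerate reduced covariance.
#'
#' @return numeric vector of D_I values with attribute `"n_components"`
#'   (the retained degrees of freedom).  A fully degenerate cloud (zero
#'   variance) yields 0 at the cloud point and `Inf` elsewhere, with a
#'   warning.
#' @export
interaction_significance <- function(c_obs, cloud, variance_target = 0.90,
                                     ridge = 1e-8) {
  stopifnot(inherits(cloud, "ni_cloud"))
  x <- rbind(c_obs)
  pca <- prcomp(cloud$points, center = TRUE, scale. = FALSE)
  ev <- pca$sdev^2
  if (sum(ev) < 1e-24) {
    warning("degenerate non-interaction cloud (zero variance)")
    di <- apply(x, 1, function(r)
      if (sqrt(sum((r - cloud$mean)^2)) < 1e-12) 0 else Inf)
    return(structure(di, n_components = 0L))
  }
  k <- which(cumsum(ev) / sum(ev) >= variance_target)[1]
  if (nrow(cloud$points) <= k)
    stop("cloud smaller than the number of retained components")
  proj <- pca$x[, seq_len(k), drop = FALSE]
  S <- cov(proj)
  if (rcond(S) < 1e-12)
    warning("near-singular cloud covariance, ridge-regularized")
  S <- S + diag(ridge, k)
  px <- predict(pca, newdata = x)[, seq_len(k), drop = FALSE]
  di <- sqrt(mahalanobis(px, colMeans(proj), S))
  structure(unname(di), n_components = k)
}

#' Decompose and call all combinations of a screen
#'
#' Runs the full interaction-calling pipeline on a set of perturbation
#' vectors: for every combination treatment whose two constituent singles
#' are available, the replicate-mean single vectors enter the
#' decomposition, a non-interaction cloud is built from the replicate
#' vectors and the same-plate controls, D_I is computed, effect-size
#' thresholds are derived from the non-significant pairs, and every pair
#' is classified.
#'
#' @param vectors a [perturbation_vectors()] object.
#' @param di_cutoff D_I significance cutoff (default 3).
#' @param mad_k MAD multiplier for the alpha/beta bands (default 2).
#' @param variance_target PCA explained-variance target (default 0.90).
#' @param cloud_mode control-perturbation variant for [ni_cloud()].
#' @param min_pairs per-drug minimum for [derive_effect_thresholds()].
#' @param remap optional named list mapping a combination id to a
#'   character pair `c(C, D)` of replacement single drugs; used by the
#'   label-swap randomization.
#' @param thresholds optional [derive_effect_thresholds()] result to reuse
#'   (e.g. the observed screen's thresholds during randomization); by
#'   default thresholds are derived from this run's non-significant pairs.
#'
#' @return An object of class `interaction_calls`: list with `pairs`
#'   (data.frame of coefficients, D_I, class and category per pair),
#'   `edges` (all emitted edges), `thresholds` and `params`.
#' @export
interaction_calls <- function(vectors, di_cutoff = 3, mad_k = 2,
                              variance_target = 0.90,
                              cloud_mode = c("multiplicative", "additive"),
                              min_pairs = 5L, remap = NULL,
                              thresholds = NULL) {
  stopifnot(inherits(vectors, "perturbation_vectors"))
  cloud_mode <- match.arg(cloud_mode)
  trts <- vectors$treatments
  combos <- Filter(function(tr) tr$role == "combination", trts)
  rows <- list()
  for (tr in combos) {
    ab <- c(tr$drug_a, tr$drug_b)
    if (!is.null(remap) && !is.null(remap[[tr$id]])) ab <- remap[[tr$id]]
    sA <- trts[[ab[1]]]; sB <- trts[[ab[2]]]
    if (is.null(sA) || is.null(sB)) next
    plate <- tr$plate[1]
    ctrl_rows <- vectors$control_rows[[as.character(plate)]]
    cvec <- tr$mean
    cloud <- ni_cloud(sA$replicates, sB$replicates, ctrl_rows,
                      mode = cloud_mode)
    d_i <- suppressWarnings(
      interaction_significance(cvec, cloud,
                               variance_target = variance_target))
    dec <- tryCatch(decompose_pair(sA$mean, sB$mean, cvec),
                    error = function(e) NULL)
    if (is.null(dec)) next
    rows[[tr$id]] <- data.frame(
      combination = tr$id, drug_a = tr$drug_a, drug_b = tr$drug_b,
      ref_a = ab[1], ref_b = ab[2],
      alpha = dec$alpha, beta = dec$beta, gamma = dec$gamma,
      d_i = as.numeric(d_i), significant = as.numeric(d_i) > di_cutoff,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    warning("no decomposable combinations (zero or collinear single vectors)")
    empty <- data.frame(from = character(), to = character(),
                        type = character(), stringsAsFactors = FALSE)
    return(structure(list(
      pairs = data.frame(combination = character(), class = character(),
                         stringsAsFactors = FALSE),
      edges = empty, thresholds = NULL,
      params = list(di_cutoff = di_cutoff, mad_k = mad_k,
                    variance_target = variance_target,
                    cloud_mode = cloud_mode, min_pairs = min_pairs)),
      class = "interaction_calls"))
  }
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  thr <- if (!is.null(thresholds)) thresholds
  else derive_effect_thresholds(
    data.frame(drug_a = pairs$ref_a, drug_b = pairs$ref_b,
               alpha = pairs$alpha, beta = pairs$beta, gamma = pairs$gamma,
               significant = pairs$significant, stringsAsFactors = FALSE),
    mad_k = mad_k, min_pairs = min_pairs)
  calls <- lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    classify_interaction(
      list(alpha = p$alpha, beta = p$beta, gamma = p$gamma), p$d_i,
      .thr_row(thr, p$ref_a), .thr_row(thr, p$ref_b),
      p$drug_a, p$drug_b, di_cutoff = di_cutoff)
  })
  pairs$class <- vapply(calls, `[[`, character(1), "class")
  pairs$category <- vapply(calls, `[[`, character(1), "category")
  pairs$state_a <- vapply(calls, `[[`, integer(1), "state_a")
  pairs$state_b <- vapply(calls, `[[`, integer(1), "state_b")
  pairs$emergent <- vapply(calls, `[[`, logical(1), "emergent")
  edges <- do.call(rbind, lapply(calls, `[[`, "edges"))
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        type = character(), stringsAsFactors = FALSE)
  structure(list(pairs = pairs, edges = edges, thresholds = thr,
                 params = list(di_cutoff = di_cutoff, mad_k = mad_k,
                               variance_target = variance_target,
                               cloud_mode = cloud_mode,
                               min_pairs = min_pairs)),
            class = "interaction_calls")
}

#' @export
print.interaction_calls <- function(x, ...) {
  ni <- x$pairs$state_a == 0 & x$pairs$state_b == 0 & !x$pairs$emergent
  cat("Interaction calls:", sum(!ni), "interactions among",
      nrow(x$pairs), "combinations\n")
  if (nrow(x$edges)) print(table(x$edges$type))
  invisible(x)
}
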