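#' Perturbation displacement vectors
#'
#' Represents every treatment as a vector in the filtered feature space
#' pointing from the unperturbed (control) centroid to the perturbed
#' state.  Replicate wells give replicate vectors; the treatment vector is
#' their arithmetic mean.  Combinations are measured in a single well and
#' yield a single-measurement vector.
#'
#' @param wt a normalized [well_table()].
#' @param selection optional [filter_features()] result restricting the
#'   feature space; `NULL` keeps all features.
#' @param validity optional [filter_perturbations()] result; invalid wells
#'   and invalid treatments are excluded.  Treatments left with zero valid
#'   wells are omitted with a reason (attribute `"omitted"`).
#' @param scope control centroid scope, `"batch"` (default, the centroid of
#'   all DMSO wells of the treatment's batch) or `"plate"`.
#'
#' @return An object of class `perturbation_vectors`: list with
#'   `treatments` (named list; each element has `id`, `role`, `drug_a`,
#'   `drug_b`, `batch`, `plate`, `replicates` matrix, `mean` vector and
#'   `norm`), `controls` (per-batch matrix of control displacement
#'   vectors), `control_rows` (per-plate matrix of raw control well
#'   profiles, used by the non-interaction cloud) and `features`.
#' @export
perturbation_vectors <- function(wt, selection = NULL, validity = NULL,
                                 scope = c("batch", "plate")) {
  stopifnot(inherits(wt, "well_table"))
  scope <- match.arg(scope)
  feats <- if (is.null(selection)) colnames(wt$values) else selection$kept
  vals <- wt$values[, feats, drop = FALSE]
  meta <- wt$meta

  keep_well <- rep(TRUE, nrow(meta))
  valid_trt <- NULL
  if (!is.null(validity)) {
    keep_well <- validity$wells$valid[match(meta$key, validity$wells$key)]
    keep_well[is.na(keep_well)] <- FALSE
    tv <- validity$treatments
    valid_trt <- tv$treatment[tv$valid]
  }

  ctrl <- meta$role == "control"
  centroid <- list()
  for (b in unique(meta$batch)) {
    i <- which(ctrl & meta$batch == b & keep_well)
    if (!length(i)) stop("no valid control wells in batch ", b)
    centroid[[as.character(b)]] <- colMeans(vals[i, , drop = FALSE])
  }
  plate_centroid <- list()
  control_rows <- list()
  for (p in unique(meta$plate)) {
    i <- which(ctrl & meta$plate == p & keep_well)
    if (length(i)) {
      plate_centroid[[as.character(p)]] <- colMeans(vals[i, , drop = FALSE])
      control_rows[[as.character(p)]] <- vals[i, , drop = FALSE]
    }
  }

  ref <- function(b, p) {
    if (scope == "batch") centroid[[as.character(b)]]
    else plate_centroid[[as.character(p)]]
  }

  controls <- list()
  for (b in unique(meta$batch)) {
    i <- which(ctrl & meta$batch == b & keep_well)
    controls[[as.character(b)]] <-
      sweep(vals[i, , drop = FALSE], 2, centroid[[as.character(b)]])
  }

  omitted <- character()
  treatments <- list()
  for (tr in unique(meta$treatment[!ctrl])) {
    i <- which(meta$treatment == tr & keep_well)
    if (!is.null(valid_trt) && !tr %in% valid_trt) {
      omitted <- c(omitted, structure(tr, names = "invalid treatment"))
      next
    }
    if (!length(i)) {
      omitted <- c(omitted, structure(tr, names = "no valid wells"))
      next
    }
    b <- meta$batch[i[1]]
    reps <- vapply(i, function(k)
      vals[k, ] - ref(meta$batch[k], meta$plate[k]), numeric(ncol(vals)))
    reps <- if (is.matrix(reps)) t(reps) else matrix(reps, ncol = 1)
    dimnames(reps) <- list(meta$key[i], colnames(vals))
    mv <- colMeans(reps)
    treatments[[tr]] <- list(
      id = tr, role = meta$role[i[1]],
      drug_a = meta$drug_a[i[1]], drug_b = meta$drug_b[i[1]],
      batch = b, plate = meta$plate[i],
      replicates = reps, mean = mv, norm = sqrt(sum(mv^2)))
  }

  structure(list(treatments = treatments, controls = controls,
                 control_rows = control_rows, features = feats,
                 scope = scope),
            class = "perturbation_vectors",
            omitted = omitted)
}

#' @export
print.perturbation_vectors <- function(x, ...) {
  roles <- vapply(x$treatments, `[[`, character(1), "role")
  cat("Perturbation vectors in", length(x$features), "dimensions:",
      sum(roles == "single"), "singles,",
      sum(roles == "combination"), "combinations\n")
  invisible(x)
}

#' Perturbation strength via the Mahalanobis distance
#'
#' Quantifies how strongly a treatment displaces the phenotype relative to
#' control variation.  Control displacement vectors are reduced by PCA to
#' the smallest number of components explaining at least `variance_target`
#' of their variance; the treatment's mean vector is projected into that
#' space and its Mahalanobis distance D_P from the projected control
#' distribution is returned.  D_P generalizes the z-score: in one
#' dimension it reduces to |x - mu| / sigma.  A perturbation is *strong*
#' if D_P exceeds `cutoff` in at least one batch.
#'
#' @param vectors a [perturbation_vectors()] object.
#' @param variance_target fraction of control variance the retained
#'   principal components must explain (default 0.90).
#' @param cutoff strength cutoff on D_P (default 7).
#' @param ridge ridge added to the diagonal of the reduced covariance for
#'   numerical safety (default 1e-8); a singular reduced covariance is
#'   regularized with a warning.
#' @param n_components optional fixed number of principal components,
#'   overriding the explained-variance rule.
#'
#' @return An object of class `strength_result`: data.frame with one row
#'   per treatment and batch (`id`, `role`, `batch`, `dp`, `n_components`,
#'   `var_explained`, `strong`), plus attribute `"by_drug"` giving the
#'   per-drug strong flag (strong in any batch).
#' @export
perturbation_strength <- function(vectors, variance_target = 0.90,
                                  cutoff = 7, ridge = 1e-8,
                                  n_components = NULL) {
  stopifnot(inherits(vectors, "perturbation_vectors"))
  out <- list()
  for (b in names(vectors$controls)) {
    ctrl <- vectors$controls[[b]]
    pca <- prcomp(ctrl, center = TRUE, scale. = FALSE)
    ev <- pca$sdev^2
    k <- if (!is.null(n_components)) n_components
         else which(cumsum(ev) / sum(ev) >= variance_target)[1]
    if (nrow(ctrl) < k + 1)
      warning("batch ", b, ": fewer control wells (", nrow(ctrl),
              ") than retained components + 1 (", k + 1,
              "); covariance ridge-regularized")
    proj_c <- pca$x[, seq_len(k), drop = FALSE]
    S <- cov(proj_c)
    if (rcond(S) < 1e-12) {
      warning("batch ", b, ": singular reduced covariance, ",
              "ridge-regularized (epsilon = ", ridge, ")")
    }
    S <- S + diag(ridge, k)
    mu <- colMeans(proj_c)
    trts <- Filter(function(tr) as.character(tr$batch) == b,
                   vectors$treatments)
    rows <- lapply(trts, function(tr) {
      x <- drop(predict(pca, newdata = rbind(tr$mean))[, seq_len(k)])
      dp <- sqrt(mahalanobis(rbind(x), mu, S))
      data.frame(id = tr$id, role = tr$role, batch = b, dp = dp,
                 n_components = k,
                 var_explained = sum(ev[seq_len(k)]) / sum(ev),
                 strong = dp > cutoff, stringsAsFactors = FALSE)
    })
    out <- c(out, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  bd <- tapply(res$strong[res$role == "single"],
               res$id[res$role == "single"], any)
  by_drug <- stats::setNames(as.logical(bd), names(bd))
  structure(res, class = c("strength_result", "data.frame"),
            by_drug = by_drug, cutoff = cutoff)
}

#' Cosine similarity of two perturbation vectors
#'
#' Dot product over the product of the norms; 1 for identical orientation,
#' 0 for orthogonal, -1 for opposite vectors.  Magnitude is ignored, so
#' scaled versions of the same phenotype compare as identical.
#'
#' @param v1,v2 numeric vectors of equal length.
#' @return similarity in \[-1, 1\]; `NA` (with a warning) if either vector
#'   is zero.
#' @export
cosine_similarity <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("vectors differ in dimension")
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) {
    warning("cosine similarity undefined for a zero vector")
    return(NA_real_)
  }
  sum(v1 * v2) / (n1 * n2)
}

#' Vector-norm filter against control variation
#'
#' Retains only treatments whose displacement-vector norm exceeds the mean
#' control-vector norm by at least `k_sd` standard deviations (per batch).
#' Used to exclude small, likely random displacements before similarity
#' analyses.
#'
#' @param vectors a [perturbation_vectors()] object.
#' @param k_sd number of standard deviations (default 2).
#' @return character vector of retained treatment ids, with attribute
#'   `"threshold"` (per-batch norm threshold).
#' @export
norm_filter <- function(vectors, k_sd = 2) {
  stopifnot(inherits(vectors, "perturbation_vectors"))
  thr <- vapply(vectors$controls, function(ctrl) {
    norms <- sqrt(rowSums(ctrl^2))
    mean(norms) + k_sd * sd(norms)
  }, numeric(1))
  keep <- vapply(vectors$treatments, function(tr)
    tr$norm > thr[[as.character(tr$batch)]], logical(1))
  structure(names(vectors$treatments)[keep], threshold = thr)
}
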