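#' Feature filter cascade
#'
#' Reduces the raw feature set to robust, reproducible, informative and
#' non-redundant features by applying four filters in order:
#'
#' 1. *Noise*: drop features whose intra-plate or inter-plate coefficient
#'    of variation (CV) over control wells is `>= cv_max`.
#' 2. *Reproducibility*: drop features whose mean between-replicate
#'    Pearson correlation (replicate i vs replicate j across single-drug
#'    treatments) is below `replicate_corr_min`.
#' 3. *Effect*: drop features for which no single or combination
#'    perturbation reaches Bonferroni-corrected significance of its
#'    control-relative z-score.
#' 4. *Redundancy*: while any retained feature pair correlates beyond
#'    `redundancy_rho` in absolute value, remove from the currently
#'    most-correlated pair the member with the smaller maximal absolute
#'    z-score (ties broken by feature name).
#'
#' Stages 1-3 are evaluated separately within each batch; a feature enters
#' stage 4 only if it passes in every batch.
#'
#' @param wt a normalized [well_table()].
#' @param cv_max CV threshold for stage 1 (default 0.2).
#' @param replicate_corr_min replicate-correlation threshold for stage 2
#'   (default 0.2).
#' @param alpha significance level for stage 3, Bonferroni-corrected over
#'   all feature x perturbation tests (default 0.05).
#' @param redundancy_rho absolute correlation above which a pair is
#'   considered redundant (default 0.8).
#'
#' @return An object of class `feature_selection`: list with `kept`
#'   (ordered retained feature names), `table` (per-feature diagnostics:
#'   CVs, replicate correlation, max |z|, removal stage and reason) and
#'   `params`.
#' @export
filter_features <- function(wt, cv_max = 0.2, replicate_corr_min = 0.2,
                            alpha = 0.05, redundancy_rho = 0.8) {
  stopifnot(inherits(wt, "well_table"))
  vals <- wt$values
  meta <- wt$meta
  feats <- colnames(vals)
  nf <- length(feats)
  batches <- unique(meta$batch)

  diag_intra <- diag_inter <- diag_rcor <- diag_z <-
    matrix(NA_real_, nf, length(batches), dimnames = list(feats, batches))

  for (bi in seq_along(batches)) {
    b <- batches[bi]
    inb <- meta$batch == b
    ctrl <- inb & meta$role == "control"
    plates <- unique(meta$plate[inb])
    for (p in plates) {
      if (sum(ctrl & meta$plate == p) < 2)
        stop("fewer than 2 control wells on plate '", p,
             "': coefficient of variation undefined")
    }
    # stage 1 diagnostics
    cv_by_plate <- sapply(plates, function(p) {
      i <- which(ctrl & meta$plate == p)
      apply(vals[i, , drop = FALSE], 2, function(x) sd(x) / mean(x))
    })
    cv_by_plate <- matrix(cv_by_plate, nrow = nf)
    diag_intra[, bi] <- rowMeans(abs(cv_by_plate))
    plate_means <- sapply(plates, function(p) {
      i <- which(ctrl & meta$plate == p)
      colMeans(vals[i, , drop = FALSE])
    })
    plate_means <- matrix(plate_means, nrow = nf)
    diag_inter[, bi] <- if (length(plates) > 1)
      apply(plate_means, 1, function(x) abs(sd(x) / mean(x)))
    else 0
    # stage 2 diagnostics: replicate columns correlated across drugs
    singles <- meta$role == "single" & inb
    drugs <- unique(meta$drug_a[singles])
    reps <- sort(unique(meta$replicate[singles]))
    if (length(drugs) >= 3 && length(reps) >= 2) {
      for (f in seq_len(nf)) {
        m <- matrix(NA_real_, length(drugs), length(reps))
        i <- which(singles)
        m[cbind(match(meta$drug_a[i], drugs), match(meta$replicate[i], reps))] <-
          vals[i, f]
        cc <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
        cc <- cc[upper.tri(cc)]
        diag_rcor[f, bi] <- if (all(is.na(cc))) NA_real_ else mean(cc, na.rm = TRUE)
      }
    }
    # stage 3 diagnostics: max |z| over perturbations
    mu_c <- colMeans(vals[ctrl, , drop = FALSE])
    sd_c <- apply(vals[ctrl, , drop = FALSE], 2, sd)
    trts <- unique(meta$treatment[inb & meta$role != "control"])
    zmax <- rep(0, nf)
    for (tr in trts) {
      i <- which(inb & meta$treatment == tr)
      m <- colMeans(vals[i, , drop = FALSE])
      z <- ifelse(sd_c > 0, (m - mu_c) / sd_c,
                  ifelse(abs(m - mu_c) > 0, Inf, 0))
      zmax <- pmax(zmax, abs(z))
    }
    diag_z[, bi] <- zmax
    attr(diag_z, paste0("ntests_", b)) <- nf * length(trts)
  }

  stage <- rep("kept", nf)
  reason <- rep("", nf)
  names(stage) <- names(reason) <- feats

  fail_cv <- apply(diag_intra >= cv_max | diag_inter >= cv_max, 1, any)
  stage[fail_cv] <- "cv"
  reason[fail_cv] <- "intra- or inter-plate CV over controls too large"

  rc <- apply(diag_rcor, 1, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) NA_real_ else min(x)
  })
  fail_rc <- stage == "kept" & !is.na(rc) & rc < replicate_corr_min
  stage[fail_rc] <- "replicate_correlation"
  reason[fail_rc] <- "between-replicate correlation below threshold"

  # Bonferroni over features x perturbations, per batch; significant in
  # every batch required
  sig <- rep(TRUE, nf)
  for (bi in seq_along(batches)) {
    ntests <- attr(diag_z, paste0("ntests_", batches[bi]))
    p <- 2 * pnorm(-diag_z[, bi])
    sig <- sig & (pmin(p * ntests, 1) < alpha)
  }
  fail_sig <- stage == "kept" & !sig
  stage[fail_sig] <- "no_effect"
  reason[fail_sig] <- "no perturbation reaches Bonferroni-corrected significance"

  # stage 4: iterative redundancy pruning on survivors
  keep <- feats[stage == "kept"]
  effect <- apply(diag_z, 1, max)
  while (length(keep) > 1) {
    cc <- abs(cor(vals[, keep, drop = FALSE]))
    diag(cc) <- 0
    if (max(cc) <= redundancy_rho) break
    top <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    pair <- sort(keep[top])
    drop <- if (effect[pair[1]] < effect[pair[2]]) pair[1]
            else if (effect[pair[2]] < effect[pair[1]]) pair[2]
            else pair[1]  # tie: lexicographically first goes
    stage[drop] <- "redundant"
    reason[drop] <- paste0("correlated (|rho| > ", redundancy_rho,
                           ") with ", setdiff(pair, drop),
                           ", smaller max |z|")
    keep <- setdiff(keep, drop)
  }

  tab <- data.frame(
    feature = feats,
    intra_cv = apply(diag_intra, 1, max),
    inter_cv = apply(diag_inter, 1, max),
    replicate_cor = rc,
    max_abs_z = effect,
    stage = unname(stage),
    reason = unname(reason),
    kept = unname(stage == "kept"),
    stringsAsFactors = FALSE)

  structure(list(kept = feats[stage == "kept"], table = tab,
                 params = list(cv_max = cv_max,
                               replicate_corr_min = replicate_corr_min,
                               alpha = alpha,
                               redundancy_rho = redundancy_rho)),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat("Feature selection:", length(x$kept), "of", nrow(x$table),
      "features retained\n")
  print(table(x$table$stage))
  invisible(x)
}
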