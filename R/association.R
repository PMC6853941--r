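#' Cohen's d effect size
#'
#' Standardized mean difference `(mu1 - mu2) / s` with the pooled standard
#' deviation `s = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#' Antisymmetric under swapping the samples.
#'
#' @param sample1,sample2 numeric vectors (each of length >= 2).
#' @return Cohen's d; `NA` with a warning when the pooled s.d. is zero.
#' @export
cohens_d <- function(sample1, sample2) {
  n1 <- length(sample1); n2 <- length(sample2)
  if (n1 < 2 || n2 < 2) stop("need at least 2 values per sample")
  s <- sqrt(((n1 - 1) * var(sample1) + (n2 - 1) * var(sample2)) /
              (n1 + n2 - 2))
  if (s == 0) {
    if (mean(sample1) == mean(sample2)) return(0)
    warning("zero pooled standard deviation; effect size undefined")
    return(NA_real_)
  }
  (mean(sample1) - mean(sample2)) / s
}

#' Bootstrap distribution of the mean
#'
#' Resamples `n` values with replacement from the sample (`n` = sample
#' size), `n_boot` times, computing the mean each time.
#'
#' @param sample numeric vector.
#' @param n_boot number of bootstrap resamples (default 10000).
#' @param seed optional RNG seed.
#' @param conf level of the percentile confidence interval.
#' @return list with `means` (the bootstrap distribution), `mean` and `ci`.
#' @export
bootstrap_means <- function(sample, n_boot = 10000L, seed = NULL,
                            conf = 0.95) {
  if (!length(sample)) stop("empty sample")
  if (!is.null(seed)) set.seed(seed)
  n <- length(sample)
  means <- vapply(seq_len(n_boot),
                  function(i) mean(sample[sample.int(n, n, replace = TRUE)]),
                  numeric(1))
  list(means = means, mean = mean(means),
       ci = quantile(means, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                     names = FALSE))
}

#' Association between a drug-pair feature and an interaction type
#'
#' Tests whether a feature differs between pairs carrying a given
#' interaction type and non-interacting pairs.  Binary features use
#' Fisher's exact test (with the odds ratio as effect), other features the
#' Mann-Whitney U test (with the fold change of means).  Significance at
#' the raw `alpha` cutoff by default; set `adjust` to apply a
#' multiple-testing correction across a batch of features yourself.
#'
#' @param table data.frame of drug pairs with a `label` column (interaction
#'   type, `"none"` for non-interacting) and feature columns.
#' @param feature name of the feature column to test.
#' @param type_label interaction type to compare against `"none"`.
#' @param alpha significance cutoff (default 0.05).
#' @return list with `p`, `direction` (`"enriched"`, `"depleted"` or
#'   `"none"`), `effect` (odds ratio or fold change), `significant` and
#'   `test`.  Degenerate contingency tables yield `p = 1`, flagged.
#' @export
feature_association <- function(table, feature, type_label, alpha = 0.05) {
  g1 <- table[table$label == type_label, feature]
  g2 <- table[table$label == "none", feature]
  if (length(g1) < 2 || length(g2) < 2)
    stop("need at least 2 pairs per group")
  x <- c(g1, g2)
  binary <- is.logical(x) || all(x %in% c(0, 1))
  if (binary) {
    tab <- rbind(c(sum(g1 == 1), sum(g1 == 0)),
                 c(sum(g2 == 1), sum(g2 == 0)))
    if (any(rowSums(tab) == 0) || all(tab[, 1] == 0) || all(tab[, 2] == 0)) {
      return(list(p = 1, direction = "none", effect = NA_real_,
                  significant = FALSE, test = "fisher",
                  degenerate = TRUE))
    }
    ft <- fisher.test(tab)
    eff <- unname(ft$estimate)
    dir <- if (ft$p.value > alpha) "none"
           else if (eff > 1) "enriched" else "depleted"
    list(p = ft$p.value, direction = dir, effect = eff,
         significant = ft$p.value <= alpha, test = "fisher",
         degenerate = FALSE)
  } else {
    wt <- suppressWarnings(wilcox.test(g1, g2))
    eff <- mean(g1) / mean(g2)
    dir <- if (wt$p.value > alpha) "none"
           else if (eff > 1) "enriched" else "depleted"
    list(p = wt$p.value, direction = dir, effect = eff,
         significant = wt$p.value <= alpha, test = "mann-whitney",
         degenerate = FALSE)
  }
}

#' Interaction-type fingerprints
#'
#' For every interaction type, Cohen's d of the type's pairs against all
#' interacting pairs, per feature -- the radial "fingerprint" profile that
#' contrasts how one interaction type differs from interactions at large.
#'
#' @param table data.frame of drug pairs with a `label` column (`"none"`
#'   for non-interacting) and numeric feature columns.
#' @param features feature column names (default: all numeric columns
#'   except the label).
#' @return An object of class `fingerprint_profile`: matrix of Cohen's d
#'   values, one row per interaction type, one column per feature.
#' @export
interaction_fingerprint <- function(table, features = NULL) {
  if (is.null(features))
    features <- names(table)[vapply(table, is.numeric, logical(1))]
  types <- setdiff(unique(table$label), "none")
  interacting <- table[table$label != "none", , drop = FALSE]
  prof <- matrix(NA_real_, length(types), length(features),
                 dimnames = list(types, features))
  for (t in types) {
    g1 <- interacting[interacting$label == t, , drop = FALSE]
    for (f in features)
      prof[t, f] <- cohens_d(g1[[f]], interacting[[f]])
  }
  structure(prof, class = c("fingerprint_profile", "matrix"))
}
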