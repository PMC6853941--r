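#' Decompose a combination vector into single-drug and emergent components
#'
#' The two single-perturbation vectors `a` and `b` span a two-dimensional
#' plane; the expected non-interacting combination is their superposition
#' `a + b`.  The observed combination vector `c` is decomposed as
#'
#'   c = alpha * a + beta * b + gamma * n
#'
#' where `(alpha, beta)` is the least-squares projection of `c` onto the
#' plane (the solution of the 2x2 normal equations with Gram matrix
#' \[\[a.a, a.b\], \[a.b, b.b\]\] and right-hand side (a.c, b.c)), `n` is
#' the unit residual direction orthogonal to both `a` and `b`, and
#' `gamma >= 0` its magnitude.  `alpha = beta = 1, gamma = 0` is exact
#' superposition, i.e. non-interaction; deviations of `alpha` (`beta`)
#' mean the contribution of `a` (`b`) was shrunk or stretched, and
#' `gamma > 0` indicates an emergent phenotype attributable to neither
#' perturbation alone.
#'
#' @param a,b single-perturbation vectors (nonzero, not collinear).
#' @param c_obs observed combination vector of the same dimension.
#' @param tol_cond condition-number limit of the Gram matrix beyond which
#'   the geometry is considered degenerate (default 1e8).
#'
#' @return An object of class `decomposition`: list with `alpha`, `beta`,
#'   `gamma` (>= 0), `n_hat` (unit residual direction; the zero vector
#'   when `gamma = 0`), and `recon_error`
#'   (`||c - (alpha a + beta b + gamma n_hat)||`).
#'   Collinear inputs raise a condition of class `perturbome_degenerate`
#'   carrying the 1-D projection coefficient as diagnostic; zero inputs
#'   are an error.
#' @export
decompose_pair <- function(a, b, c_obs, tol_cond = 1e8) {
  if (length(a) != length(b) || length(a) != length(c_obs))
    stop("vectors differ in dimension")
  aa <- sum(a * a); bb <- sum(b * b); ab <- sum(a * b)
  if (aa == 0 || bb == 0) stop("single-perturbation vector is zero")
  G <- matrix(c(aa, ab, ab, bb), 2, 2)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= 0 || ev[1] / ev[2] > tol_cond) {
    proj <- sum(a * c_obs) / aa
    cond <- structure(
      class = c("perturbome_degenerate", "error", "condition"),
      list(message = "single-perturbation vectors are (near) collinear",
           call = sys.call(), projection_1d = proj))
    stop(cond)
  }
  p <- solve(G, c(sum(a * c_obs), sum(b * c_obs)))
  resid <- c_obs - p[1] * a - p[2] * b
  gamma <- sqrt(sum(resid^2))
  if (gamma < 1e-10 * max(1, sqrt(sum(c_obs^2)))) gamma <- 0
  n_hat <- if (gamma > 0) resid / gamma else resid * 0
  recon <- p[1] * a + p[2] * b + gamma * n_hat
  structure(list(alpha = p[1], beta = p[2], gamma = gamma, n_hat = n_hat,
                 recon_error = sqrt(sum((c_obs - recon)^2))),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("Decomposition: alpha = %.4f, beta = %.4f, gamma = %.4f\n",
              x$alpha, x$beta, x$gamma))
  invisible(x)
}

# internal: class label from state signs and emergent flag
.state_names <- c("decreased", "unchanged", "increased")
.class_label <- function(sa, sb, emergent) {
  paste0("A:", .state_names[sa + 2], "|B:", .state_names[sb + 2],
         "|emergent:", ifelse(emergent, "present", "absent"))
}
.class_category <- function(sa, sb) {
  n <- (sa != 0) + (sb != 0)
  c("undirected", "uni-directional", "bi-directional")[n + 1]
}

#' Enumerate the interaction taxonomy
#'
#' The sign pattern of `(alpha - 1, beta - 1, gamma)` over \{-, 0, +\}^3
#' divides the coefficient space into 27 subspaces (1 point, 6 lines,
#' 12 surfaces, 8 volumes).  Because positive and negative `gamma` describe
#' the same emergent phenotype, subspaces differing only in the sign of
#' `gamma` merge, leaving 18 distinct interaction classes: 2 undirected
#' (non-interaction; emergent only), 8 uni-directional (only one
#' perturbation modulated) and 8 bi-directional.
#'
#' @return An object of class `interaction_taxonomy`: list with
#'   `subspaces` (27 sign patterns with their dimension), `classes` (the 18
#'   merged classes with labels and categories), `dimension_histogram` and
#'   `category_counts`.
#' @export
enumerate_interaction_classes <- function() {
  sub <- expand.grid(s_alpha = -1:1, s_beta = -1:1, s_gamma = -1:1)
  sub$dimension <- rowSums(sub != 0)
  cls <- unique(data.frame(s_alpha = sub$s_alpha, s_beta = sub$s_beta,
                           emergent = sub$s_gamma != 0))
  cls$label <- .class_label(cls$s_alpha, cls$s_beta, cls$emergent)
  cls$category <- .class_category(cls$s_alpha, cls$s_beta)
  cls <- cls[order(cls$category, cls$label), ]
  rownames(cls) <- NULL
  structure(list(
    subspaces = sub,
    classes = cls,
    dimension_histogram = table(factor(sub$dimension, levels = 0:3)),
    category_counts = table(cls$category)),
    class = "interaction_taxonomy")
}

#' @export
print.interaction_taxonomy <- function(x, ...) {
  cat(nrow(x$subspaces), "subspaces (dimensions:",
      paste(sprintf("%s-D: %d", names(x$dimension_histogram),
                    x$dimension_histogram), collapse = ", "), ")\n")
  cat(nrow(x$classes), "interaction classes:",
      paste(sprintf("%s = %d", names(x$category_counts),
                    x$category_counts), collapse = ", "), "\n")
  invisible(x)
}

#' Drug-specific effect-size thresholds
#'
#' Deviations of alpha, beta and gamma only count as interactions when they
#' exceed robust thresholds estimated from the *non-significant* pairs
#' (those with D_I below the cutoff): per drug, the alpha/beta band is the
#' median of its non-significant coefficients plus/minus `mad_k` (raw)
#' median absolute deviations, and the gamma threshold is the largest gamma
#' observed among its non-significant pairs.  Drugs with fewer than
#' `min_pairs` non-significant pairs fall back to thresholds pooled over
#' all drugs, flagged in the output.
#'
#' @param pairs data.frame with columns `drug_a`, `drug_b`, `alpha`,
#'   `beta`, `gamma`, `significant` (logical, D_I above cutoff).
#' @param mad_k MAD multiplier (default 2).
#' @param min_pairs minimum non-significant pairs per drug before the
#'   global fallback applies (default 5).
#'
#' @return An object of class `effect_thresholds`: data.frame per drug with
#'   `center`, `mad`, `lo`, `hi` (the unchanged band), `t_gamma`, `n_ns`
#'   and `fallback`.
#' @export
derive_effect_thresholds <- function(pairs, mad_k = 2, min_pairs = 5L) {
  ns <- !pairs$significant
  if (!any(ns)) {
    warning("no non-significant pairs; thresholds estimated from all pairs")
    ns <- rep(TRUE, nrow(pairs))
  }
  gvals <- c(pairs$alpha[ns], pairs$beta[ns])
  g_center <- median(gvals)
  g_mad <- mad(gvals, constant = 1)
  g_tg <- max(pairs$gamma[ns])
  drugs <- sort(unique(c(pairs$drug_a, pairs$drug_b)))
  rows <- lapply(drugs, function(d) {
    vals <- c(pairs$alpha[ns & pairs$drug_a == d],
              pairs$beta[ns & pairs$drug_b == d])
    gam <- pairs$gamma[ns & (pairs$drug_a == d | pairs$drug_b == d)]
    if (length(vals) < min_pairs) {
      data.frame(drug = d, n_ns = length(vals), center = g_center,
                 mad = g_mad, lo = g_center - mad_k * g_mad,
                 hi = g_center + mad_k * g_mad, t_gamma = g_tg,
                 fallback = TRUE, stringsAsFactors = FALSE)
    } else {
      ctr <- median(vals); md <- mad(vals, constant = 1)
      data.frame(drug = d, n_ns = length(vals), center = ctr, mad = md,
                 lo = ctr - mad_k * md, hi = ctr + mad_k * md,
                 t_gamma = max(gam), fallback = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  structure(res, class = c("effect_thresholds", "data.frame"),
            mad_k = mad_k, min_pairs = min_pairs,
            global = data.frame(drug = NA_character_, n_ns = sum(ns),
                                center = g_center, mad = g_mad,
                                lo = g_center - mad_k * g_mad,
                                hi = g_center + mad_k * g_mad,
                                t_gamma = g_tg, fallback = TRUE,
                                stringsAsFactors = FALSE))
}

# internal: threshold row for a drug, falling back to the global row
.thr_row <- function(thr, drug) {
  i <- which(thr$drug == drug)
  if (length(i)) thr[i[1], ] else attr(thr, "global")
}

#' Classify a decomposed drug pair
#'
#' Applies the two-stage calling rule: a pair is an interaction only if its
#' combination vector deviates significantly from the non-interaction
#' cloud (`d_i > di_cutoff`) AND at least one coefficient exceeds its
#' effect-size threshold.  `alpha` below (above) drug A's unchanged band
#' means A's contribution decreased (increased), and analogously for
#' `beta`; `gamma` beyond the threshold means an emergent component is
#' present.  A significant pair whose coefficients all stay within their
#' bands is conservatively called non-interaction.
#'
#' Edges follow the modulation: a changed `alpha` is drug B modulating drug
#' A, so a directed edge B -> A signed by the direction of change; a
#' changed `beta` gives A -> B; an emergent component gives an undirected
#' A -- B edge.
#'
#' @param dec a [decompose_pair()] result (or a list with `alpha`, `beta`,
#'   `gamma`).
#' @param d_i interaction Mahalanobis distance of the pair.
#' @param thr_a,thr_b single rows of [derive_effect_thresholds()] for drugs
#'   A and B; the gamma test uses `max(thr_a$t_gamma, thr_b$t_gamma)`.
#' @param drug_a,drug_b drug identifiers.
#' @param di_cutoff significance cutoff on D_I (default 3).
#'
#' @return An object of class `interaction_call`: list with `pair`,
#'   coefficient values, `d_i`, `significant`, the state triple, `class`
#'   label, `category` and an `edges` data.frame (`from`, `to`, `type` in
#'   positive/negative/emergent).
#' @export
classify_interaction <- function(dec, d_i, thr_a, thr_b, drug_a, drug_b,
                                 di_cutoff = 3) {
  significant <- is.finite(d_i) && d_i > di_cutoff
  sa <- sb <- 0L
  emergent <- FALSE
  if (significant) {
    if (dec$alpha < thr_a$lo) sa <- -1L else if (dec$alpha > thr_a$hi) sa <- 1L
    if (dec$beta < thr_b$lo) sb <- -1L else if (dec$beta > thr_b$hi) sb <- 1L
    emergent <- dec$gamma > max(thr_a$t_gamma, thr_b$t_gamma)
  }
  if (sa == 0L && sb == 0L && !emergent) {
    label <- .class_label(0L, 0L, FALSE)
    category <- "undirected"
    edges <- data.frame(from = character(), to = character(),
                        type = character(), stringsAsFactors = FALSE)
  } else {
    label <- .class_label(sa, sb, emergent)
    category <- if (emergent && sa == 0L && sb == 0L) "undirected"
                else .class_category(sa, sb)
    edges <- list()
    if (sa != 0L)
      edges[[length(edges) + 1]] <- data.frame(
        from = drug_b, to = drug_a,
        type = if (sa > 0) "positive" else "negative",
        stringsAsFactors = FALSE)
    if (sb != 0L)
      edges[[length(edges) + 1]] <- data.frame(
        from = drug_a, to = drug_b,
        type = if (sb > 0) "positive" else "negative",
        stringsAsFactors = FALSE)
    if (emergent)
      edges[[length(edges) + 1]] <- data.frame(
        from = min(drug_a, drug_b), to = max(drug_a, drug_b),
        type = "emergent", stringsAsFactors = FALSE)
    edges <- do.call(rbind, edges)
  }
  structure(list(pair = .pair_id(drug_a, drug_b), drug_a = drug_a,
                 drug_b = drug_b, alpha = dec$alpha, beta = dec$beta,
                 gamma = dec$gamma, d_i = d_i, significant = significant,
                 state_a = sa, state_b = sb, emergent = emergent,
                 class = label, category = category, edges = edges),
            class = "interaction_call")
}

#' @export
print.interaction_call <- function(x, ...) {
  cat(sprintf("%s: %s (D_I = %.2f, alpha = %.3f, beta = %.3f, gamma = %.3f)\n",
              x$pair, x$class, x$d_i, x$alpha, x$beta, x$gamma))
  invisible(x)
}
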