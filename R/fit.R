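#' Analysis parameters for a perturbome fit
#'
#' Collects every threshold of the pipeline in one place, at the defaults
#' used throughout: CV < 0.2, replicate correlation >= 0.2, Bonferroni
#' alpha 0.05, redundancy rho 0.8, >= 30 cells per well, >= 3 replicate
#' wells, stability slope 0.05 with 30% count difference, symmetric
#' 0.5/99.5 percentile clipping, 90% PCA variance, D_P > 7, D_I > 3,
#' 2-MAD effect bands.
#'
#' @param cv_max,replicate_corr_min,alpha,redundancy_rho feature filters,
#'   see [filter_features()].
#' @param min_cells,min_wells,stability_slope,stability_diff perturbation
#'   filters, see [filter_perturbations()].
#' @param lower,upper scaling clip percentiles, see
#'   [scale_unit_interval()].
#' @param variance_target PCA explained-variance target.
#' @param dp_cutoff strong-perturbation cutoff on D_P.
#' @param di_cutoff interaction significance cutoff on D_I.
#' @param mad_k MAD multiplier for effect-size bands.
#' @param min_pairs per-drug minimum of non-significant pairs before the
#'   global threshold fallback.
#' @param cloud_mode non-interaction cloud variant, see [ni_cloud()].
#' @param polish run the plate median polish?
#' @param select_features run the feature filter cascade?
#' @return a `perturbome_control` list.
#' @export
perturbome_control <- function(cv_max = 0.2, replicate_corr_min = 0.2,
                               alpha = 0.05, redundancy_rho = 0.8,
                               min_cells = 30L, min_wells = 3L,
                               stability_slope = 0.05,
                               stability_diff = 0.30,
                               lower = 0.005, upper = 0.995,
                               variance_target = 0.90, dp_cutoff = 7,
                               di_cutoff = 3, mad_k = 2, min_pairs = 5L,
                               cloud_mode = "multiplicative",
                               polish = TRUE, select_features = TRUE) {
  structure(as.list(environment()), class = "perturbome_control")
}

#' Fit the perturbome of a screen
#'
#' Runs the complete analysis on a per-cell feature table and plate map:
#' per-well median aggregation, plate median polish and unit-interval
#' scaling, feature and perturbation filtering, displacement vectors and
#' strength calls, non-interaction clouds, interaction decomposition and
#' classification, and assembly of the typed interaction network.
#'
#' @param cells per-cell feature table, see [aggregate_wells()].
#' @param meta plate map, see [well_table()].
#' @param control a [perturbome_control()] list of thresholds.
#'
#' @return An object of class `perturbome`: list with `wells` (normalized
#'   [well_table()]), `selection`, `validity`, `vectors`, `strength`,
#'   `calls` and `network`, with [print()], [summary()], [coef()] (the
#'   per-pair alpha/beta/gamma/D_I matrix) and [plot()] methods.
#' @seealso [simulate_screen()] for generating inputs with known ground
#'   truth.
#' @export
perturbome <- function(cells, meta, control = perturbome_control()) {
  stopifnot(inherits(control, "perturbome_control"))
  wt <- aggregate_wells(cells, meta)
  wt <- normalize_wells(wt, polish = control$polish,
                        lower = control$lower, upper = control$upper)
  selection <- if (control$select_features)
    filter_features(wt, cv_max = control$cv_max,
                    replicate_corr_min = control$replicate_corr_min,
                    alpha = control$alpha,
                    redundancy_rho = control$redundancy_rho)
  else NULL
  if (!is.null(selection) && length(selection$kept) < 2)
    stop("feature filtering retained fewer than 2 features")
  validity <- filter_perturbations(wt, min_cells = control$min_cells,
                                   min_wells = control$min_wells,
                                   stability_slope = control$stability_slope,
                                   stability_diff = control$stability_diff)
  vectors <- perturbation_vectors(wt, selection, validity)
  strength <- perturbation_strength(vectors,
                                    variance_target = control$variance_target,
                                    cutoff = control$dp_cutoff)
  calls <- interaction_calls(vectors, di_cutoff = control$di_cutoff,
                             mad_k = control$mad_k,
                             variance_target = control$variance_target,
                             cloud_mode = control$cloud_mode,
                             min_pairs = control$min_pairs)
  network <- assemble_perturbome(calls, strength)
  structure(list(wells = wt, selection = selection, validity = validity,
                 vectors = vectors, strength = strength, calls = calls,
                 network = network, control = control),
            class = "perturbome")
}

#' @export
print.perturbome <- function(x, ...) {
  cat("Perturbome fit\n")
  cat("  wells:", nrow(x$wells$values),
      " features retained:",
      if (is.null(x$selection)) ncol(x$wells$values)
      else length(x$selection$kept), "\n")
  strong <- attr(x$strength, "by_drug")
  cat("  drugs:", length(strong), "( strong:", sum(strong), ")\n")
  cat("  combinations called:", nrow(x$calls$pairs),
      " interactions:", nrow(x$network$edges), "\n")
  print(x$network$counts)
  invisible(x)
}

#' @export
summary.perturbome <- function(object, ...) {
  strong <- attr(object$strength, "by_drug")
  s <- sum(strong); w <- sum(!strong)
  out <- list(
    n_wells = nrow(object$wells$values),
    n_features = if (is.null(object$selection))
      ncol(object$wells$values) else length(object$selection$kept),
    n_drugs = length(strong), n_strong = s,
    n_pairs = nrow(object$calls$pairs),
    n_interactions = nrow(object$network$edges),
    counts = object$network$counts,
    sparseness = network_sparseness(object$network),
    class_table = table(object$calls$pairs$class))
  class(out) <- "summary.perturbome"
  out
}

#' @export
print.summary.perturbome <- function(x, ...) {
  cat("Perturbome summary\n")
  cat(sprintf("  %d wells, %d features, %d drugs (%d strong)\n",
              x$n_wells, x$n_features, x$n_drugs, x$n_strong))
  cat(sprintf("  %d of %d combinations interact (sparseness %.3f)\n",
              x$n_interactions, x$n_pairs, x$sparseness))
  cat("  edge types:\n")
  print(x$counts)
  cat("  interaction classes:\n")
  print(x$class_table)
  invisible(x)
}

#' @export
coef.perturbome <- function(object, ...) {
  p <- object$calls$pairs
  m <- as.matrix(p[, c("alpha", "beta", "gamma", "d_i")])
  rownames(m) <- p$combination
  m
}

#' @export
plot.perturbome <- function(x, ...) {
  net <- x$network
  if (!nrow(net$edges)) {
    plot(0, 0, type = "n", axes = FALSE, xlab = "", ylab = "",
         main = "Perturbome (no interactions)")
    return(invisible(x))
  }
  g <- graph_from_data_frame(net$edges, directed = TRUE,
                             vertices = net$nodes)
  cols <- c(positive = "forestgreen", negative = "firebrick",
            emergent = "steelblue")
  plot(g, layout = layout_with_fr(g),
       vertex.color = ifelse(net$nodes$strong, "orange", "grey85"),
       vertex.size = 8, vertex.label.cex = 0.6,
       edge.color = cols[net$edges$type],
       edge.arrow.size = ifelse(net$edges$type == "emergent", 0, 0.3),
       main = "Perturbome network", ...)
  legend("bottomleft", bty = "n", cex = 0.8,
         legend = c("positive", "negative", "emergent", "strong drug"),
         col = c(cols, "orange"), pch = c(NA, NA, NA, 19),
         lty = c(1, 1, 1, NA))
  invisible(x)
}
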