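#' Read a protein-protein interaction network
#'
#' Reads a two-column edge list (TSV) into an undirected simple igraph
#' graph; self-loops and duplicate edges are dropped.
#'
#' @param file path to a tab-separated edge list (no header by default).
#' @param header logical, does the file carry a header line?
#' @param lcc restrict to the largest connected component?
#' @return an undirected simple igraph graph.
#' @export
read_interactome <- function(file, header = FALSE, lcc = FALSE) {
  el <- utils::read.delim(file, header = header,
                          colClasses = "character")[, 1:2]
  g <- simplify(graph_from_data_frame(el, directed = FALSE))
  if (lcc) {
    comp <- components(g)
    g <- induced_subgraph(g, which(comp$membership ==
                                     which.max(comp$csize)))
  }
  g
}

#' Read drug target sets
#'
#' @param file TSV with columns drug and protein (header expected).
#' @param graph optional interactome graph; unmapped targets (proteins
#'   absent from the graph) are dropped, with the per-drug dropped count
#'   kept in the `"dropped"` attribute.
#' @return named list of character vectors (drug -> protein set).
#' @export
read_target_sets <- function(file, graph = NULL) {
  tab <- utils::read.delim(file, header = TRUE, colClasses = "character")
  sets <- split(tab[[2]], tab[[1]])
  sets <- lapply(sets, unique)
  dropped <- integer(length(sets))
  names(dropped) <- names(sets)
  if (!is.null(graph)) {
    nodes <- V(graph)$name
    for (d in names(sets)) {
      mapped <- intersect(sets[[d]], nodes)
      dropped[d] <- length(sets[[d]]) - length(mapped)
      sets[[d]] <- mapped
    }
  }
  structure(sets, dropped = dropped)
}

# internal: shortest-path matrix among a node subset
.sp_among <- function(graph, nodes) {
  distances(graph, v = nodes, to = nodes)
}

# internal: mean nearest-same-set distance given a distance submatrix
.ds_mean <- function(D) {
  diag(D) <- Inf
  d_s <- apply(D, 1, min)
  finite <- is.finite(d_s)
  if (!all(finite))
    attr(finite, "n_unreachable") <- sum(!finite)
  mean(d_s[finite])
}

#' Module diameter on the interactome
#'
#' For each target protein of a drug, the shortest-path distance `d_s` to
#' the next-closest target of the same drug is found; their mean is the
#' module diameter.  Targets unreachable from every other target
#' (different component) are excluded from the mean with a warning.
#'
#' @param graph an undirected igraph interactome.
#' @param targets character vector of protein ids (>= 2 must map to the
#'   graph).
#' @return mean nearest-neighbour distance (numeric scalar).
#' @export
module_diameter <- function(graph, targets) {
  targets <- intersect(unique(targets), V(graph)$name)
  if (length(targets) < 2)
    stop("need at least 2 targets mapped to the interactome")
  D <- .sp_among(graph, targets)
  diag(D) <- Inf
  d_s <- apply(D, 1, min)
  if (any(!is.finite(d_s))) {
    warning(sum(!is.finite(d_s)),
            " target(s) unreachable from all others; excluded from the mean")
    d_s <- d_s[is.finite(d_s)]
  }
  mean(d_s)
}

#' Interactome localization of a target module (Glass' Delta)
#'
#' Compares the observed module diameter of a target set to the
#' distribution obtained from `n_random` random node sets of the same
#' size: `Delta = (<d_s> - mu_random) / sigma_random`.  Strongly negative
#' values (conventionally Delta < -1) indicate a localized module.  The
#' size of the largest connected subgraph induced by the targets and its
#' z-score against the same null are also reported.
#'
#' @param graph undirected igraph interactome.
#' @param targets character vector of protein ids.
#' @param n_random number of random modules (default 10000).
#' @param seed optional RNG seed.
#' @param degree_matched sample the null within degree bins matching the
#'   target degrees instead of uniformly (default `FALSE`, plain uniform
#'   sampling).
#' @param n_bins degree bins used when `degree_matched = TRUE`.
#'
#' @return An object of class `localization_result`: list with `d_s`
#'   (observed), `mu_random`, `sigma_random`, `delta`, `lcc_size`,
#'   `lcc_z`, `n_random` and `n_targets`.
#' @export
glass_delta <- function(graph, targets, n_random = 10000L, seed = NULL,
                        degree_matched = FALSE, n_bins = 10L) {
  targets <- intersect(unique(targets), V(graph)$name)
  m <- length(targets)
  n <- vcount(graph)
  if (m < 2) stop("need at least 2 mapped targets")
  if (m >= n) stop("module size must be smaller than the graph")
  if (!is.null(seed)) set.seed(seed)
  Dfull <- distances(graph)
  idx_t <- match(targets, V(graph)$name)
  obs <- .ds_mean(Dfull[idx_t, idx_t, drop = FALSE])
  lcc_obs <- max(components(induced_subgraph(graph, targets))$csize)

  if (degree_matched) {
    deg <- degree(graph)
    breaks <- unique(quantile(deg, probs = seq(0, 1, length.out = n_bins + 1)))
    bins <- cut(deg, breaks = breaks, include.lowest = TRUE)
    target_bins <- bins[idx_t]
    pool <- split(seq_len(n), bins)
    draw <- function() {
      unlist(lapply(levels(bins), function(b) {
        need <- sum(target_bins == b)
        if (need) sample(pool[[b]], need) else integer()
      }), use.names = FALSE)
    }
  } else {
    draw <- function() sample.int(n, m)
  }

  null_ds <- numeric(n_random)
  null_lcc <- numeric(n_random)
  for (i in seq_len(n_random)) {
    s <- draw()
    null_ds[i] <- .ds_mean(Dfull[s, s, drop = FALSE])
    null_lcc[i] <- max(components(induced_subgraph(graph, s))$csize)
  }
  mu <- mean(null_ds); sigma <- sd(null_ds)
  structure(list(d_s = obs, mu_random = mu, sigma_random = sigma,
                 delta = (obs - mu) / sigma,
                 lcc_size = lcc_obs,
                 lcc_z = (lcc_obs - mean(null_lcc)) / sd(null_lcc),
                 n_random = n_random, n_targets = m),
            class = "localization_result")
}

#' @export
print.localization_result <- function(x, ...) {
  cat(sprintf(
    "Module localization: <d_s> = %.3f vs null %.3f +/- %.3f, Delta = %.2f\n",
    x$d_s, x$mu_random, x$sigma_random, x$delta))
  cat(sprintf("  LCC size %d (z = %.2f), %d targets, %d random modules\n",
              x$lcc_size, x$lcc_z, x$n_targets, x$n_random))
  invisible(x)
}

#' Interactome separation of two target modules
#'
#' Network-based overlap of two drugs' target modules:
#' `s_AB = <d_AB> - (<d_AA> + <d_BB>)/2`, where `<d_AB>` is the mean over
#' all proteins of both sets of the shortest distance to the closest
#' protein of the *other* set (shared proteins contribute 0) and `<d_AA>`,
#' `<d_BB>` are the module diameters.  Negative `s_AB` means overlapping
#' modules, positive separated ones.  The mean over all cross pairs
#' (`d_mean_AB`) and the minimum cross distance (`d_min_AB`) are also
#' returned.
#'
#' @param graph undirected igraph interactome.
#' @param targets_a,targets_b character vectors of protein ids (>= 1
#'   mapped each).
#' @return An object of class `separation_result`: list with `d_aa`,
#'   `d_bb`, `d_ab`, `s_ab`, `d_mean_ab`, `d_min_ab`.  Module diameters of
#'   singleton sets are 0 by convention; unreachable pairs are excluded
#'   from means as in [module_diameter()].
#' @export
interactome_separation <- function(graph, targets_a, targets_b) {
  nodes <- V(graph)$name
  A <- intersect(unique(targets_a), nodes)
  B <- intersect(unique(targets_b), nodes)
  if (!length(A) || !length(B))
    stop("both target sets need at least one mapped protein")
  diam <- function(set) {
    if (length(set) < 2) return(0)
    module_diameter(graph, set)
  }
  d_aa <- diam(A); d_bb <- diam(B)
  Dx <- distances(graph, v = A, to = B)
  # nearest-other-set distances; shared proteins are distance 0 by matrix
  near_a <- apply(Dx, 1, min)
  near_b <- apply(Dx, 2, min)
  both <- c(near_a, near_b)
  if (any(!is.finite(both))) {
    warning(sum(!is.finite(both)),
            " cross-component target(s) excluded from <d_AB>")
    both <- both[is.finite(both)]
  }
  d_ab <- mean(both)
  cross <- as.vector(Dx)
  cross_f <- cross[is.finite(cross)]
  structure(list(d_aa = d_aa, d_bb = d_bb, d_ab = d_ab,
                 s_ab = d_ab - (d_aa + d_bb) / 2,
                 d_mean_ab = mean(cross_f),
                 d_min_ab = min(cross_f)),
            class = "separation_result")
}

#' @export
print.separation_result <- function(x, ...) {
  cat(sprintf(
    "s_AB = %.3f (<d_AB> = %.3f, <d_AA> = %.3f, <d_BB> = %.3f): %s\n",
    x$s_ab, x$d_ab, x$d_aa, x$d_bb,
    if (x$s_ab < 0) "overlapping" else "separated"))
  invisible(x)
}

#' Annotation-based protein similarity
#'
#' Similarity of two proteins from the specificity of their shared
#' annotation terms: `S(a, b) = 2 / min(n_i)` over the shared terms, where
#' `n_i` is the number of proteins annotated to term `i`; 0 when no term
#' is shared, and 1 when the two proteins are the only members of a shared
#' term.  `annotation_set_similarity()` averages `S` over all unordered
#' pairs of a protein set.
#'
#' @param annotations data.frame with columns `term` and `protein`.
#' @param a,b protein ids.  Proteins absent from the table count as
#'   annotation-free (similarity 0 with any partner).
#' @return similarity in \[0, 1\].
#' @export
annotation_similarity <- function(annotations, a, b) {
  term_sizes <- tapply(annotations$protein, annotations$term,
                       function(p) length(unique(p)))
  terms_a <- unique(annotations$term[annotations$protein == a])
  terms_b <- unique(annotations$term[annotations$protein == b])
  shared <- intersect(terms_a, terms_b)
  if (!length(shared)) return(0)
  2 / min(term_sizes[shared])
}

#' @rdname annotation_similarity
#' @param proteins character vector of protein ids (>= 2).
#' @export
annotation_set_similarity <- function(annotations, proteins) {
  proteins <- unique(proteins)
  if (length(proteins) < 2) stop("need at least 2 proteins")
  prs <- combn(proteins, 2)
  mean(vapply(seq_len(ncol(prs)), function(i)
    annotation_similarity(annotations, prs[1, i], prs[2, i]), numeric(1)))
}

#' Tanimoto coefficient of two binary fingerprints
#'
#' Set-bit intersection over set-bit union.  Accepts bitstrings
#' (`"1011"`) or logical/0-1 vectors of equal length.
#'
#' @param fp_a,fp_b fingerprints.
#' @return coefficient in \[0, 1\]; two empty fingerprints give 0 with a
#'   warning.
#' @export
tanimoto <- function(fp_a, fp_b) {
  tobits <- function(x) {
    if (is.character(x) && length(x) == 1)
      x <- as.integer(strsplit(x, "")[[1]])
    as.logical(x)
  }
  a <- tobits(fp_a); b <- tobits(fp_b)
  if (length(a) != length(b)) stop("fingerprints differ in length")
  uni <- sum(a | b)
  if (uni == 0) {
    warning("both fingerprints empty; Tanimoto defined as 0")
    return(0)
  }
  sum(a & b) / uni
}
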