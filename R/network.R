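#' Assemble the perturbome network
#'
#' Collects all emitted interaction edges into a single typed network over
#' the valid drugs.  Directed edges (positive/negative) point at the
#' modulated drug and are admissible only when that drug has a strong
#' phenotype; the emergent edge type is undirected and admissible between
#' any pair.  A weak-weak pair can thus carry at most 1 edge, a weak-strong
#' pair 2, and a strong-strong pair 3 -- the counting behind
#' [max_possible_links()].  Inadmissible or unknown-drug edges are rejected
#' and reported in the `"dropped"` attribute.
#'
#' @param calls an [interaction_calls()] object (or a data.frame of edges
#'   with columns `from`, `to`, `type`).
#' @param strength a [perturbation_strength()] result, or a named logical
#'   vector of per-drug strong flags.
#'
#' @return An object of class `perturbome_network`: list with `nodes`
#'   (drug, strong), `edges` (from, to, type) and `counts`.
#' @export
assemble_perturbome <- function(calls, strength) {
  edges <- if (inherits(calls, "interaction_calls")) calls$edges else calls
  strong <- if (inherits(strength, "strength_result"))
    attr(strength, "by_drug") else strength
  nodes <- data.frame(drug = names(strong), strong = as.logical(strong),
                      stringsAsFactors = FALSE)
  dropped <- data.frame(from = character(), to = character(),
                        type = character(), reason = character(),
                        stringsAsFactors = FALSE)
  if (nrow(edges)) {
    unknown <- !(edges$from %in% nodes$drug) | !(edges$to %in% nodes$drug)
    if (any(unknown)) {
      dropped <- rbind(dropped, cbind(edges[unknown, , drop = FALSE],
                                      reason = "unknown or invalid drug"))
      edges <- edges[!unknown, , drop = FALSE]
    }
    directed <- edges$type %in% c("positive", "negative")
    weak_target <- directed &
      !nodes$strong[match(edges$to, nodes$drug)]
    if (any(weak_target)) {
      dropped <- rbind(dropped, cbind(edges[weak_target, , drop = FALSE],
                                      reason = "directed edge at weak drug"))
      edges <- edges[!weak_target, , drop = FALSE]
    }
    edges <- unique(edges)
  }
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 counts = table(factor(edges$type,
                                       levels = c("positive", "negative",
                                                  "emergent")))),
            class = "perturbome_network", dropped = dropped)
}

#' @export
print.perturbome_network <- function(x, ...) {
  cat("Perturbome network:", nrow(x$nodes), "drugs (",
      sum(x$nodes$strong), "strong ),", nrow(x$edges), "interactions\n")
  print(x$counts)
  invisible(x)
}

#' Convert a perturbome network to an igraph graph
#'
#' @param net a `perturbome_network`.
#' @param collapse if `TRUE` (default) returns the undirected simple
#'   backbone (any edge type contributes adjacency 1), as used by the
#'   core-periphery analysis; otherwise a directed multigraph with an edge
#'   `type` attribute (emergent edges appear once, undirected semantics).
#' @return an igraph object with node attribute `strong`.
#' @export
as_igraph_perturbome <- function(net, collapse = TRUE) {
  stopifnot(inherits(net, "perturbome_network"))
  g <- graph_from_data_frame(net$edges, directed = !collapse,
                             vertices = net$nodes)
  if (collapse) g <- simplify(g)
  g
}

#' Maximum possible number of typed interaction links
#'
#' With `s` strong and `w` weak drugs, a weak-weak pair admits one link
#' type (emergent only), a weak-strong pair two (emergent + directed at
#' the strong drug) and a strong-strong pair three, giving
#' `M_max = w(w-1)/2 + 2ws + 3s(s-1)/2`.
#'
#' @param s number of strong drugs.
#' @param w number of weak drugs.
#' @return integer-valued count of admissible typed links.
#' @export
max_possible_links <- function(s, w) {
  if (s < 0 || w < 0) stop("counts must be non-negative")
  w * (w - 1) / 2 + 2 * w * s + 3 * s * (s - 1) / 2
}

#' Sparseness of an interaction network
#'
#' The ratio of observed to maximally possible typed links.  Given a
#' core/periphery assignment, the breakdown within the core, within the
#' periphery and between them is also reported, each against its own
#' admissible maximum.
#'
#' @param x a `perturbome_network`, or the observed edge count.
#' @param s,w strong/weak counts (taken from the network's nodes when `x`
#'   is a network).
#' @param core optional named logical vector (core membership per drug).
#' @return sparseness fraction, or (with `core`) a list with the overall
#'   value and the within/between breakdown.  `M_max = 0` yields `NaN`
#'   with a warning.
#' @export
network_sparseness <- function(x, s = NULL, w = NULL, core = NULL) {
  if (inherits(x, "perturbome_network")) {
    n_edges <- nrow(x$edges)
    if (is.null(s)) s <- sum(x$nodes$strong)
    if (is.null(w)) w <- sum(!x$nodes$strong)
  } else n_edges <- x
  mm <- max_possible_links(s, w)
  if (mm == 0) {
    warning("no admissible links; sparseness undefined")
    return(NaN)
  }
  overall <- n_edges / mm
  if (is.null(core)) return(overall)
  stopifnot(inherits(x, "perturbome_network"))
  nodes <- x$nodes
  nodes$core <- core[nodes$drug]
  part <- function(sel_from, sel_to) {
    inset <- function(d, sel) nodes$core[match(d, nodes$drug)] == sel
    e <- x$edges
    within <- (inset(e$from, sel_from) & inset(e$to, sel_to)) |
              (inset(e$from, sel_to) & inset(e$to, sel_from))
    sum(within)
  }
  n_cc <- part(TRUE, TRUE); n_pp <- part(FALSE, FALSE)
  n_cp <- nrow(x$edges) - n_cc - n_pp
  mm_of <- function(sel) max_possible_links(
    sum(nodes$strong & nodes$core == sel), sum(!nodes$strong & nodes$core == sel))
  mm_cc <- mm_of(TRUE); mm_pp <- mm_of(FALSE)
  list(overall = overall,
       within_core = if (mm_cc > 0) n_cc / mm_cc else NaN,
       within_periphery = if (mm_pp > 0) n_pp / mm_pp else NaN,
       between = n_cp / (mm - mm_cc - mm_pp),
       edge_counts = c(within_core = n_cc, within_periphery = n_pp,
                       between = n_cp))
}

#' Per-node degree profiles
#'
#' Splits each drug's connectivity into incoming directed, outgoing
#' directed and emergent degree, and tabulates the distribution of each.
#'
#' @param net a `perturbome_network`.
#' @return list with `per_node` (data.frame: drug, in_degree, out_degree,
#'   emergent_degree) and `distributions` (frequency tables per type).
#' @export
degree_profiles <- function(net) {
  stopifnot(inherits(net, "perturbome_network"))
  drugs <- net$nodes$drug
  e <- net$edges
  directed <- e[e$type %in% c("positive", "negative"), , drop = FALSE]
  emergent <- e[e$type == "emergent", , drop = FALSE]
  cnt <- function(x) table(factor(x, levels = drugs))
  per_node <- data.frame(
    drug = drugs,
    in_degree = as.integer(cnt(directed$to)),
    out_degree = as.integer(cnt(directed$from)),
    emergent_degree = as.integer(cnt(emergent$from)) +
      as.integer(cnt(emergent$to)),
    stringsAsFactors = FALSE)
  list(per_node = per_node,
       distributions = list(incoming = table(per_node$in_degree),
                            outgoing = table(per_node$out_degree),
                            emergent = table(per_node$emergent_degree)))
}

# internal: sample replacement singles for every combination
.remap_pairs <- function(combos, singles) {
  remap <- list()
  for (tr in combos) {
    pool <- setdiff(singles, c(tr$drug_a, tr$drug_b))
    if (length(pool) < 2)
      stop("fewer than two singles outside the combination; ",
           "cannot randomize labels")
    remap[[tr$id]] <- sample(pool, 2)
  }
  remap
}

#' Label-swap randomization of the perturbome
#'
#' Tests the specificity of the observed interactions by re-running the
#' full calling pipeline with swapped drug labels: in every iteration each
#' combination AB is decomposed against two distinct single drugs C, D
#' sampled from outside the combination, with identical thresholds and
#' parameters.  The per-type interaction counts of the randomized runs
#' form the null against which the observed counts are expressed as
#' z-scores.
#'
#' @param vectors a [perturbation_vectors()] object.
#' @param n_iter number of randomized perturbomes (>= 2).
#' @param seed RNG seed; a fixed seed makes the null reproducible.
#' @param ... passed to [interaction_calls()].
#' @return An object of class `randomization_result`: data.frame with
#'   observed count, null mean, null s.d. and z-score per interaction
#'   type, plus attributes `n_iter` and `null_counts`.
#' @export
randomize_perturbome <- function(vectors, n_iter = 100L, seed = NULL, ...) {
  if (n_iter < 2) stop("need at least 2 iterations to estimate a s.d.")
  if (!is.null(seed)) set.seed(seed)
  observed <- interaction_calls(vectors, ...)
  types <- c("positive", "negative", "emergent")
  obs <- table(factor(observed$edges$type, levels = types))
  singles <- names(Filter(function(tr) tr$role == "single",
                          vectors$treatments))
  combos <- Filter(function(tr) tr$role == "combination",
                   vectors$treatments)
  null_counts <- matrix(0, n_iter, length(types),
                        dimnames = list(NULL, types))
  for (it in seq_len(n_iter)) {
    remap <- .remap_pairs(combos, singles)
    rnd <- interaction_calls(vectors, remap = remap,
                             thresholds = observed$thresholds, ...)
    null_counts[it, ] <- table(factor(rnd$edges$type, levels = types))
  }
  mu <- colMeans(null_counts)
  sdev <- apply(null_counts, 2, sd)
  res <- data.frame(type = types, observed = as.integer(obs),
                    null_mean = mu, null_sd = sdev,
                    z = ifelse(sdev > 0, (as.integer(obs) - mu) / sdev, NA),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, class = c("randomization_result", "data.frame"),
            n_iter = n_iter, null_counts = null_counts)
}

#' Export a perturbome network
#'
#' `write_network_sif()` writes the simple interaction format (one line
#' per edge: `from type to`); `write_network_graphml()` writes GraphML via
#' igraph with the edge `type` and node `strength` attributes.
#'
#' @param net a `perturbome_network`.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_network_sif <- function(net, file) {
  stopifnot(inherits(net, "perturbome_network"))
  writeLines(paste(net$edges$from, net$edges$type, net$edges$to), file)
  invisible(file)
}

#' @rdname write_network_sif
#' @export
write_network_graphml <- function(net, file) {
  g <- graph_from_data_frame(net$edges, directed = TRUE,
                             vertices = data.frame(
                               name = net$nodes$drug,
                               strength = ifelse(net$nodes$strong,
                                                 "strong", "weak")))
  write_graph(g, file, format = "graphml")
  invisible(file)
}
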