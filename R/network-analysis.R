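#' First-degree neighborhood of a seed gene set
#'
#' Induced subgraph on the seeds present in the network plus all their
#' direct interaction partners — the "disease interactome" when seeded with
#' a disease gene panel. Seeds absent from the network are dropped and
#' reported as attrition.
#'
#' @param net igraph interaction network.
#' @param seeds character vector of seed symbols.
#' @return induced igraph subgraph; attributes `seeds_present` and
#'   `seed_attrition` record how many seeds were found / missing.
#' @export
disease_neighborhood <- function(net, seeds) {
  seeds <- unique(trimws(seeds))
  present <- intersect(seeds, igraph::V(net)$name)
  attrition <- length(seeds) - length(present)
  if (!length(present)) stop_fmt("none of the %d seed gene(s) are in the network", length(seeds))
  if (attrition) log_note("%d of %d seed gene(s) absent from the network",
                          attrition, length(seeds))
  nbrs <- unique(unlist(lapply(igraph::adjacent_vertices(net, present), names)))
  sub <- igraph::induced_subgraph(net, union(present, nbrs))
  attr(sub, "seeds_present") <- length(present)
  attr(sub, "seed_attrition") <- attrition
  sub
}

#' Overlap between a DEG list and a subnetwork's node set
#'
#' @param degs character vector of DEG symbols (or a data.frame with a
#'   `gene` column).
#' @param subnet igraph subnetwork.
#' @return list `n_overlap`, `pct_of_degs` (percent; `NA` for an empty DEG
#'   list), `overlap_genes` (alphabetical).
#' @export
overlap_stats <- function(degs, subnet) {
  if (is.data.frame(degs)) degs <- degs$gene
  degs <- unique(degs)
  ov <- sort_c(intersect(degs, igraph::V(subnet)$name))
  list(n_overlap = length(ov),
       pct_of_degs = if (length(degs)) 100 * length(ov) / length(degs) else NA_real_,
       overlap_genes = ov)
}

#' Reduce a subnetwork to an overlap gene neighborhood
#'
#' Same first-degree-neighborhood construction as
#' [disease_neighborhood()], seeded with the disease-DEG overlap genes:
#' keeps only those genes and their direct partners.
#'
#' @param subnet igraph network.
#' @param overlap_genes seed symbols (e.g. `overlap_stats()$overlap_genes`).
#' @return induced igraph subgraph.
#' @export
reduce_to_overlap_neighborhood <- function(subnet, overlap_genes) {
  disease_neighborhood(subnet, overlap_genes)
}

#' Degree centrality
#' @param net igraph network.
#' @return data.frame `node`, `degree`, alphabetical by node.
#' @export
degree_centrality <- function(net) {
  nodes <- sort_c(igraph::V(net)$name)
  data.frame(node = nodes,
             degree = as.integer(igraph::degree(net)[nodes]),
             stringsAsFactors = FALSE)
}

#' Bottleneck centrality
#'
#' For every root node a BFS shortest-path tree is built over the root's
#' component, with each node's parent fixed as the lexicographically
#' smallest neighbor among its shortest-path predecessors. A node collects
#' one point from a root whenever its subtree holds more than a quarter of
#' the tree's nodes (so every root scores at least its own tree); the
#' bottleneck score is the total over all roots. High scorers sit on many
#' shortest-path trees' trunk lines — classic "bridge" hubs.
#'
#' @param net igraph network (disconnected graphs allowed).
#' @return data.frame `node`, `bottleneck`, alphabetical by node.
#' @export
bottleneck_centrality <- function(net) {
  nodes <- sort_c(igraph::V(net)$name)
  n <- length(nodes)
  if (!n) return(data.frame(node = character(), bottleneck = integer()))
  el <- igraph::as_edgelist(net)
  adj <- vector("list", n)
  if (nrow(el)) {
    a <- match(el[, 1L], nodes); b <- match(el[, 2L], nodes)
    adj <- lapply(seq_len(n), function(i) integer())
    tab <- split(c(b, a) - 1L, c(a, b))
    adj[as.integer(names(tab))] <- lapply(tab, as.integer)
  } else {
    adj <- rep(list(integer()), n)
  }
  data.frame(node = nodes,
             bottleneck = as.integer(bottleneck_scores(adj)),
             stringsAsFactors = FALSE)
}

#' Combined centrality table
#' @param net igraph network.
#' @return data.frame `node`, `degree`, `bottleneck`.
#' @export
centrality_table <- function(net) {
  merge(degree_centrality(net), bottleneck_centrality(net), by = "node",
        sort = TRUE)
}

#' Dual-metric hub prioritization
#'
#' Takes the top `k` nodes by degree and the top `k` by bottleneck
#' centrality (ties broken by node symbol ascending, exactly `k` per
#' metric) and returns their union with the induced subgraph — a modest,
#' high-confidence hub set for downstream functional analysis.
#'
#' @param net igraph network.
#' @param k top-node count per metric (default 100); clamped to the node
#'   count with a warning if larger.
#' @return list `nodes` (alphabetical union), `subgraph` (induced igraph),
#'   `centrality` (full [centrality_table()] with `in_union` flag).
#' @export
prioritize_union <- function(net, k = 100) {
  stopifnot(k >= 1)
  ct <- centrality_table(net)
  if (k > nrow(ct)) {
    warn_fmt("k = %d exceeds the %d nodes; clamped", k, nrow(ct))
    k <- nrow(ct)
  }
  top_by <- function(score) ct$node[order(-score, ct$node)][seq_len(k)]
  sel <- union(top_by(ct$degree), top_by(ct$bottleneck))
  ct$in_union <- ct$node %in% sel
  list(nodes = sort_c(sel),
       subgraph = igraph::induced_subgraph(net, sel),
       centrality = ct)
}
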