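# Independent brute-force oracles and fixture builders used across tests.
# These deliberately share no code with the package implementations.

# Bottleneck centrality by explicit parent-chain walking: for each root,
# distances come from igraph, each node's parent is its lexicographically
# smallest shortest-path predecessor, and subtree sizes are accumulated by
# walking every node's ancestor chain.
oracle_bottleneck <- function(g) {
  nodes <- sort(igraph::V(g)$name, method = "radix")
  D <- igraph::distances(g)[nodes, nodes, drop = FALSE]
  nbrs <- lapply(nodes, function(v) sort(names(igraph::neighbors(g, v)), method = "radix"))
  names(nbrs) <- nodes
  bn <- setNames(integer(length(nodes)), nodes)
  for (s in nodes) {
    comp <- nodes[is.finite(D[s, ])]
    parent <- sapply(comp, function(v) {
      if (v == s) return(NA_character_)
      cand <- nbrs[[v]][D[s, nbrs[[v]]] == D[s, v] - 1]
      cand[1L]
    })
    size <- setNames(integer(length(comp)), comp)
    for (w in comp) {
      v <- w
      while (!is.na(v)) { size[v] <- size[v] + 1L; v <- parent[[v]] }
    }
    bn[comp] <- bn[comp] + as.integer(size > length(comp) / 4)
  }
  bn
}

# Step-up BH by the literal double loop: q_i = min over j with p_j >= p_i of
# p_(j) * m / rank(j).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(vapply(i:m, function(j) min(ps[j] * m / j, 1), numeric(1)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Exact hypergeometric upper tail by direct pmf summation with choose().
oracle_hyper_tail <- function(N, K, n, k) {
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Random labeled simple graph on n nodes with edge probability p.
random_graph <- function(n, p) {
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p
  adipolink::interaction_network(pairs[keep, , drop = FALSE], nodes = nodes)
}

# Graph from an explicit edge string like "A-B,B-C".
graph_from_spec <- function(spec, nodes = NULL) {
  if (!nzchar(spec)) {
    return(adipolink::interaction_network(matrix(character(), ncol = 2),
                                          nodes = nodes))
  }
  e <- do.call(rbind, strsplit(strsplit(spec, ",", fixed = TRUE)[[1]], "-"))
  adipolink::interaction_network(e, nodes = nodes)
}

# Tiny deterministic expression fixture: g genes x s samples around mean 8.
tiny_expression <- function(g = 4, s = 6, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(g * s, 8, 0.5), nrow = g,
              dimnames = list(sprintf("G%02d", seq_len(g)),
                              sprintf("S%02d", seq_len(s))))
  adipolink::expression_matrix(m)
}

two_group_samples <- function(n1, n2, traits = NULL) {
  df <- data.frame(sample_id = c(sprintf("C%02d", seq_len(n1)),
                                 sprintf("T%02d", seq_len(n2))),
                   group = rep(c("control", "case"), c(n1, n2)),
                   stringsAsFactors = FALSE)
  if (!is.null(traits)) df <- cbind(df, traits)
  adipolink::sample_table(df)
}
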