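#' Protein-interaction network construction and IO
#'
#' Networks are undirected simple [igraph][igraph::igraph-package] graphs
#' over gene symbols: no self-loops, no duplicate edges, optional edge
#' attribute `confidence` in \[0, 1\].
#'
#' @param edges two-column character matrix or data.frame of endpoints.
#' @param confidence optional numeric vector of edge confidences in \[0,1\].
#' @param nodes optional extra isolated nodes to include.
#' @return igraph object.
#' @export
interaction_network <- function(edges, confidence = NULL, nodes = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop_fmt("edges must have two endpoint columns")
  mode(edges) <- "character"
  edges[] <- trimws(edges)
  self <- edges[, 1L] == edges[, 2L]
  if (any(self)) {
    log_note("dropped %d self-loop(s)", sum(self))
    edges <- edges[!self, , drop = FALSE]
    confidence <- confidence[!self]
  }
  # canonical endpoint order so (A,B) and (B,A) collapse to one edge
  key <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]),
               sep = "\r")
  keep <- !duplicated(key)
  edges <- edges[keep, , drop = FALSE]
  confidence <- confidence[keep]
  all_nodes <- sort_c(unique(c(as.vector(edges), nodes)))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(all_nodes), name = all_nodes)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, t(matrix(match(edges, all_nodes), ncol = 2L)))
    if (!is.null(confidence)) {
      if (any(confidence < 0 | confidence > 1)) {
        stop_fmt("edge confidence must lie in [0, 1]")
      }
      igraph::E(g)$confidence <- confidence
    }
  }
  g
}

#' Read an interaction network from an edge-list file
#'
#' Accepts 2-3 column TSV (`nodeA TAB nodeB [TAB score]`) and 3-column SIF
#' (`nodeA relation nodeB`). A 3-column line whose last field parses as a
#' number in \[0, 1\] is treated as a scored edge; otherwise the middle
#' field is taken to be a SIF relation label and ignored. Self-loops are
#' dropped (count logged); duplicate and reversed edges collapse; edges
#' with score below `min_confidence` are dropped.
#'
#' @param path edge-list file.
#' @param min_confidence minimum confidence to keep a scored edge.
#' @return igraph object.
#' @export
read_network <- function(path, min_confidence = 0) {
  stopifnot(min_confidence >= 0, min_confidence <= 1)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_fmt("network file '%s' is empty", path)
  fields <- strsplit(lines, "[\t ]+")
  nf <- lengths(fields)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad)) stop_fmt("malformed network line %d in '%s'", bad[1L], path)
  a <- character(length(fields)); b <- character(length(fields))
  score <- rep(NA_real_, length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) == 2L) {
      a[i] <- f[1L]; b[i] <- f[2L]
    } else {
      s <- suppressWarnings(as.numeric(f[3L]))
      if (!is.na(s) && s >= 0 && s <= 1) {        # nodeA nodeB score
        a[i] <- f[1L]; b[i] <- f[2L]; score[i] <- s
      } else {                                    # SIF: nodeA relation nodeB
        a[i] <- f[1L]; b[i] <- f[3L]
      }
    }
  }
  keep <- is.na(score) | score >= min_confidence
  if (any(!keep)) {
    log_note("dropped %d edge(s) below confidence %.3g", sum(!keep), min_confidence)
  }
  conf <- score[keep]
  interaction_network(cbind(a[keep], b[keep]),
                      confidence = if (!all(is.na(conf))) ifelse(is.na(conf), 1, conf))
}

#' Write a network as a 2-3 column TSV edge list
#' @param net igraph object.
#' @param path output path.
#' @export
write_network <- function(net, path) {
  el <- igraph::as_edgelist(net)
  df <- data.frame(nodeA = el[, 1L], nodeB = el[, 2L], stringsAsFactors = FALSE)
  if ("confidence" %in% igraph::edge_attr_names(net)) {
    df$score <- igraph::E(net)$confidence
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
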