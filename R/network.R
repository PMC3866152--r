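# Weighted undirected gene networks and their centrality measures.
#
# Shortest-path measures (closeness, betweenness) run on the unweighted
# skeleton by default: co-occurrence frequencies are similarity-like, not
# distances. An inverse-weight distance mode is available for closeness.

#' Build a gene network from a pair table
#'
#' Nodes are the genes appearing in retained edges; edges are the pairs
#' with weight at or above `min_edge_weight`. The network is undirected
#' with no self-loops.
#'
#' @param table a `pair_table`.
#' @param min_edge_weight minimum co-occurrence weight for an edge.
#' @return an [igraph::igraph] graph with edge attribute `weight` and graph
#'   attribute `kind`.
#' @export
build_network <- function(table, min_edge_weight = 1) {
  stopifnot(inherits(table, "pair_table"))
  keep <- table$weight >= min_edge_weight
  d <- as.data.frame(table)[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(d, directed = FALSE)
  igraph::graph_attr(g, "kind") <- attr(table, "kind")
  g
}

#' Node centrality measures
#'
#' The five measures used for gene ranking. `degree_centrality` is the
#' incident edge count; `weighted_degree` sums incident edge weights;
#' `closeness_centrality` for a node `v` with `r` reachable others is
#' `r / sum of distances`, computed within `v`'s connected component
#' (no whole-graph rescaling; an isolated node scores 0);
#' `betweenness_centrality` is Brandes' shortest-path betweenness on the
#' unweighted skeleton, endpoints excluded, each unordered pair counted
#' once.
#'
#' @param net an igraph network from [build_network()].
#' @param distance_mode `"hop"` (default) treats every edge as distance 1;
#'   `"inverse_weight"` uses 1/weight so that frequent pairs are close.
#' @return named numeric vector over nodes.
#' @name centralities
NULL

#' @rdname centralities
#' @export
degree_centrality <- function(net) {
  igraph::degree(net, loops = FALSE)
}

#' @rdname centralities
#' @export
weighted_degree <- function(net) {
  igraph::strength(net, weights = igraph::E(net)$weight)
}

#' @rdname centralities
#' @export
closeness_centrality <- function(net, distance_mode = c("hop",
                                                        "inverse_weight")) {
  distance_mode <- match.arg(distance_mode)
  if (igraph::vcount(net) == 0L) return(stats::setNames(numeric(0),
                                                        character(0)))
  w <- if (distance_mode == "hop") NA else 1 / igraph::E(net)$weight
  cc <- suppressWarnings(igraph::closeness(net, weights = w,
                                           normalized = TRUE))
  cc[!is.finite(cc)] <- 0  # isolated nodes
  cc
}

#' @rdname centralities
#' @export
betweenness_centrality <- function(net) {
  igraph::betweenness(net, weights = NA, directed = FALSE)
}

#' PageRank by power iteration
#'
#' Weighted PageRank on the undirected network: each edge acts as two
#' directed arcs carrying the edge weight, a random surfer follows arcs
#' with probability proportional to weight and teleports uniformly with
#' probability `1 - damping`. Iterates until the L1 change drops below
#' `tol`; scores sum to 1.
#'
#' @param net a non-empty igraph network.
#' @param damping damping factor (probability of following a link).
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap; exceeding it is an error.
#' @return named numeric vector summing to 1.
#' @export
pagerank_centrality <- function(net, damping = 0.85, tol = 1e-10,
                                max_iter = 1000) {
  n <- igraph::vcount(net)
  if (n == 0L) stop("PageRank is undefined on an empty network",
                    call. = FALSE)
  A <- if (igraph::ecount(net) > 0) {
    igraph::as_adjacency_matrix(net, attr = "weight", sparse = TRUE)
  } else {
    Matrix::Matrix(0, n, n, sparse = TRUE)
  }
  s <- Matrix::rowSums(A)
  dangling <- s == 0
  p <- rep(1 / n, n)
  for (iter in seq_len(max_iter)) {
    out <- p / ifelse(dangling, 1, s)
    out[dangling] <- 0
    p_new <- as.numeric((1 - damping) / n +
                          damping * (Matrix::crossprod(A, out) +
                                       sum(p[dangling]) / n))
    if (sum(abs(p_new - p)) < tol) {
      return(stats::setNames(p_new / sum(p_new), igraph::V(net)$name))
    }
    p <- p_new
  }
  stop(sprintf("PageRank failed to converge within %d iterations", max_iter),
       call. = FALSE)
}

#' All five centrality measures as one table
#'
#' @inheritParams pagerank_centrality
#' @return data.frame with columns `gene`, `degree`, `weighted_degree`,
#'   `closeness`, `betweenness`, `pagerank`, in node order.
#' @export
centrality_table <- function(net, damping = 0.85) {
  data.frame(gene = igraph::V(net)$name,
             degree = as.integer(degree_centrality(net)),
             weighted_degree = weighted_degree(net),
             closeness = closeness_centrality(net),
             betweenness = betweenness_centrality(net),
             pagerank = pagerank_centrality(net),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Top-ranked nodes with an optional value threshold
#'
#' Ranking rule used for the top-25 gene lists: optionally drop nodes below
#' a minimum measure value (used where large tie groups would otherwise
#' flood the list), sort by value descending with lexicographic
#' tie-breaking, and truncate.
#'
#' @param values named numeric vector (node -> measure value).
#' @param k list length cap.
#' @param min_value minimum value to qualify, or `NULL` for no threshold.
#' @return data.frame with columns `gene` and `value`, in rank order.
#' @export
top_nodes <- function(values, k = 25, min_value = NULL) {
  stopifnot(k >= 1)
  if (!is.null(min_value)) values <- values[values >= min_value]
  o <- order(-values, names(values))
  out <- data.frame(gene = names(values)[o], value = unname(values[o]),
                    stringsAsFactors = FALSE)
  utils::head(out, k)
}

#' Louvain modularity clustering
#'
#' Weighted-modularity Louvain partition of the network; deterministic for
#' a given `rng_seed` (the caller's RNG state is untouched).
#'
#' @param net a non-empty igraph network.
#' @param resolution modularity resolution parameter.
#' @param rng_seed integer seed for the (randomized) Louvain sweep order.
#' @return list with `membership` (named integer vector, cluster id per
#'   node) and `modularity_q`.
#' @export
louvain_clusters <- function(net, resolution = 1.0, rng_seed = 1L) {
  if (igraph::vcount(net) == 0L) {
    stop("clustering is undefined on an empty network", call. = FALSE)
  }
  cl <- with_rng_seed(rng_seed,
                      igraph::cluster_louvain(net,
                                              weights = igraph::E(net)$weight,
                                              resolution = resolution))
  list(membership = stats::setNames(as.integer(igraph::membership(cl)),
                                    igraph::V(net)$name),
       modularity_q = igraph::modularity(net, igraph::membership(cl),
                                         weights = igraph::E(net)$weight))
}

#' Export an annotated network
#'
#' Writes the network with whatever vertex attributes have been attached
#' (centrality measures, cluster id, disease category) and the edge
#' weights. GraphML goes through igraph's writer; GEXF 1.2 is written
#' directly.
#'
#' @param net an igraph network.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
export_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' @rdname export_graphml
#' @export
export_gexf <- function(net, path) {
  vnames <- igraph::vertex_attr_names(net)
  attrs <- setdiff(vnames, "name")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl('<?xml version="1.0" encoding="UTF-8"?>')
  wl('<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">')
  wl('  <graph mode="static" defaultedgetype="undirected">')
  if (length(attrs) > 0) {
    wl('    <attributes class="node">')
    for (i in seq_along(attrs)) {
      type <- if (is.numeric(igraph::vertex_attr(net, attrs[i])))
        "double" else "string"
      wl('      <attribute id="%d" title="%s" type="%s"/>',
         i - 1L, xml_escape(attrs[i]), type)
    }
    wl('    </attributes>')
  }
  wl('    <nodes>')
  ids <- igraph::V(net)$name
  for (v in seq_len(igraph::vcount(net))) {
    if (length(attrs) == 0) {
      wl('      <node id="%s" label="%s"/>', xml_escape(ids[v]),
         xml_escape(ids[v]))
    } else {
      wl('      <node id="%s" label="%s">', xml_escape(ids[v]),
         xml_escape(ids[v]))
      wl('        <attvalues>')
      for (i in seq_along(attrs)) {
        val <- igraph::vertex_attr(net, attrs[i], v)
        wl('          <attvalue for="%d" value="%s"/>', i - 1L,
           xml_escape(format(val, scientific = FALSE)))
      }
      wl('        </attvalues>')
      wl('      </node>')
    }
  }
  wl('    </nodes>')
  wl('    <edges>')
  el <- igraph::as_edgelist(net)
  ew <- igraph::E(net)$weight
  for (e in seq_len(nrow(el))) {
    wl('      <edge id="%d" source="%s" target="%s" weight="%s"/>',
       e - 1L, xml_escape(el[e, 1]), xml_escape(el[e, 2]),
       format(ew[e], scientific = FALSE))
  }
  wl('    </edges>')
  wl('  </graph>')
  wl('</gexf>')
  invisible(path)
}
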