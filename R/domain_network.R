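# Domain interaction network: confidence-filtered undirected graph plus the
# topological quantities the HRC method uses (degree k, local clustering
# coefficient C_i, characteristic path length).

#' Build the domain interaction network
#'
#' Keeps edges whose confidence score meets the cutoff (the method uses
#' InterDom-style confidence with a default cutoff of 10), removes
#' self-loops, merges duplicates, and returns an undirected simple graph.
#' Domains known to the run (e.g. present in the domain-protein map) but
#' touched by no surviving edge are carried as isolated nodes with k = 0 and
#' C_i = 0.
#'
#' @param edges edge `data.frame` (`domain_a`, `domain_b`, `confidence`), as
#'   from [read_edge_table()] or [make_edge_table()].
#' @param min_confidence minimum confidence to keep an edge (inclusive).
#' @param isolated_domains character vector of additional domains to include
#'   as isolated nodes.
#' @return object of class `domain_network`.
#' @export
build_network <- function(edges, min_confidence = 10,
                          isolated_domains = character()) {
  edges <- make_edge_table(edges)
  keep <- edges$confidence >= min_confidence
  kept <- edges[keep, , drop = FALSE]
  if (nrow(edges) > 0L && nrow(kept) == 0L) {
    warning("all edges fall below the confidence cutoff; network is empty")
  }
  nodes <- sort(unique(c(kept$domain_a, kept$domain_b,
                         normalize_id(isolated_domains))))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (nrow(kept) > 0L) {
    g <- igraph::add_edges(g, rbind(kept$domain_a, kept$domain_b),
                           confidence = kept$confidence)
  }
  structure(list(graph = g, min_confidence = min_confidence),
            class = "domain_network")
}

#' @export
print.domain_network <- function(x, ...) {
  cat(sprintf("domain_network: %d domains, %d interactions (confidence >= %g)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$min_confidence))
  invisible(x)
}

#' Extract the underlying igraph object
#' @param network a `domain_network`.
#' @return an `igraph` graph.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "domain_network"))
  network$graph
}

#' Node names of a domain network
#' @param network a `domain_network`.
#' @return character vector of domain accessions.
#' @export
network_domains <- function(network) {
  igraph::V(as_igraph(network))$name
}

#' Degree of domains in the network
#'
#' @param network a `domain_network`.
#' @param nodes domains to query (default: all).
#' @return named integer vector of degrees k.
#' @export
domain_degree <- function(network, nodes = NULL) {
  g <- as_igraph(network)
  if (is.null(nodes)) nodes <- igraph::V(g)$name
  nodes <- normalize_id(nodes)
  missing <- setdiff(nodes, igraph::V(g)$name)
  if (length(missing) > 0L) {
    stop("unknown domain(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  d <- igraph::degree(g, v = nodes)
  setNames(as.integer(d), nodes)
}

#' Interaction partners of a domain
#' @param network a `domain_network`.
#' @param node a domain accession.
#' @return character vector of distinct partner domains.
#' @export
domain_partners <- function(network, node) {
  g <- as_igraph(network)
  node <- normalize_id(node)
  if (!node %in% igraph::V(g)$name) {
    stop("unknown domain: ", node, call. = FALSE)
  }
  sort(igraph::neighbors(g, node)$name)
}

#' Local clustering coefficient C_i
#'
#' Fraction of a domain's neighbor pairs that are themselves connected:
#' `C_i = 2 * t_i / (k_i * (k_i - 1))` where `t_i` counts edges among the
#' neighbors. `C_i` is 1 when all neighbors are linked to each other and 0
#' when the neighborhood is locally sparse. Nodes of degree 0 or 1 are
#' assigned `C_i = 0` (not `NaN`), so every candidate can be compared
#' against the HRC cutoff.
#'
#' @param network a `domain_network`.
#' @param nodes domains to query (default: all).
#' @return named numeric vector of clustering coefficients in \[0, 1\].
#' @export
clustering_coefficient <- function(network, nodes = NULL) {
  g <- as_igraph(network)
  if (is.null(nodes)) nodes <- igraph::V(g)$name
  nodes <- normalize_id(nodes)
  missing <- setdiff(nodes, igraph::V(g)$name)
  if (length(missing) > 0L) {
    stop("unknown domain(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(nodes) == 0L) return(setNames(numeric(0), character(0)))
  ci <- igraph::transitivity(g, type = "local", vids = nodes,
                             isolates = "zero")
  setNames(as.numeric(ci), nodes)
}

#' Topological summary of the domain network
#'
#' Node and edge counts, mean degree, mean local clustering coefficient
#' (degree-0/1 nodes contribute 0), and the characteristic path length: the
#' mean shortest-path length over connected pairs of the largest connected
#' component (disconnected pairs are excluded rather than counted as
#' infinite).
#'
#' @param network a non-empty `domain_network`.
#' @return object of class `network_summary` (a list with `node_count`,
#'   `edge_count`, `mean_degree`, `mean_clustering`,
#'   `characteristic_path_length`).
#' @export
network_summary <- function(network) {
  g <- as_igraph(network)
  if (igraph::vcount(g) == 0L) stop("empty network", call. = FALSE)
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  cpl <- if (igraph::vcount(giant) > 1L) {
    igraph::mean_distance(giant, directed = FALSE)
  } else NA_real_
  out <- list(node_count = igraph::vcount(g),
              edge_count = igraph::ecount(g),
              mean_degree = 2 * igraph::ecount(g) / igraph::vcount(g),
              mean_clustering = mean(clustering_coefficient(network)),
              characteristic_path_length = cpl)
  class(out) <- "network_summary"
  out
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf(paste0("network summary: %d nodes, %d edges, mean k = %.3g, ",
                     "mean C_i = %.3g, characteristic path length = %.3g\n"),
              x$node_count, x$edge_count, x$mean_degree, x$mean_clustering,
              x$characteristic_path_length))
  invisible(x)
}

#' Per-domain topology table
#'
#' @param network a `domain_network`.
#' @return `data.frame` with columns `domain`, `degree`,
#'   `clustering_coefficient`, sorted by domain.
#' @export
network_node_table <- function(network) {
  doms <- network_domains(network)
  data.frame(domain = doms,
             degree = as.integer(domain_degree(network, doms)),
             clustering_coefficient = as.numeric(
               clustering_coefficient(network, doms)),
             stringsAsFactors = FALSE)
}
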