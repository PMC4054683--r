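#' Generate a community-structured (planted-partition) interaction network
#'
#' Nodes are split into `n_clusters` near-equal blocks; each within-block
#' pair is connected independently with probability `p_in` and each
#' cross-block pair with probability `p_out`. The planted block label is
#' kept as the vertex attribute `block` so that clustering recovery can be
#' scored against the truth.
#'
#' With `degree_heterogeneity > 0` the model is degree-corrected: every
#' node gets a lognormal propensity with mean 1 (sdlog =
#' `degree_heterogeneity`) multiplying its edge probabilities, giving the
#' heavy-tailed degree distribution real protein-interaction networks
#' show while leaving expected edge counts unchanged.
#'
#' @param n_nodes Number of nodes, or leave `NULL` and give `nodes`.
#' @param n_clusters Number of planted blocks.
#' @param p_in,p_out Within-/between-block edge probabilities
#'   (`p_in > p_out`).
#' @param seed Integer seed.
#' @param nodes Optional character vector of node (gene) identifiers used
#'   instead of synthetic ids.
#' @param degree_heterogeneity Lognormal sdlog of node propensities;
#'   0 (default) gives the plain planted-partition model.
#' @return An undirected simple `igraph` graph with vertex attributes
#'   `name` and `block`.
#' @export
generate_ppi_network <- function(n_nodes = NULL, n_clusters = 4,
                                 p_in = 0.3, p_out = 0.01, seed = 1L,
                                 nodes = NULL, degree_heterogeneity = 0) {
  if (is.null(nodes)) {
    n_nodes <- check_count(n_nodes, "n_nodes", min = 2)
    nodes <- sprintf("N%04d", seq_len(n_nodes))
  }
  n_nodes <- length(nodes)
  n_clusters <- check_count(n_clusters, "n_clusters")
  check_prob(p_in, "p_in"); check_prob(p_out, "p_out")
  if (p_in <= p_out) {
    abort("`p_in` must exceed `p_out`", class = "transppi_invalid_parameter")
  }

  with_seed(seed, {
    block <- rep(seq_len(n_clusters), length.out = n_nodes)
    block <- block[order(rep(seq_len(n_clusters),
                             length.out = n_nodes))] # contiguous blocks
    ij <- utils::combn(n_nodes, 2)
    same <- block[ij[1, ]] == block[ij[2, ]]
    p <- ifelse(same, p_in, p_out)
    if (degree_heterogeneity > 0) {
      w <- stats::rlnorm(n_nodes, -degree_heterogeneity^2 / 2,
                         degree_heterogeneity)
      p <- pmin(p * w[ij[1, ]] * w[ij[2, ]], 1)
    }
    keep <- runif(ncol(ij)) < p
    g <- igraph::graph_from_edgelist(
      cbind(nodes[ij[1, keep]], nodes[ij[2, keep]]), directed = FALSE)
    g <- g + igraph::vertices(setdiff(nodes, igraph::V(g)$name))
    g <- igraph::permute(g, match(igraph::V(g)$name, nodes))
    igraph::V(g)$block <- block
    g
  })
}

#' Load an interaction network from a two-column edge list
#'
#' Duplicate edges (in either orientation) are collapsed and self-loops
#' dropped with a warning; the resulting graph is simple and undirected.
#'
#' @param path Tab-separated file whose first two columns are node ids,
#'   or a two-column character matrix/data frame.
#' @return An undirected simple `igraph` graph.
#' @export
load_network <- function(path) {
  el <- if (is.character(path) && length(path) == 1) {
    as.matrix(readr::read_tsv(path, col_names = FALSE,
                              show_col_types = FALSE,
                              col_types = readr::cols(
                                .default = readr::col_character()))[, 1:2])
  } else {
    as.matrix(path)[, 1:2, drop = FALSE]
  }
  loops <- el[, 1] == el[, 2]
  if (any(loops)) {
    warn(sprintf("dropped %d self-loop(s)", sum(loops)))
    el <- el[!loops, , drop = FALSE]
  }
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  message(sprintf("network: %d nodes, %d edges",
                  igraph::vcount(g), igraph::ecount(g)))
  g
}

#' @rdname load_network
#' @param network An `igraph` graph.
#' @export
write_edge_list <- function(network, path) {
  el <- igraph::as_edgelist(network)
  readr::write_tsv(tibble::tibble(from = el[, 1], to = el[, 2]), path,
                   col_names = FALSE)
  invisible(path)
}

#' Node degree
#'
#' Number of edges incident on each requested node.
#'
#' @param network An `igraph` graph.
#' @param nodes Node identifiers (default: all).
#' @return Named integer vector of degrees.
#' @export
ppi_degree <- function(network, nodes = igraph::V(network)$name) {
  missing_nodes <- setdiff(nodes, igraph::V(network)$name)
  if (length(missing_nodes)) {
    abort(sprintf("nodes not in network: %s",
                  paste(missing_nodes, collapse = ", ")),
          class = "transppi_invalid_parameter")
  }
  d <- igraph::degree(network, v = nodes)
  stats::setNames(as.integer(d), nodes)
}

#' All-pairs shortest-path distances with a disconnected-component
#' convention
#'
#' Hop-count geodesic distances between every pair of nodes. Pairs in
#' different connected components are assigned twice the maximum finite
#' distance observed within any component, so downstream averages remain
#' defined on fragmented networks.
#'
#' @param network An `igraph` graph.
#' @return A symmetric integer matrix with zero diagonal and attribute
#'   `cross_component_value` (the substituted cross-component distance,
#'   `NA` when the graph is connected).
#' @export
all_pairs_distances <- function(network) {
  D <- igraph::distances(network, algorithm = "unweighted")
  finite <- D[is.finite(D)]
  mx <- if (length(finite)) max(finite) else 0
  cross <- if (mx > 0) 2 * mx else 2
  disconnected <- any(is.infinite(D))
  D[is.infinite(D)] <- cross
  attr(D, "cross_component_value") <- if (disconnected) cross else NA_real_
  D
}

#' Canonical shortest path between two nodes
#'
#' Breadth-first geodesic with a deterministic tie-break: the path is
#' reconstructed backwards from the target, at each layer stepping to the
#' lexicographically smallest neighbour one layer closer to the source.
#'
#' @param network An `igraph` graph.
#' @param source,target Node identifiers in the same component.
#' @return A list of class `path_record` with `nodes` (ordered ids),
#'   `length` (edge count) and `intermediates` (nodes minus endpoints).
#' @export
shortest_path <- function(network, source, target) {
  ids <- igraph::V(network)$name
  if (!all(c(source, target) %in% ids)) {
    abort("source/target not in network", class = "transppi_invalid_parameter")
  }
  d <- igraph::distances(network, v = source, algorithm = "unweighted")[1, ]
  if (is.infinite(d[[target]])) {
    abort(sprintf("no path between %s and %s (different components)",
                  source, target),
          class = "transppi_no_path_error")
  }
  path <- target
  cur <- target
  while (cur != source) {
    nb <- igraph::V(network)$name[
      igraph::neighbors(network, cur)]
    prev <- sort(nb[d[nb] == d[[cur]] - 1])[1]
    path <- c(prev, path)
    cur <- prev
  }
  structure(list(nodes = path, length = length(path) - 1L,
                 intermediates = path[-c(1, length(path))]),
            class = "path_record")
}

#' @export
print.path_record <- function(x, ...) {
  cat(sprintf("<path_record> %s (%d edges)\n",
              paste(x$nodes, collapse = " - "), x$length))
  invisible(x)
}

#' Louvain modularity clustering
#'
#' Partitions the network by greedy modularity optimisation (Louvain
#' two-phase heuristic). Cluster ids are renumbered by decreasing size
#' (ties by smallest member id) for stable reporting; randomness in the
#' node sweep is controlled by `seed`. An edgeless graph yields the
#' degenerate singleton partition with a warning and `modularity_q = 0`.
#'
#' @param network An `igraph` graph.
#' @param seed Integer seed.
#' @return A `ppi_partition`: tibble `(node, cluster)` with attributes
#'   `modularity_q`, `sizes` and `n_nontrivial` (clusters of size >= 2).
#' @export
louvain_clusters <- function(network, seed = 1L) {
  nodes <- igraph::V(network)$name
  if (igraph::ecount(network) == 0) {
    warn("network has no edges; returning singleton partition (q = 0)")
    membership <- seq_along(nodes)
    q <- 0
  } else {
    cl <- with_seed(seed, igraph::cluster_louvain(network))
    membership <- igraph::membership(cl)
    q <- igraph::modularity(network, membership)
  }
  # renumber by decreasing size, ties by smallest member id
  first_member <- tapply(nodes, membership, min)
  sizes <- table(membership)
  ord <- order(-as.integer(sizes), first_member)
  relabel <- stats::setNames(seq_along(ord), names(sizes)[ord])
  cluster <- as.integer(relabel[as.character(membership)])
  out <- tibble::tibble(node = nodes, cluster = cluster)
  attr(out, "modularity_q") <- q
  attr(out, "sizes") <- as.integer(table(cluster))
  attr(out, "n_nontrivial") <- sum(table(cluster) >= 2)
  class(out) <- c("ppi_partition", class(out))
  out
}

#' Newman-Girvan modularity of a given partition
#'
#' @param network An `igraph` graph.
#' @param assignment A `ppi_partition`, or a named vector / two-column
#'   data frame mapping every node to a cluster id.
#' @return Modularity Q in `[-0.5, 1]`.
#' @export
network_modularity <- function(network, assignment) {
  nodes <- igraph::V(network)$name
  memb <- if (is.data.frame(assignment)) {
    stats::setNames(assignment$cluster, assignment$node)
  } else assignment
  if (!all(nodes %in% names(memb))) {
    abort("assignment must cover every network node",
          class = "transppi_invalid_parameter")
  }
  igraph::modularity(network, as.integer(factor(memb[nodes])))
}

#' @export
tidy.ppi_partition <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("node", "cluster")])
}

#' @export
glance.ppi_partition <- function(x, ...) {
  tibble::tibble(modularity_q = attr(x, "modularity_q"),
                 n_clusters = length(attr(x, "sizes")),
                 n_nontrivial = attr(x, "n_nontrivial"),
                 n_nodes = nrow(x))
}
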