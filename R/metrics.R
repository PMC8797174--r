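#' Shortest-path distances with inverse-weight link lengths
#'
#' The stronger an association, the shorter the social distance: every edge
#' of weight `w` has length `1 / w`, and the distance between two nodes is
#' the minimum total length over paths connecting them. Unreachable pairs
#' get `Inf`; the diagonal is 0.
#'
#' @param net An [assoc_network()].
#' @return A symmetric numeric matrix of distances, dimnames = node ids.
#' @export
shortest_path_lengths <- function(net) {
  g <- as_igraph(net)
  w <- if (igraph::ecount(g)) 1 / igraph::E(g)$weight else NULL
  igraph::distances(g, weights = w)
}

#' Betweenness centrality under inverse-weight link lengths
#'
#' The number of shortest paths (computed on link lengths `1 / weight`)
#' passing through each node as an intermediary, endpoints excluded, with
#' the standard fractional split among tied geodesics (Brandes accounting).
#' Unnormalized. Set `weighted = FALSE` for binary shortest paths on the
#' unweighted skeleton.
#'
#' @param net An [assoc_network()].
#' @param weighted Use inverse-weight link lengths (default) or hop counts.
#' @return A tibble with columns `id` and `betweenness`.
#' @export
node_betweenness <- function(net, weighted = TRUE) {
  g <- as_igraph(net)
  if (weighted && igraph::ecount(g)) {
    b <- igraph::betweenness(g, directed = FALSE, weights = 1 / igraph::E(g)$weight)
  } else {
    # weights = NA: ignore the weight attribute, use hop counts
    b <- igraph::betweenness(g, directed = FALSE, weights = NA)
  }
  tibble(id = names(b), betweenness = unname(b))
}

#' Global clustering coefficient (transitivity)
#'
#' The ratio of closed triplets to all (open and closed) triplets, computed
#' on the unweighted skeleton of the network (edge weights are ignored).
#' Returns `NaN` when the network has no connected triplets.
#'
#' @param net An [assoc_network()].
#' @return Transitivity in `[0, 1]` (or `NaN`).
#' @export
clustering_coefficient <- function(net) {
  igraph::transitivity(as_igraph(net), type = "global")
}

#' Weighted diameter
#'
#' The maximum shortest-path distance (inverse-weight link lengths) over all
#' reachable pairs of nodes. On a fragmented network the maximum is taken
#' over reachable pairs only and the result carries attribute
#' `disconnected = TRUE`, so deletion trajectories remain comparable.
#'
#' @param net An [assoc_network()] with at least one edge.
#' @return The diameter (numeric), with logical attribute `disconnected`.
#' @export
weighted_diameter <- function(net) {
  if (n_edges(net) == 0) abort("Diameter is undefined on an edgeless network.")
  d <- shortest_path_lengths(net)
  off <- d[upper.tri(d)]
  disconnected <- any(!is.finite(off))
  structure(max(off[is.finite(off)]), disconnected = disconnected)
}

#' Weighted global efficiency
#'
#' The mean, over all ordered pairs of distinct nodes, of the reciprocal
#' shortest-path distance (inverse-weight link lengths). Unreachable pairs
#' contribute zero efficiency, so the measure is defined on fragmented
#' networks and equals 0 on an edgeless one. A complete network with all
#' weights `w` has efficiency exactly `w`.
#'
#' @param net An [assoc_network()] with at least two nodes.
#' @return Efficiency (numeric, >= 0).
#' @export
global_efficiency <- function(net) {
  if (n_nodes(net) < 2) abort("Efficiency needs at least two nodes.")
  d <- shortest_path_lengths(net)
  inv <- 1 / d
  inv[!is.finite(inv) | inv < 0] <- 0 # diagonal (1/0) and unreachable (1/Inf)
  diag(inv) <- 0
  sum(inv) / (nrow(d) * (nrow(d) - 1))
}

#' Weighted modularity via leading-eigenvector communities
#'
#' Detects communities with Newman's leading-eigenvector method on the
#' weighted network, then returns the weighted modularity Q of the detected
#' partition: the fraction of edge weight within communities minus its
#' expectation under a strength-preserving random rewiring.
#'
#' @param net An [assoc_network()] with at least one edge.
#' @return A list with `membership` (named integer vector) and `q`.
#' @export
weighted_modularity <- function(net) {
  if (n_edges(net) == 0) abort("Modularity is undefined on an edgeless network.")
  g <- as_igraph(net)
  cl <- igraph::cluster_leading_eigen(g, weights = igraph::E(g)$weight)
  memb <- igraph::membership(cl)
  list(
    membership = memb,
    q = igraph::modularity(g, memb, weights = igraph::E(g)$weight)
  )
}

#' Number of connected components
#'
#' Isolated nodes count as components of size one.
#'
#' @param net An [assoc_network()].
#' @return Integer >= 1 (0 for an empty node set).
#' @export
component_count <- function(net) {
  igraph::components(as_igraph(net))$no
}

#' Degree and strength of every node
#'
#' Convenience accessor (degree correlates strongly with betweenness on
#' these networks; betweenness is the deletion metric used by the
#' experiments).
#'
#' @param net An [assoc_network()].
#' @return Tibble with `id`, `degree`, `strength`.
#' @export
node_degree <- function(net) {
  g <- as_igraph(net)
  tibble(
    id = igraph::V(g)$name,
    degree = unname(igraph::degree(g)),
    strength = unname(igraph::strength(g, weights = igraph::E(g)$weight))
  )
}

#' All four global network indices at once
#'
#' Computes the index set tracked by the deletion experiments: unweighted
#' clustering coefficient, weighted diameter, weighted global efficiency and
#' weighted leading-eigenvector modularity, plus the component count and a
#' fragmentation flag.
#'
#' @param net An [assoc_network()].
#' @return A one-row tibble: `clustering`, `diameter`, `efficiency`,
#'   `modularity`, `n_components`, `disconnected`.
#' @examples
#' pop <- generate_population(population_config(1, 1, 1), seed = 1)
#' net <- simulate_network(pop, n_steps = 50, snapshot_at = 50, seed = 1)$network[[1]]
#' network_metrics(net)
#' @export
network_metrics <- function(net) {
  stopifnot(inherits(net, "assoc_network"))
  if (n_edges(net) == 0) {
    return(tibble(
      clustering = NaN, diameter = NA_real_, efficiency = 0,
      modularity = NA_real_, n_components = component_count(net),
      disconnected = n_nodes(net) > 1
    ))
  }
  diam <- weighted_diameter(net)
  ncomp <- component_count(net)
  tibble(
    clustering = clustering_coefficient(net),
    diameter = as.numeric(diam),
    efficiency = global_efficiency(net),
    modularity = weighted_modularity(net)$q,
    n_components = ncomp,
    disconnected = ncomp > 1
  )
}
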