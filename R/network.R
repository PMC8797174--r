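#' Weighted association networks
#'
#' The package's network container is deliberately light: a tibble edge list
#' (`id_a`, `id_b`, `weight`) plus a roster of nodes with their age category
#' and group memberships. Edge weights are strictly positive -- an absent
#' edge means weight zero. Empirically assembled networks carry association
#' indices in `[0, 1]`; simulated networks carry integer interaction counts.
#'
#' @param edges Tibble with columns `id_a`, `id_b`, `weight`.
#' @param roster Population roster (see [generate_population()]); defaults
#'   to a minimal roster built from the edge endpoints. Isolated nodes can
#'   only be represented through the roster.
#' @param id Optional network identifier (used in experiment output tables).
#' @return An object of class `"assoc_network"`: a list with elements
#'   `edges`, `roster`, `id`.
#' @examples
#' net <- assoc_network(tibble::tibble(id_a = "a", id_b = "b", weight = 0.5))
#' @export
assoc_network <- function(edges, roster = NULL, id = NULL) {
  edges <- as_tibble(edges)
  required <- c("id_a", "id_b", "weight")
  missing <- setdiff(required, names(edges))
  if (length(missing)) {
    abort(sprintf("Edge list is missing columns: %s", paste(missing, collapse = ", ")))
  }
  edges$id_a <- as.character(edges$id_a)
  edges$id_b <- as.character(edges$id_b)
  if (any(edges$id_a == edges$id_b)) abort("Self-loops are not allowed.")
  if (any(!is.finite(edges$weight)) || any(edges$weight <= 0)) {
    abort("Edge weights must be finite and strictly positive.")
  }
  if (anyDuplicated(pair_key(edges$id_a, edges$id_b))) {
    abort("Duplicate edges (the network is undirected).")
  }
  endpoints <- unique(c(edges$id_a, edges$id_b))
  if (is.null(roster)) {
    roster <- tibble(
      id = endpoints, age_category = NA_character_,
      core_id = NA_character_, bond_id = NA_character_, clan_id = NA_character_
    )
  } else {
    roster <- as_tibble(roster)
    if (!all(endpoints %in% roster$id)) {
      abort(sprintf(
        "Edge endpoints missing from roster: %s",
        paste(setdiff(endpoints, roster$id), collapse = ", ")
      ))
    }
  }
  structure(
    list(edges = select(edges, "id_a", "id_b", "weight"), roster = roster,
         id = id %||% "net"),
    class = "assoc_network"
  )
}

#' @export
print.assoc_network <- function(x, ...) {
  cat(sprintf(
    "<assoc_network '%s'>  %d nodes, %d edges, weights in [%.4g, %.4g]\n",
    x$id, nrow(x$roster), nrow(x$edges),
    if (nrow(x$edges)) min(x$edges$weight) else NA,
    if (nrow(x$edges)) max(x$edges$weight) else NA
  ))
  invisible(x)
}

#' Number of nodes and edges of a network
#'
#' @param net An [assoc_network()].
#' @return Integer count.
#' @export
n_nodes <- function(net) {
  stopifnot(inherits(net, "assoc_network"))
  nrow(net$roster)
}

#' @rdname n_nodes
#' @export
n_edges <- function(net) {
  stopifnot(inherits(net, "assoc_network"))
  nrow(net$edges)
}

# igraph view of an assoc_network; vertices are all roster ids (isolates kept)
as_igraph <- function(net) {
  stopifnot(inherits(net, "assoc_network"))
  vertices <- net$roster
  g <- igraph::graph_from_data_frame(
    d = data.frame(
      from = net$edges$id_a, to = net$edges$id_b, weight = net$edges$weight
    ),
    directed = FALSE,
    vertices = data.frame(name = vertices$id, vertices[-match("id", names(vertices))])
  )
  g
}

# fraction of all unordered dyads carrying at least one edge
network_density <- function(net) {
  n <- n_nodes(net)
  if (n < 2) return(NA_real_)
  nrow(net$edges) / (n * (n - 1) / 2)
}
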