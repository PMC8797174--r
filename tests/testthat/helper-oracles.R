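# Brute-force oracles, independent of the package's metric implementations.
# All operate on a plain edge data frame (id_a, id_b, weight) plus a node
# vector, using inverse-weight link lengths.

# adjacency matrix of link lengths (Inf = no edge)
oracle_length_matrix <- function(edges, nodes) {
  n <- length(nodes)
  m <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(m) <- 0
  for (k in seq_len(nrow(edges))) {
    i <- match(edges$id_a[k], nodes)
    j <- match(edges$id_b[k], nodes)
    m[i, j] <- m[j, i] <- 1 / edges$weight[k]
  }
  m
}

# all-pairs shortest paths by Floyd-Warshall
oracle_distances <- function(edges, nodes) {
  d <- oracle_length_matrix(edges, nodes)
  n <- length(nodes)
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      via <- d[i, k] + d[k, ]
      d[i, ] <- pmin(d[i, ], via)
    }
  }
  d
}

oracle_efficiency <- function(edges, nodes) {
  d <- oracle_distances(edges, nodes)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  n <- length(nodes)
  sum(inv) / (n * (n - 1))
}

oracle_diameter <- function(edges, nodes) {
  d <- oracle_distances(edges, nodes)
  off <- d[upper.tri(d)]
  max(off[is.finite(off)])
}

# global transitivity by O(n^3) triplet census on the unweighted skeleton
oracle_transitivity <- function(edges, nodes) {
  n <- length(nodes)
  a <- oracle_length_matrix(edges, nodes) < Inf
  diag(a) <- FALSE
  closed <- 0
  triplets <- 0
  for (v in seq_len(n)) {
    nb <- which(a[v, ])
    k <- length(nb)
    if (k < 2) next
    pairs <- utils::combn(nb, 2)
    triplets <- triplets + ncol(pairs)
    closed <- closed + sum(a[cbind(pairs[1, ], pairs[2, ])])
  }
  if (triplets == 0) return(NaN)
  closed / triplets
}

# betweenness by exhaustive enumeration of simple paths (small n only):
# for each unordered pair, find all simple paths, keep those of minimal
# length, and credit each interior node 1/(number of shortest paths).
oracle_betweenness <- function(edges, nodes) {
  len <- oracle_length_matrix(edges, nodes)
  n <- length(nodes)
  score <- stats::setNames(numeric(n), nodes)
  all_simple_paths <- function(s, t) {
    paths <- list()
    walk <- function(v, visited, total) {
      if (v == t) {
        paths[[length(paths) + 1]] <<- list(path = visited, length = total)
        return(invisible())
      }
      for (w in seq_len(n)) {
        if (is.finite(len[v, w]) && len[v, w] > 0 && !(w %in% visited)) {
          walk(w, c(visited, w), total + len[v, w])
        }
      }
    }
    walk(s, s, 0)
    paths
  }
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      paths <- all_simple_paths(s, t)
      if (!length(paths)) next
      lens <- vapply(paths, `[[`, numeric(1), "length")
      best <- min(lens)
      shortest <- paths[lens <= best + 1e-12]
      for (p in shortest) {
        interior <- setdiff(p$path, c(s, t))
        score[interior] <- score[interior] + 1 / length(shortest)
      }
    }
  }
  score
}

oracle_component_count <- function(edges, nodes) {
  # union-find
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (k in seq_len(nrow(edges))) {
    i <- find(match(edges$id_a[k], nodes))
    j <- find(match(edges$id_b[k], nodes))
    if (i != j) parent[i] <- j
  }
  length(unique(vapply(seq_along(nodes), find, numeric(1))))
}

# modularity Q of a given membership on a weighted graph
oracle_modularity_q <- function(edges, nodes, membership) {
  w <- edges$weight
  total <- 2 * sum(w)
  strength <- stats::setNames(numeric(length(nodes)), nodes)
  for (k in seq_len(nrow(edges))) {
    strength[edges$id_a[k]] <- strength[edges$id_a[k]] + w[k]
    strength[edges$id_b[k]] <- strength[edges$id_b[k]] + w[k]
  }
  q <- 0
  for (k in seq_len(nrow(edges))) {
    if (membership[edges$id_a[k]] == membership[edges$id_b[k]]) {
      q <- q + 2 * w[k] / total
    }
  }
  for (comm in unique(membership)) {
    a <- sum(strength[names(membership)[membership == comm]]) / total
    q <- q - a^2
  }
  q
}

# best bipartition of a small graph by exhaustive search (<= ~14 nodes)
oracle_best_bipartition <- function(edges, nodes) {
  n <- length(nodes)
  best_q <- -Inf
  best <- NULL
  for (code in 0:(2^(n - 1) - 1)) {
    membership <- stats::setNames(
      c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L), nodes
    )
    q <- oracle_modularity_q(edges, nodes, membership)
    if (q > best_q) {
      best_q <- q
      best <- membership
    }
  }
  list(membership = best, q = best_q)
}

# -- fixture builders ---------------------------------------------------------

# random connected-ish weighted graph with continuous weights (no ties)
random_test_network <- function(n, p = 0.4, id = "rnd") {
  nodes <- sprintf("v%02d", seq_len(n))
  idx <- utils::combn(n, 2)
  keep <- stats::runif(ncol(idx)) < p
  # ensure at least a spanning path so most graphs are connected
  edges <- tibble::tibble(
    id_a = c(nodes[seq_len(n - 1)], nodes[idx[1, keep]]),
    id_b = c(nodes[seq(2, n)], nodes[idx[2, keep]]),
    weight = stats::runif(n - 1 + sum(keep), 0.1, 5)
  )
  edges <- edges[!duplicated(paste(pmin(edges$id_a, edges$id_b),
                                   pmax(edges$id_a, edges$id_b))), ]
  assoc_network(edges, id = id)
}

make_net <- function(id_a, id_b, weight, roster = NULL, id = "fix") {
  assoc_network(tibble::tibble(id_a = id_a, id_b = id_b, weight = weight),
                roster = roster, id = id)
}

# tiny two-core-group roster used across assembly tests
two_group_roster <- function() {
  tibble::tibble(
    id = c("g1", "g2", "g3", "b1", "b2"),
    age_category = c("matriarch", "young_adult", "prime_adult",
                     "matriarch", "young_adult"),
    core_id = c("G", "G", "G", "B", "B"),
    bond_id = c("B1", "B1", "B1", "B1", "B1"),
    clan_id = "K1"
  )
}

expect_setequal_num <- function(x, y, tol = 1e-9) {
  expect_equal(sort(as.numeric(x)), sort(as.numeric(y)), tolerance = tol)
}

# small simulated network with roster, reused across experiment tests
sim_fixture <- function(seed = 50, cfg = population_config(1, 2, c(1, 2))) {
  pop <- generate_population(cfg, seed = seed)
  simulate_network(pop, n_steps = 200, snapshot_at = 200,
                   seed = seed + 1)$network[[1]]
}
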