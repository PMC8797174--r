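#' Build the targeted-deletion pool of a network
#'
#' Ranks nodes on the intact network by the deletion metric -- betweenness
#' centrality (inverse-weight geodesics) or age-category rank (matriarchs
#' highest) -- and returns the top `pool_fraction` of nodes. Ties at the
#' pool boundary, and ordering within an age category, are broken by the
#' current RNG stream. The pool is what the incremental targeted deletions
#' draw from: its membership is fixed; only the removal order varies across
#' replicates.
#'
#' @param net An [assoc_network()] whose roster carries age categories when
#'   `metric = "age_category"`.
#' @param metric `"betweenness"` or `"age_category"`.
#' @param pool_fraction Fraction of nodes in the pool (default 0.20).
#' @return Character vector of node ids, length `round_half_up(pool_fraction * n)`.
#' @export
deletion_pool <- function(net, metric = c("betweenness", "age_category"),
                          pool_fraction = 0.2) {
  metric <- match.arg(metric)
  n <- n_nodes(net)
  if (n == 0) abort("Empty network.")
  pool_size <- round_half_up(pool_fraction * n)
  if (pool_size == 0) return(character(0))

  score <- switch(metric,
    betweenness = {
      b <- node_betweenness(net)
      stats::setNames(b$betweenness, b$id)[net$roster$id]
    },
    age_category = {
      if (anyNA(net$roster$age_category)) {
        abort("Age-targeted deletion needs age categories in the roster.")
      }
      stats::setNames(age_rank(net$roster$age_category), net$roster$id)
    }
  )
  # random tiebreak => boundary ties resolved by the RNG
  ord <- order(-score, stats::runif(n))
  net$roster$id[ord][seq_len(pool_size)]
}

#' Select nodes for a targeted deletion
#'
#' Shuffles the (static) targeted pool and returns the first
#' `round_half_up(proportion * n)` nodes -- the removal set for one targeted
#' deletion at the given proportion.
#'
#' @inheritParams deletion_pool
#' @param proportion Deletion proportion in `[0, pool_fraction]`.
#' @return Character vector of node ids to remove.
#' @export
select_targets <- function(net, metric = c("betweenness", "age_category"),
                           proportion, pool_fraction = 0.2) {
  if (proportion < 0 || proportion > pool_fraction + 1e-12) {
    abort("`proportion` must lie in [0, pool_fraction].")
  }
  pool <- deletion_pool(net, metric, pool_fraction)
  k <- round_half_up(proportion * n_nodes(net))
  sample(pool)[seq_len(k)]
}

#' Select nodes for a random deletion
#'
#' Uniform sample without replacement of `round_half_up(proportion * n)`
#' nodes: the null model the targeted deletions are contrasted against.
#'
#' @inheritParams select_targets
#' @return Character vector of node ids to remove.
#' @export
select_random <- function(net, proportion) {
  n <- n_nodes(net)
  if (n == 0) abort("Empty network.")
  if (proportion < 0 || proportion > 1) abort("`proportion` must lie in [0, 1].")
  k <- round_half_up(proportion * n)
  sample(net$roster$id, k)
}

#' Remove nodes from a network
#'
#' Returns the induced subnetwork on the remaining nodes: the removed nodes
#' and all their incident edges disappear; remaining edge weights are
#' untouched.
#'
#' @param net An [assoc_network()].
#' @param nodes Character vector of node ids to delete (must exist).
#' @return An [assoc_network()].
#' @export
apply_deletion <- function(net, nodes) {
  stopifnot(inherits(net, "assoc_network"))
  unknown <- setdiff(nodes, net$roster$id)
  if (length(unknown)) {
    abort(sprintf("Unknown node ids: %s", paste(unknown, collapse = ", ")))
  }
  if (!length(nodes)) return(net)
  assoc_network(
    filter(net$edges, !(.data$id_a %in% nodes | .data$id_b %in% nodes)),
    roster = filter(net$roster, !(.data$id %in% nodes)),
    id = net$id
  )
}

#' Run the full targeted-versus-random deletion experiment
#'
#' The poaching simulation: for each network, each deletion metric
#' (betweenness centrality or age category), each deletion type (targeted or
#' random) and each replicate, nodes are removed incrementally along the
#' deletion-proportion grid and the four global network indices are
#' recomputed after every increment.
#'
#' By default removal sequences are nested within a replicate: one shuffled
#' removal order is drawn per replicate and each proportion removes a prefix
#' of it, so trajectories along the proportion axis are internally
#' consistent. Set `nested = FALSE` to redraw the removal set independently
#' at every proportion.
#'
#' @param networks An [assoc_network()] or a list of them.
#' @param metrics Deletion metrics to run (`"betweenness"`,
#'   `"age_category"`). Random deletions are replicated per metric as
#'   matched controls.
#' @param proportions Deletion-proportion grid (default 0 to 0.20 in steps
#'   of 0.04).
#' @param replicates Number of replicates per condition (>= 1).
#' @param seed Optional integer seed for the whole experiment.
#' @param pool_fraction Fraction of nodes in the targeted pool.
#' @param nested Nested removal sequences within a replicate (default) or
#'   independent draws per proportion.
#' @return A tibble of class `"deletion_results"`, one row per (network,
#'   metric, type, proportion, replicate): `network_id`, `metric`, `type`,
#'   `proportion`, `replicate`, `n_removed`, `clustering`, `diameter`,
#'   `efficiency`, `modularity`, `n_components`, `disconnected`.
#' @examples
#' pop <- generate_population(population_config(1, 2, 1), seed = 1)
#' net <- simulate_network(pop, n_steps = 60, snapshot_at = 60, seed = 1)$network[[1]]
#' res <- run_deletion_experiment(net, replicates = 2, seed = 42)
#' @export
run_deletion_experiment <- function(networks,
                                    metrics = c("betweenness", "age_category"),
                                    proportions = seq(0, 0.2, by = 0.04),
                                    replicates = 100, seed = NULL,
                                    pool_fraction = 0.2, nested = TRUE) {
  networks <- as_network_list(networks)
  stopifnot_scalar_count(replicates, "replicates", min = 1)
  proportions <- sort(unique(proportions))
  if (any(proportions < 0) || any(proportions > pool_fraction + 1e-12)) {
    abort("`proportions` must lie in [0, pool_fraction].")
  }

  with_seed_if(seed, {
    purrr::map_dfr(networks, function(net) {
      n <- n_nodes(net)
      baseline <- network_metrics(net)
      max_k <- round_half_up(max(proportions) * n)
      pools <- lapply(stats::setNames(nm = metrics), function(m) {
        deletion_pool(net, m, pool_fraction)
      })

      grid <- tidyr::expand_grid(
        metric = metrics, type = c("targeted", "random"),
        replicate = seq_len(replicates)
      )
      purrr::pmap_dfr(grid, function(metric, type, replicate) {
        # one removal order per replicate; proportions take prefixes
        seq_ids <- if (type == "targeted") {
          sample(pools[[metric]])
        } else {
          sample(net$roster$id, max_k)
        }
        purrr::map_dfr(proportions, function(p) {
          k <- round_half_up(p * n)
          removed <- if (nested) {
            seq_ids[seq_len(k)]
          } else if (type == "targeted") {
            sample(pools[[metric]])[seq_len(k)]
          } else {
            sample(net$roster$id, k)
          }
          m <- if (k == 0) baseline else network_metrics(apply_deletion(net, removed))
          bind_cols(
            tibble(
              network_id = net$id, metric = metric, type = type,
              proportion = p, replicate = replicate, n_removed = k
            ),
            m
          )
        })
      })
    }) |>
      new_deletion_results()
  })
}

new_deletion_results <- function(x) {
  class(x) <- c("deletion_results", class(x))
  x
}

as_network_list <- function(networks) {
  if (inherits(networks, "assoc_network")) networks <- list(networks)
  if (!length(networks) || !all(purrr::map_lgl(networks, inherits, "assoc_network"))) {
    abort("`networks` must be an assoc_network or a list of them.")
  }
  ids <- purrr::map_chr(networks, "id")
  if (anyDuplicated(ids)) {
    networks <- purrr::imap(networks, function(net, i) {
      net$id <- sprintf("net%03d", i)
      net
    })
  }
  networks
}

#' Remove the weakest links of a network
#'
#' Divides every edge weight by the maximum weight and removes (without
#' replacement) all edges whose relative weight is at most
#' `threshold_pct` percent. Nodes are retained, so filtering can fragment
#' the network into components containing isolated nodes.
#'
#' @param net An [assoc_network()] with at least one edge.
#' @param threshold_pct Threshold in percent of the maximum link weight
#'   (the experiments use 1, 2 and 3).
#' @return The filtered [assoc_network()].
#' @export
filter_weak_links <- function(net, threshold_pct) {
  stopifnot(inherits(net, "assoc_network"))
  if (n_edges(net) == 0) abort("Cannot filter an edgeless network.")
  if (threshold_pct < 0 || threshold_pct >= 100) {
    abort("`threshold_pct` must be in [0, 100).")
  }
  wmax <- max(net$edges$weight)
  keep <- net$edges$weight / wmax > threshold_pct / 100
  assoc_network(net$edges[keep, ], roster = net$roster, id = net$id)
}

#' Census of filtered-out weak links by age pair and kinship tier
#'
#' Tabulates which dyads the weak-link filter removes: for each unordered
#' age-category pair and kinship tier, the count and percentage of all
#' removed links. Percentages sum to 100 over nonempty cells.
#'
#' @inheritParams filter_weak_links
#' @param pop Roster used to type the dyads; defaults to the network's own
#'   roster.
#' @return Tibble with columns `age_pair`, `tier`, `n`, `pct` (empty when
#'   nothing is filtered).
#' @export
weak_link_census <- function(net, threshold_pct, pop = NULL) {
  stopifnot(inherits(net, "assoc_network"))
  if (n_edges(net) == 0) abort("Cannot filter an edgeless network.")
  pop <- pop %||% net$roster
  if (anyNA(pop$age_category) || anyNA(pop$core_id)) {
    abort("The census needs a roster with age categories and group memberships.")
  }
  pop <- validate_population(pop)
  wmax <- max(net$edges$weight)
  dropped <- filter(net$edges, .data$weight / wmax <= threshold_pct / 100)
  if (!nrow(dropped)) {
    return(tibble(age_pair = character(), tier = character(),
                  n = integer(), pct = numeric()))
  }
  dy <- dyad_table(pop) |>
    mutate(key = pair_key(.data$id_a, .data$id_b)) |>
    select("key", "age_pair", "tier")
  dropped |>
    mutate(key = pair_key(.data$id_a, .data$id_b)) |>
    left_join(dy, by = "key") |>
    count(.data$age_pair, .data$tier) |>
    mutate(pct = 100 * .data$n / sum(.data$n)) |>
    arrange(desc(.data$n))
}

#' Weak-link filtering followed by deletion experiments
#'
#' For each filtering threshold: filters every network, flags the networks
#' that break down (two or more connected components) as a result of
#' filtering alone, excludes them, and runs the full deletion experiment on
#' the surviving filtered networks.
#'
#' @inheritParams run_deletion_experiment
#' @param thresholds Weak-link thresholds in percent (default `1:3`).
#' @return A list with elements `breakdowns` (tibble: `threshold_pct`,
#'   `network_id`, `broke_down`, `n_components`, `n_edges_removed`),
#'   `weak_links` (per-threshold census of filtered dyads) and `results`
#'   (deletion results for surviving networks, with a `threshold_pct`
#'   column).
#' @export
filtered_deletion_study <- function(networks, thresholds = 1:3,
                                    metrics = c("betweenness", "age_category"),
                                    proportions = seq(0, 0.2, by = 0.04),
                                    replicates = 100, seed = NULL, ...) {
  networks <- as_network_list(networks)
  with_seed_if(seed, {
    out <- purrr::map(sort(thresholds), function(th) {
      filtered <- purrr::map(networks, filter_weak_links, threshold_pct = th)
      census <- purrr::map2_dfr(networks, filtered, function(orig, filt) {
        tibble(
          threshold_pct = th,
          network_id = orig$id,
          n_components = component_count(filt),
          broke_down = component_count(filt) >= 2,
          n_edges_removed = n_edges(orig) - n_edges(filt)
        )
      })
      links <- purrr::map_dfr(networks, function(net) {
        # census requires a typed roster; skip attribute-free networks
        if (anyNA(net$roster$age_category) || anyNA(net$roster$core_id)) {
          return(tibble())
        }
        mutate(weak_link_census(net, th),
               threshold_pct = th, network_id = net$id)
      })
      survivors <- filtered[!census$broke_down]
      results <- if (length(survivors)) {
        mutate(
          run_deletion_experiment(survivors, metrics = metrics,
                                  proportions = proportions,
                                  replicates = replicates, ...),
          threshold_pct = th
        )
      } else {
        tibble()
      }
      list(census = census, links = links, results = results)
    })
    list(
      breakdowns = purrr::map_dfr(out, "census"),
      weak_links = purrr::map_dfr(out, "links"),
      results = new_deletion_results(purrr::map_dfr(out, "results"))
    )
  })
}
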