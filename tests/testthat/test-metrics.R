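test_that("distances are inverse-weight path sums with Inf for unreachable pairs", {
  net <- make_net("a", "b", 2)
  d <- shortest_path_lengths(net)
  expect_equal(d["a", "b"], 0.5)
  expect_equal(diag(d), c(a = 0, b = 0))

  # heavy direct edge beats a light two-hop detour
  tri <- make_net(c("a", "b", "a"), c("b", "c", "c"), c(1, 1, 10))
  d <- shortest_path_lengths(tri)
  expect_equal(d["a", "c"], 0.1)

  roster <- tibble::tibble(id = c("a", "b", "c"), age_category = NA,
                           core_id = NA, bond_id = NA, clan_id = NA)
  disc <- assoc_network(tibble::tibble(id_a = "a", id_b = "b", weight = 1),
                        roster = roster)
  expect_equal(shortest_path_lengths(disc)["a", "c"], Inf)
})

test_that("star betweenness concentrates on the hub", {
  star <- make_net(rep("hub", 4), paste0("leaf", 1:4), rep(1, 4))
  b <- node_betweenness(star)
  expect_equal(b$betweenness[b$id == "hub"], 6) # (n-1)(n-2)/2 with n = 5
  expect_true(all(b$betweenness[b$id != "hub"] == 0))
})

test_that("complete equal-weight graphs have zero betweenness everywhere", {
  ids <- utils::combn(letters[1:6], 2)
  net <- make_net(ids[1, ], ids[2, ], rep(2, ncol(ids)))
  expect_true(all(node_betweenness(net)$betweenness == 0))
})

test_that("weighted betweenness matches exhaustive geodesic enumeration", {
  withr::with_seed(31, {
    for (rep in 1:8) {
      net <- random_test_network(sample(5:8, 1), p = 0.4)
      got <- node_betweenness(net)
      want <- oracle_betweenness(net$edges, net$roster$id)
      expect_equal(stats::setNames(got$betweenness, got$id)[names(want)],
                   want, tolerance = 1e-9)
    }
  })
})

test_that("clustering coefficient equals the triplet census", {
  tri <- make_net(c("a", "b", "a"), c("b", "c", "c"), c(1, 1, 1))
  expect_equal(clustering_coefficient(tri), 1)
  path <- make_net(c("a", "b"), c("b", "c"), c(1, 1))
  expect_equal(clustering_coefficient(path), 0)
  withr::with_seed(32, {
    for (rep in 1:6) {
      net <- random_test_network(10, p = 0.35)
      expect_equal(clustering_coefficient(net),
                   oracle_transitivity(net$edges, net$roster$id),
                   tolerance = 1e-9)
    }
  })
})

test_that("weighted diameter takes the longest geodesic and flags fragmentation", {
  chain <- make_net(c("a", "b", "c"), c("b", "c", "d"), rep(1, 3))
  expect_equal(as.numeric(weighted_diameter(chain)), 3)
  single <- make_net("a", "b", 4)
  expect_equal(as.numeric(weighted_diameter(single)), 0.25)

  two_comp <- make_net(c("a", "c"), c("b", "d"), c(1, 2))
  d <- weighted_diameter(two_comp)
  expect_true(attr(d, "disconnected"))
  expect_equal(as.numeric(d), 1) # max over reachable pairs
  expect_error(weighted_diameter(assoc_network(
    tibble::tibble(id_a = character(), id_b = character(), weight = numeric()),
    roster = tibble::tibble(id = "a", age_category = NA, core_id = NA,
                            bond_id = NA, clan_id = NA)
  )), "edgeless")
})

test_that("global efficiency has the complete-graph closed form and edgeless limit", {
  ids <- utils::combn(letters[1:5], 2)
  for (w in c(0.5, 2)) {
    net <- make_net(ids[1, ], ids[2, ], rep(w, ncol(ids)))
    expect_equal(global_efficiency(net), w, tolerance = 1e-12)
  }
  roster <- tibble::tibble(id = c("a", "b", "c"), age_category = NA,
                           core_id = NA, bond_id = NA, clan_id = NA)
  empty <- assoc_network(
    tibble::tibble(id_a = character(), id_b = character(), weight = numeric()),
    roster = roster
  )
  expect_equal(network_metrics(empty)$efficiency, 0)
})

test_that("distances, efficiency and clustering match oracles on random graphs", {
  withr::with_seed(33, {
    for (rep in 1:12) {
      net <- random_test_network(sample(6:12, 1), p = 0.35)
      nodes <- net$roster$id
      expect_equal(shortest_path_lengths(net)[nodes, nodes],
                   oracle_distances(net$edges, nodes), tolerance = 1e-9)
      expect_equal(global_efficiency(net),
                   oracle_efficiency(net$edges, nodes), tolerance = 1e-9)
      expect_equal(clustering_coefficient(net),
                   oracle_transitivity(net$edges, nodes), tolerance = 1e-9)
      expect_equal(as.numeric(weighted_diameter(net)),
                   oracle_diameter(net$edges, nodes), tolerance = 1e-9)
    }
  })
})

test_that("two disjoint unit triangles give modularity Q = 0.5", {
  net <- make_net(c("a", "b", "a", "x", "y", "x"),
                  c("b", "c", "c", "y", "z", "z"), rep(1, 6))
  m <- weighted_modularity(net)
  expect_equal(m$q, 0.5, tolerance = 1e-12)
  memb <- m$membership
  expect_equal(length(unique(memb[c("a", "b", "c")])), 1L)
  expect_equal(length(unique(memb[c("x", "y", "z")])), 1L)
  expect_false(memb[["a"]] == memb[["x"]])
})

test_that("a single clique has no community structure (Q near zero or below)", {
  ids <- utils::combn(letters[1:6], 2)
  net <- make_net(ids[1, ], ids[2, ], rep(1, ncol(ids)))
  expect_lte(weighted_modularity(net)$q, 1e-9)
})

test_that("leading-eigenvector recovers a planted two-block partition", {
  withr::with_seed(34, {
    blocks <- list(paste0("a", 1:6), paste0("b", 1:6))
    within <- do.call(rbind, lapply(blocks, function(bl) {
      idx <- utils::combn(6, 2)
      cbind(bl[idx[1, ]], bl[idx[2, ]])
    }))
    across <- cbind(blocks[[1]][1:3], blocks[[2]][1:3])
    edges <- tibble::tibble(
      id_a = c(within[, 1], across[, 1]),
      id_b = c(within[, 2], across[, 2]),
      weight = c(stats::runif(nrow(within), 5, 6), stats::runif(3, 0.1, 0.2))
    )
    net <- assoc_network(edges)
    m <- weighted_modularity(net)
    truth <- stats::setNames(rep(1:2, each = 6), unlist(blocks))
    # same partition up to label switching
    expect_equal(length(unique(m$membership[names(truth)[truth == 1]])), 1L)
    expect_equal(length(unique(m$membership[names(truth)[truth == 2]])), 1L)
    # and its Q matches the exhaustive best bipartition
    best <- oracle_best_bipartition(edges, net$roster$id)
    expect_equal(m$q, best$q, tolerance = 1e-9)
  })
})

test_that("component counting treats isolated nodes as components", {
  net <- make_net(c("a", "c"), c("b", "d"), c(1, 1))
  expect_equal(component_count(net), 2L)
  roster <- tibble::tibble(id = c("a", "b", "z"), age_category = NA,
                           core_id = NA, bond_id = NA, clan_id = NA)
  with_iso <- assoc_network(tibble::tibble(id_a = "a", id_b = "b", weight = 1),
                            roster = roster)
  expect_equal(component_count(with_iso), 2L)
  # cutting a bridge raises the count by one
  bridge <- make_net(c("a", "b", "c", "d"), c("b", "c", "d", "e"), rep(1, 4))
  cut <- assoc_network(bridge$edges[-2, ], roster = bridge$roster)
  expect_equal(component_count(cut), component_count(bridge) + 1L)
})

test_that("uniform weight rescaling acts as expected on every index", {
  withr::with_seed(35, {
    net <- random_test_network(9, p = 0.45)
  })
  scaled <- assoc_network(dplyr::mutate(net$edges, weight = weight * 3.7),
                          roster = net$roster)
  expect_equal(clustering_coefficient(scaled), clustering_coefficient(net))
  b1 <- node_betweenness(net)
  b2 <- node_betweenness(scaled)
  expect_equal(order(-b1$betweenness), order(-b2$betweenness))
  expect_equal(shortest_path_lengths(scaled),
               shortest_path_lengths(net) / 3.7, tolerance = 1e-12)
  expect_equal(global_efficiency(scaled), global_efficiency(net) * 3.7,
               tolerance = 1e-12)
  m1 <- weighted_modularity(net)
  m2 <- weighted_modularity(scaled)
  expect_equal(m1$q, m2$q, tolerance = 1e-9)
})

test_that("efficiency is monotone nonincreasing under edge removal", {
  withr::with_seed(36, {
    net <- random_test_network(10, p = 0.5)
    e0 <- global_efficiency(net)
    for (k in sample(nrow(net$edges), 5)) {
      sub <- assoc_network(net$edges[-k, ], roster = net$roster)
      expect_lte(global_efficiency(sub), e0 + 1e-12)
    }
  })
})
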