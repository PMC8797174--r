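test_that("proportion zero selects nobody and leaves metrics at baseline", {
  net <- sim_fixture()
  withr::with_seed(1, {
    expect_length(select_targets(net, "betweenness", 0), 0)
    expect_length(select_random(net, 0), 0)
  })
  res <- run_deletion_experiment(net, proportions = c(0, 0.08),
                                 replicates = 3, seed = 2)
  base <- network_metrics(net)
  zero <- dplyr::filter(res, proportion == 0)
  expect_true(all(zero$clustering == base$clustering))
  expect_true(all(zero$efficiency == base$efficiency))
  expect_true(all(zero$n_removed == 0))
})

test_that("betweenness targeting finds the hub of a star", {
  star <- make_net(rep("hub", 4), paste0("leaf", 1:4), rep(1, 4))
  withr::with_seed(3, {
    # n = 5: the pool is round_half_up(0.2 * 5) = 1 node, the unique maximum
    picked <- select_targets(star, "betweenness", proportion = 0.2)
  })
  expect_equal(picked, "hub")
})

test_that("age targeting fills the pool matriarchs-first", {
  net <- sim_fixture(seed = 60, cfg = population_config(1, 2, 2))
  k_mat <- sum(net$roster$age_category == "matriarch")
  withr::with_seed(4, {
    pool <- deletion_pool(net, "age_category", pool_fraction = 0.2)
  })
  # matriarchs enter the pool before any lower category
  pool_ages <- net$roster$age_category[match(pool, net$roster$id)]
  expect_equal(sum(pool_ages == "matriarch"), min(k_mat, length(pool)))
  expect_true(all(diff(age_rank(pool_ages)) <= 0)) # descending age rank
})

test_that("random selection draws the rounded count without replacement", {
  amb <- amboseli_population(seed = 1)
  cnt <- generate_sightings(amb, n_events = 60, seed = 2)
  net <- assemble_network(cnt, amb)
  withr::with_seed(5, s1 <- select_random(net, 0.2))
  withr::with_seed(6, s2 <- select_random(net, 0.2))
  expect_length(s1, 17) # round-half-up of 0.2 * 83
  expect_equal(anyDuplicated(s1), 0L)
  expect_false(identical(sort(s1), sort(s2)))
  # the full grid on n = 83: 3, 7, 10, 13, 17 removals
  withr::with_seed(7, {
    ks <- vapply(c(0.04, 0.08, 0.12, 0.16, 0.2),
                 function(p) length(select_random(net, p)), numeric(1))
  })
  expect_equal(ks, c(3, 7, 10, 13, 17))
})

test_that("apply_deletion removes nodes and their incident edges only", {
  net <- sim_fixture()
  expect_identical(apply_deletion(net, character(0))$edges, net$edges)
  two <- net$roster$id[1:2]
  keep_all_but_two <- setdiff(net$roster$id, two)
  stripped <- apply_deletion(net, keep_all_but_two)
  expect_lte(nrow(stripped$edges), 1)
  expect_setequal(stripped$roster$id, two)
  expect_error(apply_deletion(net, "nobody"), "Unknown node")
  # cutting a cut vertex raises the component count
  bridge <- make_net(c("a", "b", "b", "c"), c("b", "x", "c", "y"), rep(1, 4))
  expect_gt(component_count(apply_deletion(bridge, "b")),
            component_count(bridge))
})

test_that("the experiment emits the full factorial of conditions", {
  net <- sim_fixture()
  res <- run_deletion_experiment(net, replicates = 4, seed = 8)
  expect_s3_class(res, "deletion_results")
  expect_equal(nrow(res), 2 * 2 * 6 * 4) # metrics x types x proportions x reps
  expect_equal(sort(unique(res$proportion)), seq(0, 0.2, by = 0.04))
  counts <- dplyr::count(res, metric, type, proportion)
  expect_true(all(counts$n == 4))
  expect_true(all(res$n_removed == floor(res$proportion * n_nodes(net) + 0.5)))
})

test_that("experiments are reproducible and pools are static across replicates", {
  net <- sim_fixture()
  a <- run_deletion_experiment(net, replicates = 3, seed = 9)
  b <- run_deletion_experiment(net, replicates = 3, seed = 9)
  expect_identical(as.data.frame(a), as.data.frame(b))
  withr::with_seed(10, pool1 <- deletion_pool(net, "betweenness"))
  withr::with_seed(11, pool2 <- deletion_pool(net, "betweenness"))
  # betweenness has no exact ties here, so the pool is rng-independent
  expect_setequal(pool1, pool2)
})

test_that("targeted betweenness deletion hurts efficiency more than random on a hub network", {
  # hub-and-clusters: three cliques joined only through one broker each
  cliques <- lapply(1:3, function(k) {
    ids <- paste0("c", k, "_", 1:5)
    idx <- utils::combn(5, 2)
    tibble::tibble(id_a = ids[idx[1, ]], id_b = ids[idx[2, ]], weight = 5)
  })
  spokes <- tibble::tibble(
    id_a = c("c1_1", "c2_1", "c3_1"),
    id_b = c("c2_1", "c3_1", "c1_1"),
    weight = 1
  )
  net <- assoc_network(dplyr::bind_rows(cliques, spokes), id = "hub")
  res <- run_deletion_experiment(net, metrics = "betweenness",
                                 proportions = c(0, 0.2),
                                 replicates = 30, seed = 12)
  at_max <- dplyr::filter(res, proportion == 0.2)
  mean_t <- mean(at_max$efficiency[at_max$type == "targeted"])
  mean_r <- mean(at_max$efficiency[at_max$type == "random"])
  expect_lt(mean_t, mean_r)
})

test_that("weak-link filtering removes by relative weight, idempotently", {
  equal <- make_net(c("a", "b", "c"), c("b", "c", "a"), rep(2, 3))
  expect_equal(n_edges(filter_weak_links(equal, 3)), 3L)

  mixed <- make_net(c("a", "b", "c"), c("b", "c", "d"), c(100, 2, 1))
  f2 <- filter_weak_links(mixed, 2)
  expect_equal(sort(f2$edges$weight), 100) # 2/100 and 1/100 both <= 2%
  expect_equal(n_nodes(f2), 4L) # nodes retained
  expect_identical(filter_weak_links(f2, 2)$edges, f2$edges)
  expect_identical(filter_weak_links(mixed, 0)$edges, mixed$edges)
  expect_error(filter_weak_links(assoc_network(
    tibble::tibble(id_a = character(), id_b = character(), weight = numeric()),
    roster = tibble::tibble(id = "a", age_category = NA, core_id = NA,
                            bond_id = NA, clan_id = NA)
  ), 1), "edgeless")
})

test_that("the weak-link census partitions the filtered edges by age pair and tier", {
  pop <- generate_population(population_config(2, 1, 1), seed = 70)
  net <- simulate_network(pop, n_steps = 300, snapshot_at = 300,
                          seed = 71)$network[[1]]
  for (th in 1:3) {
    census <- weak_link_census(net, th)
    wmax <- max(net$edges$weight)
    n_dropped <- sum(net$edges$weight / wmax <= th / 100)
    expect_equal(sum(census$n), n_dropped)
    if (n_dropped > 0) expect_equal(sum(census$pct), 100)
  }
  # all-weak cross-clan links in a constructed fixture land in nonkin cells
  roster <- tibble::tibble(
    id = c("a1", "a2", "b1", "b2"),
    age_category = c("matriarch", "young_adult", "matriarch", "young_adult"),
    core_id = c("A", "A", "B", "B"),
    bond_id = c("BA", "BA", "BB", "BB"),
    clan_id = c("K1", "K1", "K2", "K2")
  )
  net2 <- assoc_network(tibble::tibble(
    id_a = c("a1", "b1", "a1", "a2"),
    id_b = c("a2", "b2", "b1", "b2"),
    weight = c(100, 100, 0.5, 0.5)
  ), roster = roster)
  census2 <- weak_link_census(net2, 1)
  expect_true(all(census2$tier == "nonkin"))
  expect_equal(sum(census2$pct), 100)
})

test_that("filtered study flags weak-bridge breakdowns and partitions the input", {
  # two strong cliques joined by one bridge at 0.9% of the max weight
  make_two_clique <- function(bridge_w, id) {
    ids1 <- paste0("p", 1:4)
    ids2 <- paste0("q", 1:4)
    idx <- utils::combn(4, 2)
    assoc_network(tibble::tibble(
      id_a = c(ids1[idx[1, ]], ids2[idx[1, ]], "p1"),
      id_b = c(ids1[idx[2, ]], ids2[idx[2, ]], "q1"),
      weight = c(rep(100, 2 * ncol(idx)), bridge_w)
    ), id = id)
  }
  fragile <- make_two_clique(0.9, "fragile") # bridge at 0.9% of max
  robust <- make_two_clique(50, "robust")
  study <- filtered_deletion_study(list(fragile, robust), thresholds = 1,
                                   metrics = "betweenness",
                                   proportions = c(0, 0.2),
                                   replicates = 2, seed = 13)
  brk <- study$breakdowns
  expect_equal(nrow(brk), 2L)
  expect_true(brk$broke_down[brk$network_id == "fragile"])
  expect_false(brk$broke_down[brk$network_id == "robust"])
  # survivors + broken partition the input per threshold
  expect_equal(sum(brk$broke_down) + sum(!brk$broke_down), 2L)
  expect_setequal(unique(study$results$network_id), "robust")
  expect_true(all(study$results$threshold_pct == 1))
})
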