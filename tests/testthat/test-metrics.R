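test_that("global efficiency follows inverse shortest-path costs", {
  two <- collinear_net(c(0, 1), data.frame(from = "a", to = "b", weight = 1),
                       ids = c("a", "b"))
  expect_equal(global_efficiency(two)$global, 1)

  # weighted path a-b-c with unit weights: d(a,c) = 2
  path3 <- collinear_net(c(0, 1, 2),
                         data.frame(from = c("a", "b"), to = c("b", "c"),
                                    weight = 1))
  expect_equal(global_efficiency(path3)$global, 5 / 6)

  # disconnected pairs contribute zero
  comp2 <- spatial_network(
    data.frame(id = letters[1:4], x = c(0, 1, 10, 11), y = 0, z = 0),
    data.frame(from = c("a", "c"), to = c("b", "d"), weight = 1)
  )
  e <- global_efficiency(comp2)
  expect_equal(e$global, 1 / 3)  # each node reaches 1 of its 3 peers
})

test_that("Onnela clustering handles the canonical toy cases", {
  tri <- complete_net(3, weight = 2)  # all weights at the maximum
  expect_equal(unname(weighted_clustering(tri)$per_node), rep(1, 3))

  star <- collinear_net(c(0, 1, 2, 3),
                        data.frame(from = "a", to = c("b", "c", "d"),
                                   weight = 1))
  expect_equal(weighted_clustering(star)$global, 0)

  # triangle with weights (1, 1, 0.125): the node joining the two
  # unit-weight edges has C = (1 * 1 * 0.125)^(1/3) = 0.5
  tri2 <- spatial_network(
    data.frame(id = c("a", "b", "c"), x = c(0, 1, 0), y = c(0, 0, 1), z = 0),
    data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
               weight = c(1, 1, 0.125))
  )
  expect_equal(unname(weighted_clustering(tri2)$per_node["a"]), 0.5)
})

test_that("efficiency and clustering match brute-force oracles", {
  for (seed in 1:4) {
    net <- random_net(25, p = 0.25, seed = seed)
    expect_equal(global_efficiency(net)$global, oracle_efficiency(net),
                 tolerance = 1e-9)
    expect_equal(weighted_clustering(net)$global,
                 oracle_clustering(net)$global, tolerance = 1e-9)
  }
})

test_that("small-world index is the product of the two ratios", {
  expect_equal(small_world_index(0.3, 0.2, 0.3, 0.2), 1)
  expect_equal(small_world_index(0.6, 0.2, 0.3, 0.2), 2)
  expect_error(small_world_index(1, 1, 0, 1), "positive")
})

test_that("hierarchy curve separates hubs from clustered periphery", {
  flat <- complete_net(5)
  hc <- hierarchy_curve(flat, bin_width = 2)
  expect_equal(hc$curve$mean_clustering_norm, 1)

  toy <- hub_and_cliques_net(3)
  hc2 <- hierarchy_curve(toy, bin_width = 2)
  hub_bin <- hc2$curve[hc2$curve$bin_hi > 9, ]
  low_bin <- hc2$curve[hc2$curve$bin_lo <= 3 & hc2$curve$bin_hi > 3, ]
  expect_lt(hub_bin$mean_clustering_norm, 1)
  expect_gt(low_bin$mean_clustering_norm, 1)
  expect_lt(hc2$spearman_rho, 0)

  # bin values average back to the global mean (weighting by bin size)
  wm <- with(hc2$curve, sum(mean_clustering_norm * n_nodes) / sum(n_nodes))
  expect_equal(wm, 1, tolerance = 1e-9)
})

test_that("degree assortativity matches its oracle and edge cases", {
  star4 <- collinear_net(c(0, 1, 2, 3, 4),
                         data.frame(from = "a", to = c("b", "c", "d", "e"),
                                    weight = 1),
                         ids = letters[1:5])
  expect_equal(degree_assortativity(star4), -1)

  two_edges <- collinear_net(c(0, 1, 2, 3),
                             data.frame(from = c("a", "c"), to = c("b", "d"),
                                        weight = 1))
  expect_warning(r <- degree_assortativity(two_edges), "undefined")
  expect_true(is.na(r))

  for (seed in 1:4) {
    net <- random_net(8, p = 0.5, seed = seed)
    expect_equal(degree_assortativity(net), oracle_assortativity(net),
                 tolerance = 1e-12)
    # independent library cross-check
    expect_equal(degree_assortativity(net),
                 igraph::assortativity_degree(as_igraph(net)),
                 tolerance = 1e-9)
  }
})

test_that("core peeling finds the innermost k-core and s-core", {
  tri <- complete_net(3)
  kc <- core_decomposition(tri, "k_core")
  expect_equal(kc$core$threshold, 2)
  expect_setequal(kc$core$members, c("a", "b", "c"))

  star <- collinear_net(c(0, 1, 2, 3),
                        data.frame(from = "a", to = c("b", "c", "d"),
                                   weight = 1))
  ks <- core_decomposition(star, "k_core")
  expect_equal(ks$core$threshold, 1)

  # on binary weights the s-core peeling reduces to the k-core
  net <- random_net(20, p = 0.3, seed = 2, weights = FALSE)
  expect_equal(core_decomposition(net, "s_core")$core$members,
               core_decomposition(net, "k_core")$core$members)

  # profile sizes shrink as the threshold grows
  wnet <- random_net(25, p = 0.3, seed = 5)
  prof <- core_decomposition(wnet, "s_core")$profile
  expect_true(all(diff(prof$size) <= 0))
  expect_true(all(diff(prof$threshold) >= 0))

  # innermost core members survive peeling at their threshold (oracle)
  sc <- core_decomposition(wnet, "s_core")$core
  expect_setequal(sc$members, oracle_core_at(wnet, sc$threshold, TRUE))
  # and a slightly higher threshold destroys the core
  expect_length(oracle_core_at(wnet, sc$threshold + 1e-6, TRUE), 0)

  kcc <- core_decomposition(wnet, "k_core")$core
  expect_equal(sort(match(kcc$members, wnet$nodes$id)),
               unname(which(igraph::coreness(as_igraph(wnet)) ==
                              max(igraph::coreness(as_igraph(wnet))))))
})

test_that("weighted rich-club reduces to k-density on binary networks", {
  net <- random_net(20, p = 0.4, seed = 6, weights = FALSE)
  rc <- weighted_rich_club(net)
  k <- node_degrees(net)
  ei <- cbind(match(net$edges$from, net$nodes$id),
              match(net$edges$to, net$nodes$id))
  for (row in which(rc$profile$valid)) {
    kk <- rc$profile$k[row]
    club <- k > kk
    classical <- sum(club[ei[, 1]] & club[ei[, 2]]) /
      (sum(club) * (sum(club) - 1) / 2)
    expect_equal(rc$profile$phi_w[row], classical, tolerance = 1e-12)
  }
})

test_that("weighted rich-club matches direct summation and its bounds", {
  for (seed in 1:4) {
    net <- random_net(18, p = 0.4, seed = seed)
    rc <- weighted_rich_club(net)
    valid <- rc$profile[rc$profile$valid, ]
    expect_true(all(valid$phi_w >= 0 & valid$phi_w <= 1))
    for (row in seq_len(nrow(valid))) {
      expect_equal(valid$phi_w[row], oracle_rich_club_k(net, valid$k[row]),
                   tolerance = 1e-12)
    }
  }

  # fully interconnected club carrying exactly the strongest weights
  nodes <- data.frame(id = letters[1:6], x = seq(0, 5), y = 0, z = 0)
  rich <- utils::combn(3, 2)  # triangle among a,b,c with the top weights
  edges <- rbind(
    data.frame(from = letters[rich[1, ]], to = letters[rich[2, ]], weight = 9),
    data.frame(from = c("a", "b", "c"), to = c("d", "e", "f"), weight = 1)
  )
  net2 <- spatial_network(nodes, edges)
  rc2 <- weighted_rich_club(net2)
  top <- rc2$profile[rc2$profile$club_size == 3 & rc2$profile$valid, ]
  expect_equal(top$phi_w[1], 1)
})

test_that("largest assessable club size solves x(x-1)/2 <= E", {
  expect_equal(max_assessable_club(1), 2)
  expect_equal(max_assessable_club(3), 3)
  expect_equal(max_assessable_club(17865), 189)
  for (E in c(2, 5, 10, 100, 5000)) {
    x <- max_assessable_club(E)
    expect_lte(x * (x - 1) / 2, E)
    expect_gt((x + 1) * x / 2, E)
  }
})

test_that("wiring statistics summarise lengths and hemispheres", {
  sq <- spatial_network(
    data.frame(id = letters[1:4], x = c(0, 1, 1, 0), y = c(0, 0, 1, 1), z = 0,
               hemisphere = c("left", "right", "right", "left")),
    data.frame(from = c("a", "b", "c", "d"), to = c("b", "c", "d", "a"),
               weight = 1)
  )
  ws <- wiring_statistics(sq)
  expect_equal(ws$summary$mean_length, 1)
  expect_equal(ws$summary$sd_length, 0)
  expect_equal(ws$summary$interhemispheric_fraction, 0.5)
  expect_equal(ws$summary$mean_interhemispheric_length, 1)

  self <- wiring_statistics(sq, reference = sq)
  expect_equal(self$summary$mean_pct_change, 0)
  expect_gt(self$summary$ranksum_p, 0.8)
})

test_that("core overlap reports intersections and internal statistics", {
  net <- random_net(6, p = 0.6, seed = 3)
  a <- core_structure(net, net$nodes$id[1:3], kind = "rich_club")
  b <- core_structure(net, net$nodes$id[1:3], kind = "s_core")
  expect_equal(core_overlap(a, b, net)$overlap, 1)

  c2 <- core_structure(net, net$nodes$id[4:6])
  expect_equal(core_overlap(a, c2, net)$overlap, 0)

  # hand enumeration on a fixed toy
  toy <- spatial_network(
    data.frame(id = letters[1:6], x = 1:6, y = 0, z = 0),
    data.frame(from = c("a", "a", "b", "c", "d"),
               to = c("b", "c", "c", "d", "e"), weight = 1)
  )
  core_abc <- core_structure(toy, c("a", "b", "c"))
  expect_equal(core_abc$internal_edges, 3)
  expect_equal(core_abc$internal_density, 1)
  expect_equal(core_abc$external_reach, 1)  # only d touches the core
  core_cde <- core_structure(toy, c("c", "d", "e"))
  ov <- core_overlap(core_abc, core_cde, toy)
  expect_equal(ov$overlap, 1 / 3)
  expect_equal(ov$internal_edges_b, 2)
})
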