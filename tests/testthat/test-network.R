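test_that("constructor validates the simple-graph invariants", {
  nodes <- data.frame(id = c("a", "b", "c"), x = c(0, 1, 2), y = 0, z = 0)
  net <- spatial_network(nodes, data.frame(from = c("a", "b"),
                                           to = c("b", "c"), weight = 1))
  expect_s3_class(net, "spatial_network")
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 2)

  expect_error(spatial_network(nodes, data.frame(from = "a", to = "a",
                                                 weight = 1)),
               "self-loop")
  expect_error(spatial_network(nodes, data.frame(from = "a", to = "z",
                                                 weight = 1)),
               "unknown endpoint")
  expect_error(spatial_network(nodes, data.frame(from = "a", to = "b",
                                                 weight = -1)),
               "> 0")
  expect_error(spatial_network(nodes, data.frame(from = c("a", "b"),
                                                 to = c("b", "a"),
                                                 weight = c(1, 2))),
               "conflicting")

  # symmetric duplicate rows with agreeing weights collapse to one edge
  net2 <- spatial_network(nodes, data.frame(from = c("a", "b"),
                                            to = c("b", "a"),
                                            weight = c(2, 2)))
  expect_equal(nrow(net2$edges), 1)
  expect_equal(net2$edges$weight, 2)
})

test_that("network round-trips through TSV files exactly", {
  net <- random_net(12, p = 0.4, seed = 7)
  np <- withr::local_tempfile(fileext = ".tsv")
  ep <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, np, ep)
  back <- read_network(np, ep)
  expect_equal(back$nodes$id, net$nodes$id)
  expect_equal(node_coords(back), node_coords(net), tolerance = 1e-12)
  expect_equal(back$edges, net$edges, tolerance = 1e-12)
})

test_that("matrix reader builds the same network as the edge-list reader", {
  nodes <- data.frame(id = c("a", "b"), x = c(0, 1), y = 0, z = 0)
  m <- matrix(c(0, 1, 1, 0), 2)
  net <- matrix_network(m, nodes)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 1)

  expect_error(matrix_network(matrix(c(0, 1, 2, 0), 2), nodes), "asymmetric")
  expect_error(matrix_network(matrix(0, 2, 3), nodes), "square")
  expect_error(matrix_network(matrix(c(1, 0, 0, 0), 2), nodes), "diagonal")

  expect_warning(z <- matrix_network(matrix(0, 2, 2), nodes), "no nonzero")
  expect_equal(nrow(z$edges), 0)

  # equivalence with read_network on the same connectivity
  net2 <- random_net(8, p = 0.5, seed = 3)
  m2 <- adjacency_matrix(net2)
  mp <- withr::local_tempfile(fileext = ".tsv")
  np <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(m2, mp, sep = "\t", row.names = FALSE, col.names = FALSE)
  readr::write_tsv(net2$nodes, np)
  back <- read_matrix(mp, np)
  expect_equal(back$edges, net2$edges, tolerance = 1e-9)
})

test_that("group aggregation sums crossing weights and conserves mass", {
  nodes <- data.frame(id = c("a", "b", "c", "d"),
                      x = c(0, 1, 10, 11), y = 0, z = 0)
  edges <- data.frame(from = c("a", "a", "c"), to = c("b", "c", "d"),
                      weight = c(5, 3, 2))
  net <- spatial_network(nodes, edges)
  grouping <- data.frame(id = c("a", "b", "c", "d"),
                         group = c("g1", "g1", "g2", "g2"))
  agg <- aggregate_to_groups(net, grouping)
  expect_equal(nrow(agg$nodes), 2)
  expect_equal(nrow(agg$edges), 1)
  expect_equal(agg$edges$weight, 3)  # only the single crossing edge
  expect_equal(sort(agg$nodes$x), c(0.5, 10.5))  # centroids

  # all nodes in one group: single node, no edges
  one <- aggregate_to_groups(net, data.frame(id = nodes$id, group = "all"))
  expect_equal(nrow(one$nodes), 1)
  expect_equal(nrow(one$edges), 0)

  expect_error(aggregate_to_groups(net, grouping[-1, ]), "missing")

  # weight conservation on a random network with random groups
  net2 <- random_net(40, p = 0.2, seed = 11)
  set.seed(2)
  grp <- data.frame(id = net2$nodes$id,
                    group = sample(paste0("g", 1:6), 40, replace = TRUE))
  agg2 <- aggregate_to_groups(net2, grp)
  g <- grp$group[match(net2$edges$from, grp$id)]
  h <- grp$group[match(net2$edges$to, grp$id)]
  intra <- sum(net2$edges$weight[g == h])
  expect_equal(sum(agg2$edges$weight) + intra, sum(net2$edges$weight),
               tolerance = 1e-9)
  # aggregated edge count equals group pairs with >= 1 crossing edge
  expect_equal(nrow(agg2$edges),
               nrow(unique(data.frame(pmin(g, h), pmax(g, h))[g != h, ])))
})

test_that("aggregation raises density on distance-decay networks", {
  net <- generate_network(synth_spec(200, 1200, decay_scale = 10, seed = 5))
  set.seed(5)
  grp <- data.frame(id = net$nodes$id,
                    group = sample(paste0("g", 1:12), 200, replace = TRUE))
  agg <- aggregate_to_groups(net, grp)
  expect_gte(connection_density(agg), connection_density(net))
})

test_that("induced subnetworks keep only internal edges and metadata", {
  net <- random_net(15, p = 0.4, seed = 2)
  all_ids <- net$nodes$id
  same <- extract_subnetwork(net, all_ids)
  expect_equal(same$edges, net$edges)

  tri <- complete_net(3)
  two <- extract_subnetwork(tri, c("a", "b"))
  expect_equal(nrow(two$nodes), 2)
  expect_equal(nrow(two$edges), 1)

  expect_error(extract_subnetwork(net, "nope"), "unknown")

  # hemisphere split leaves no inter-hemispheric edges
  net$nodes$hemisphere <- ifelse(net$nodes$x < 5, "left", "right")
  left <- extract_subnetwork(net, net$nodes$id[net$nodes$hemisphere == "left"])
  expect_true(all(left$nodes$hemisphere == "left"))
  hem <- stats::setNames(net$nodes$hemisphere, net$nodes$id)
  expect_true(all(hem[left$edges$from] == hem[left$edges$to]))
})

test_that("connection density matches E / (n (n - 1) / 2)", {
  expect_equal(connection_density(complete_net(5)), 1)
  net <- random_net(20, p = 0.3, seed = 9)
  expect_equal(connection_density(net),
               nrow(net$edges) / (20 * 19 / 2))
  one <- spatial_network(data.frame(id = "a", x = 0, y = 0, z = 0),
                         data.frame(from = character(), to = character(),
                                    weight = double()))
  expect_error(connection_density(one), "two nodes")
})

test_that("edge lengths are Euclidean distances recomputed from coordinates", {
  net <- collinear_net(c(0, 3, 7), data.frame(from = c("a", "b"),
                                              to = c("b", "c"), weight = 1))
  expect_equal(edge_lengths(net), c(3, 4))
  expect_equal(unname(node_total_lengths(net)), c(3, 7, 4))
  expect_equal(total_wiring_length(net), 7)
})
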