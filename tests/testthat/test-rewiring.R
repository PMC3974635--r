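test_that("swap-count bookkeeping floors F * E / 2", {
  expect_equal(required_swaps(17865, 20), 178650)
  expect_equal(required_swaps(17865, 1), 8932)
  expect_equal(required_swaps(2, 1), 1)
  expect_error(required_swaps(1, 1), "two edges")
})

test_that("proposals respect the self-connection and parallel-link bans", {
  # 4-cycle a-b-c-d: swapping (a,b),(c,d) -> (a,c),(b,d) valid iff absent
  cyc <- spatial_network(
    data.frame(id = letters[1:4], x = c(0, 1, 1, 0), y = c(0, 0, 1, 1), z = 0),
    data.frame(from = c("a", "b", "c", "a"), to = c("b", "c", "d", "d"),
               weight = 1:4)
  )
  e_ab <- which(cyc$edges$from == "a" & cyc$edges$to == "b")
  e_cd <- which(cyc$edges$from == "c" & cyc$edges$to == "d")
  cand <- wirecost:::swap_candidate(cyc, e_ab, e_cd)
  expect_true(cand$valid)  # neither a-c nor b-d exists
  expect_equal(cand$added$from, c("a", "b"))
  expect_equal(cand$added$to, c("c", "d"))
  # replacement edges carry the removed edges' weights
  expect_equal(cand$added$weight, cyc$edges$weight[c(e_ab, e_cd)])

  # edges sharing a node can never be swapped
  e_bc <- which(cyc$edges$from == "b" & cyc$edges$to == "c")
  shared <- wirecost:::swap_candidate(cyc, e_ab, e_bc)
  expect_false(shared$valid)

  # complete graph: every replacement already exists, all proposals invalid
  k4 <- complete_net(4)
  for (e1 in 1:5) for (e2 in (e1 + 1):6) {
    expect_false(wirecost:::swap_candidate(k4, e1, e2)$valid)
    expect_false(wirecost:::swap_candidate(k4, e2, e1)$valid)
  }
})

test_that("acceptance rules encode the three wiring constraints", {
  cfg_rnd <- rewiring_config("random")
  cfg_sp <- rewiring_config("spatial")
  cfg_red <- rewiring_config("reduced")

  # collinear 0,1,2,3 with edges (a,b),(c,d): swap lengthens both new edges
  net1 <- collinear_net(0:3, data.frame(from = c("a", "c"), to = c("b", "d"),
                                        weight = 1))
  cand1 <- wirecost:::swap_candidate(net1, 1, 2)
  expect_true(cand1$valid)
  expect_true(accept_swap(net1, net1, cand1, cfg_rnd))
  expect_false(accept_swap(net1, net1, cand1, cfg_sp))
  expect_false(accept_swap(net1, net1, cand1, cfg_red))

  # points 0,1,10,11 with edges (a,c),(b,d) -> (a,b),(c,d): 10+10 -> 1+1,
  # every touched region's total strictly decreases
  net2 <- collinear_net(c(0, 1, 10, 11),
                        data.frame(from = c("a", "b"), to = c("c", "d"),
                                   weight = 1))
  cand2 <- wirecost:::swap_candidate(net2, 1, 2)
  expect_true(cand2$valid)
  expect_true(accept_swap(net2, net2, cand2, cfg_red))
  expect_true(accept_swap(net2, net2, cand2,
                          rewiring_config("reduced",
                                          reduced_mode = "total_length")))
  expect_true(accept_swap(net2, net2, cand2, cfg_sp))
})

test_that("ensembles preserve degrees, weights and the node layout", {
  net <- generate_network(synth_spec(80, 500, decay_scale = 15,
                                     propensity_sd = 0.5, seed = 6))
  src_deg <- node_degrees(net)
  src_w <- sort(net$edges$weight)
  for (ty in c("random", "spatial", "reduced")) {
    ens <- generate_ensemble(net, rewiring_config(ty, seed = 42),
                             n_members = 3)
    for (m in ens$members) {
      expect_identical(m$nodes, net$nodes)
      expect_equal(nrow(m$edges), nrow(net$edges))
      expect_equal(node_degrees(m), src_deg)
      expect_equal(sort(m$edges$weight), src_w)
    }
  }
})

test_that("spatial members never exceed per-region source wiring", {
  net <- generate_network(synth_spec(80, 500, decay_scale = 15, seed = 6))
  ens <- generate_ensemble(net, rewiring_config("spatial", seed = 1), 3)
  src <- node_total_lengths(net)
  for (m in ens$members) {
    expect_true(all(node_total_lengths(m) <= src + 1e-9))
  }
  # and members are genuinely rewired, not copies
  expect_lt(similarity_binary(net, ens$members[[1]]), 1)
})

test_that("reduced members shorten total wiring monotonically", {
  net <- generate_network(synth_spec(80, 500, decay_scale = 15, seed = 6))
  for (mode in c("per_region_strict", "total_length")) {
    ens <- generate_ensemble(net, rewiring_config("reduced",
                                                  reduced_mode = mode,
                                                  seed = 2), 2)
    for (m in ens$members) {
      expect_lt(total_wiring_length(m), total_wiring_length(net))
    }
  }

  # per accepted swap the total strictly decreases (R-level replay;
  # acceptance is rare, so propose until ten swaps have landed)
  set.seed(7)
  cur <- net
  cfg <- rewiring_config("reduced")
  tot <- total_wiring_length(cur)
  accepted <- 0
  for (i in 1:20000) {
    if (accepted >= 10) break
    cand <- propose_swap(cur)
    if (!cand$valid) next
    if (!accept_swap(net, cur, cand, cfg)) next
    edges <- cur$edges
    edges[cand$edge_rows[1], ] <- cand$added[1, ]
    edges[cand$edge_rows[2], ] <- cand$added[2, ]
    cur <- spatial_network(cur$nodes, edges)
    new_tot <- total_wiring_length(cur)
    expect_lt(new_tot, tot)
    tot <- new_tot
    accepted <- accepted + 1
  }
  expect_gte(accepted, 10)
})

test_that("ensemble generation is deterministic and order-independent", {
  net <- generate_network(synth_spec(50, 200, decay_scale = 20, seed = 3))
  a <- generate_ensemble(net, rewiring_config("random", seed = 9), 3)
  b <- generate_ensemble(net, rewiring_config("random", seed = 9), 3)
  expect_equal(a$members[[2]]$edges, b$members[[2]]$edges)
  # member seeds derive from base seed + index, so a shorter run reproduces
  # the same leading members
  c1 <- generate_ensemble(net, rewiring_config("random", seed = 9), 1)
  expect_equal(c1$members[[1]]$edges, a$members[[1]]$edges)
})

test_that("saturation is reported, not fatal", {
  # a tiny dense graph quickly runs out of length-reducing swaps
  net <- generate_network(synth_spec(12, 40, decay_scale = 5, seed = 1))
  ens <- generate_ensemble(net, rewiring_config("reduced", swaps_per_edge = 20,
                                                max_attempts_factor = 2,
                                                seed = 1), 2)
  expect_true(all(ens$provenance$saturated))
  expect_true(all(ens$provenance$accepted < ens$provenance$required))
})
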