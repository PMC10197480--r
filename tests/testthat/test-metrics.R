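test_that("analytic fixed points: empty, complete, path, disjoint triangles", {
  empty <- make_net(matrix(0L, 16, 16))
  me <- network_metrics(empty)
  expect_equal(unname(me$degree), rep(0L, 16))
  expect_equal(me$edge_density, 0)
  expect_equal(me$modularity, 0)                    # convention for the edgeless graph
  expect_identical(me$n_modules, 16L)               # isolated nodes are singletons

  comp <- make_net(matrix(1L, 16, 16) - diag(16L))
  mc <- network_metrics(comp)
  expect_equal(unname(mc$degree), rep(15L, 16))
  expect_equal(mc$edge_density, 1)
  expect_identical(mc$n_modules, 1L)
  expect_equal(mc$modularity, 0)                    # one module: 1 - 1^2 = 0

  path <- matrix(0L, 3, 3); path[1, 2] <- path[2, 3] <- 1L
  mp <- network_metrics(make_net(path + t(path), traits = c("A", "B", "C")))
  expect_equal(unname(mp$degree[c("A", "B", "C")]), c(1L, 2L, 1L))

  tri2 <- matrix(0L, 6, 6)
  tri2[1, 2] <- tri2[2, 3] <- tri2[1, 3] <- 1L
  tri2[4, 5] <- tri2[5, 6] <- tri2[4, 6] <- 1L
  mt <- network_metrics(make_net(tri2 + t(tri2)))
  expect_equal(mt$modularity, 0.5)
  expect_identical(mt$n_modules, 2L)
  expect_identical(unname(mt$membership[1:3]), rep(mt$membership[[1]], 3))
})

test_that("degree, density and Q match brute-force oracles on random graphs", {
  set.seed(41)
  for (rep in 1:60) {
    k <- sample(3:16, 1)
    adj <- random_adjacency(k)
    m <- network_metrics(make_net(adj))
    expect_identical(unname(m$degree), oracle_degree(adj))
    expect_equal(m$edge_density, oracle_density(adj))
    expect_equal(m$modularity, oracle_modularity(adj, unname(m$membership)),
                 tolerance = 1e-12)
    expect_equal(sum(m$degree), 2 * oracle_edge_count(adj))  # handshake lemma
    expect_gte(m$modularity, -0.5)
    expect_lte(m$modularity, 1)
  }
})

test_that("greedy Q never exceeds the exhaustive optimum on small graphs", {
  set.seed(42)
  for (rep in 1:25) {
    k <- sample(3:6, 1)
    adj <- random_adjacency(k)
    if (oracle_edge_count(adj) == 0) next
    m <- network_metrics(make_net(adj))
    expect_lte(m$modularity, oracle_best_modularity(adj) + 1e-12)
  }
})

test_that("community detection is reproducible", {
  x <- log_transform(simulate_traits(n = 150, seed = 43))
  net <- threshold_network(x)
  g1 <- network_metrics(net)
  g2 <- network_metrics(net)
  expect_identical(g1$membership, g2$membership)     # greedy: bit-reproducible

  l1 <- network_metrics(net, method = "louvain", seed = 99)
  l2 <- network_metrics(net, method = "louvain", seed = 99)
  expect_identical(l1$membership, l2$membership)
  expect_error(network_metrics(net, method = "louvain"), "seed")
})

test_that("planted blocks are recovered as modules at high signal", {
  x <- simulate_traits(n = 500, rho_in = 0.9, rho_out = 0, seed = 44)
  met <- network_metrics(threshold_network(log_transform(x)))
  ari <- adjusted_rand_index(met$membership, ptn_truth(x)$membership)
  expect_equal(ari, 1)
})

test_that("hub ranking is deterministic and finds a planted hub", {
  degs <- make_net(matrix(0L, 4, 4), traits = c("D", "B", "C", "A"))
  m <- network_metrics(degs)
  expect_identical(hub_traits(m, 4)$trait, c("A", "B", "C", "D"))  # lexicographic ties

  path <- matrix(0L, 3, 3); path[1, 2] <- path[2, 3] <- 1L
  mp <- network_metrics(make_net(path + t(path), traits = c("A", "B", "C")))
  expect_identical(hub_traits(mp, 1)$trait, "B")

  x <- suppressWarnings(  # block+hub construction is mildly non-PSD; repaired
    simulate_traits(n = 400, rho_in = 0.8, rho_out = 0,
                    hub_trait = "SPC", rho_hub = 0.45, seed = 45))
  mh <- network_metrics(threshold_network(log_transform(x)))
  expect_identical(hub_traits(mh, 1)$trait, "SPC")
})

test_that("category importance follows its definitions", {
  comp <- network_metrics(make_net(matrix(1L, 16, 16) - diag(16L),
                                   traits = ptn_traits()))
  imp <- trait_importance(comp)
  expect_equal(imp$absolute_importance, rep(15, 3))
  expect_equal(imp$relative_importance, rep(15 / 240, 3))

  empty <- network_metrics(make_net(matrix(0L, 16, 16), traits = ptn_traits()))
  imp0 <- trait_importance(empty)
  expect_equal(imp0$absolute_importance, rep(0, 3))
  expect_equal(imp0$relative_importance, rep(0, 3))

  # hand-computed: economic degrees all 2, chemical all 0, structural all 1
  deg <- tibble::tibble(trait = ptn_traits(),
                        degree = rep(c(2, 0, 1), times = c(6, 6, 4)))
  imp2 <- trait_importance(deg)
  expect_equal(imp2$absolute_importance[match(c("economic", "chemical", "structural"),
                                              imp2$category)], c(2, 0, 1))
  expect_equal(imp2$relative_importance[match(c("economic", "chemical", "structural"),
                                              imp2$category)], c(0.125, 0, 0.0625))
  # sum over categories of (absolute x size) = total degree
  expect_equal(sum(imp2$absolute_importance * imp2$n_traits), sum(deg$degree))

  expect_error(trait_importance(deg, tibble::tibble(trait = "nope", category = "x")),
               "does not cover|unknown")
})
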