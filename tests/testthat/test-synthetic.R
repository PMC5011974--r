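test_that("generators are reproducible and leave the caller's RNG alone", {
  a <- generate_network("erdos-renyi-np", n = 30, p = 0.2, seed = 11)
  b <- generate_network("erdos-renyi-np", n = 30, p = 0.2, seed = 11)
  expect_identical(a$arcs, b$arcs)
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_network("erdos-renyi-np", 10, p = 0.5,
                                           seed = 3))
  expect_identical(runif(1), before)
})

test_that("model semantics: p = 0, planted hub, nm count, bipartite cover", {
  expect_equal(n_arcs(generate_network("erdos-renyi-np", 50, p = 0,
                                       seed = 1)), 0)
  hub <- generate_network("planted-hub", n = 20, p = 0, seed = 4)
  expect_equal(solve_mds(hub)$genes, "hub")

  nm <- generate_network("erdos-renyi-nm", n = 12, m = 30, seed = 5)
  expect_equal(n_arcs(nm), 30)
  expect_true(all(nm$arcs$from != nm$arcs$to))

  bp <- generate_network("tf-target-bipartite", n = 25, p = 0.1, n_tf = 5,
                         seed = 6)
  expect_true(all(bp$arcs$from %in% sprintf("TF%d", 1:5)))
  targets <- setdiff(bp$nodes, sprintf("TF%d", 1:5))
  expect_true(all(targets %in% bp$arcs$to))          # every target covered
  expect_true(all(bp$is_tf[sprintf("TF%d", 1:5)]))

  expect_error(generate_network("erdos-renyi-np", 10, p = 1.5, seed = 1),
               "p must")
  expect_error(generate_network("erdos-renyi-nm", 5, m = 99, seed = 1),
               "m must")
})

test_that("benchmark grid shape, oracle agreement and Jaccard edge cases", {
  tab <- benchmark_grid(sizes = c(6, 8), densities = 0.3, seeds = 1:2)
  expect_equal(nrow(tab), 2 * 2 * 3)
  expect_setequal(unique(tab$method),
                  c("mds-ilp", "mcds-ilp", "mcds-heuristic"))
  for (r in which(tab$method == "mcds-ilp")) {
    net <- generate_network("erdos-renyi-np", n = tab$n[r], p = tab$p[r],
                            seed = tab$seed[r])
    comp <- netdom:::resolve_component(net, "auto")
    expect_equal(tab$size[r], brute_force_mcds(comp$net)$size)
  }
  hj <- tab$jaccard_vs_ilp[tab$method == "mcds-heuristic"]
  expect_true(all(hj >= 0 & hj <= 1))

  expect_equal(jaccard_index(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_index("a", "b"), 0)
  expect_equal(jaccard_index(character(0), character(0)), 1)
})

test_that("identical seeds give identical benchmark tables", {
  t1 <- benchmark_grid(6, 0.3, 1, methods = "mcds-heuristic")
  t2 <- benchmark_grid(6, 0.3, 1, methods = "mcds-heuristic")
  expect_identical(t1[names(t1) != "elapsed"], t2[names(t2) != "elapsed"])
})
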