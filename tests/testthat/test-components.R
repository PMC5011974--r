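test_that("SCC/WCC basics: cycles, DAGs, isolated nodes", {
  cyc <- regulatory_network(c("a", "b", "c"), c("b", "c", "a"))
  sccs <- strongly_connected_components(cyc)
  expect_length(sccs, 1)
  expect_equal(length(sccs[[1]]$members), 3)
  expect_equal(sccs[[1]]$kind, "SCC")

  dag <- directed_path()
  expect_length(strongly_connected_components(dag), 3)

  net <- regulatory_network("a", "b", nodes = c("a", "b", "c"))
  wccs <- weakly_connected_components(net)
  expect_length(wccs, 2)
  expect_equal(wccs[[1]]$members, c("a", "b"))
  expect_equal(wccs[[2]]$members, "c")

  empty4 <- regulatory_network(nodes = letters[1:4])
  expect_length(weakly_connected_components(empty4), 4)
})

test_that("SCC partition matches the reachability-closure oracle", {
  for (s in 1:25) {
    net <- random_net(n = 8, p = 0.15 + (s %% 4) / 10, seed = 100 + s)
    got <- strongly_connected_components(net)
    got_sets <- lapply(got, `[[`, "members")
    want_sets <- oracle_scc_partition(net)
    key <- function(sets) sort(vapply(sets, function(x)
      paste(sort(x), collapse = ","), ""))
    expect_equal(key(got_sets), key(unname(want_sets)))
    # partition property and WCC containment
    expect_setequal(unlist(got_sets), net$nodes)
    expect_equal(sum(lengths(got_sets)), n_nodes(net))
    wcc <- weakly_connected_components(net)
    for (sc in got_sets) {
      holder <- vapply(wcc, function(w) all(sc %in% w$members), TRUE)
      expect_equal(sum(holder), 1)
    }
  }
})

test_that("density follows |E|/(|V||V-1|) with singleton = 0", {
  cyc <- strongly_connected_components(
    regulatory_network(c("a", "b", "c"), c("b", "c", "a")))[[1]]
  expect_equal(cyc$density, 3 / 6)
  singleton <- weakly_connected_components(
    regulatory_network(nodes = "x"))[[1]]
  expect_equal(singleton$density, 0)
  complete <- regulatory_network(rep(c("a", "b"), 1), c("b", "a"))
  expect_equal(weakly_connected_components(complete)[[1]]$density, 1)
  # self-loops never contribute
  loopy <- regulatory_network(c("a", "a", "b"), c("a", "b", "a"))
  expect_equal(weakly_connected_components(loopy)[[1]]$density, 1)
})

test_that("component selection: whole network, density rule, ties", {
  expect_equal(select_component(toy_fig_a())$selection, "whole")

  # LCC {a,b,c,d} density 4/12 < LSCC {a,b,c} density 3/6 -> LSCC
  net <- regulatory_network(c("a", "b", "c", "a", "e"),
                            c("b", "c", "a", "d", "f"))
  sel <- select_component(net)
  expect_equal(sel$selection, "lscc")
  expect_setequal(sel$members, c("a", "b", "c"))
  expect_equal(sel$density, 0.5)

  # equal-size WCCs: the one whose smallest node appears first is the LCC
  two <- regulatory_network(c("x", "p"), c("y", "q"))
  expect_equal(weakly_connected_components(two)[[1]]$members, c("x", "y"))

  expect_error(select_component(regulatory_network()), "empty")
})
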