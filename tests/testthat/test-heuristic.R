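test_that("phase 1: stars and the path hand-trace", {
  st <- phase1_dominators(out_star(4))
  expect_equal(st$net$nodes[st$color == 2L], "center")
  expect_equal(sum(st$color == 1L), 4)

  two <- regulatory_network(c(rep("c1", 3), rep("c2", 3)),
                            c(paste0("a", 1:3), paste0("b", 1:3)))
  st <- phase1_dominators(two)
  expect_setequal(two$nodes[st$color == 2L], c("c1", "c2"))

  # path a->b->c: tie on coverage 1, b wins by in-degree; a remains white
  st <- phase1_dominators(directed_path())
  expect_setequal(st$net$nodes[st$color == 2L], c("a", "b"))
})

test_that("phase 2 connects black nodes through shortest-seeming joins", {
  # a -> b -> c with black {a, c}: b must become dark gray
  net <- directed_path()
  st <- netdom:::new_coloring(net)
  st$color <- c(2L, 1L, 2L)
  st <- phase2_connectors(st, net)
  expect_equal(net$nodes[st$color == 3L], "b")
  expect_length(check_weak_connectivity(net$nodes[st$color >= 2L],
                                        underlying_undirected(net)), 1)

  # already-connected black set: nothing added
  st2 <- netdom:::new_coloring(net)
  st2$color <- c(2L, 2L, 1L)
  expect_equal(sum(phase2_connectors(st2, net)$color == 3L), 0)

  # two hubs joined only by a 2-node path: both path nodes turn dark gray
  hubs <- regulatory_network(
    c(rep("h1", 3), rep("h2", 3), "h1", "h2", "m1"),
    c(paste0("x", 1:3), paste0("y", 1:3), "m1", "m2", "m2"))
  st3 <- phase1_dominators(hubs)
  expect_setequal(hubs$nodes[st3$color == 2L], c("h1", "h2"))
  st3 <- phase2_connectors(st3, hubs)
  expect_setequal(hubs$nodes[st3$color == 3L], c("m1", "m2"))

  disc <- regulatory_network(c("a", "c"), c("b", "d"))
  std <- phase1_dominators(disc)
  expect_error(phase2_connectors(std, disc), "not weakly connected")
})

test_that("phase 3 prunes redundant members only", {
  # center covers everything; a stray black leaf is removable
  net <- out_star(4)
  st <- netdom:::new_coloring(net)
  st$color <- c(2L, 2L, 1L, 1L, 1L)  # center black, l1 black too
  res <- phase3_prune(st, net)
  expect_equal(res$genes, "center")
  expect_equal(res$meta$n_pruned, 1)

  st2 <- netdom:::new_coloring(net)
  st2$color <- c(2L, 1L, 1L, 1L, 1L)
  expect_equal(phase3_prune(st2, net)$genes, "center")
})

test_that("full heuristic: validity, determinism, planted optimum", {
  res <- run_heuristic(directed_path())
  expect_setequal(res$genes, c("a", "b"))

  # universal out-hub is found exactly
  hub <- generate_network("planted-hub", n = 20, p = 0, seed = 1)
  expect_equal(run_heuristic(hub)$genes, "hub")

  # disconnected input runs on the density-selected component
  net <- regulatory_network(c("a", "b", "c", "a", "e"),
                            c("b", "c", "a", "d", "f"))
  res <- run_heuristic(net)
  expect_equal(res$selection, "lscc")
  expect_true(all(res$genes %in% c("a", "b", "c")))

  # byte-identical repeated runs
  r1 <- run_heuristic(toy_fig_a())
  r2 <- run_heuristic(toy_fig_a())
  expect_identical(r1$genes, r2$genes)
  expect_identical(r1$roles, r2$roles)
})

test_that("heuristic is always valid and never beats the ILP", {
  infl <- numeric(0)
  n_done <- 0; s <- 0
  while (n_done < 25) {
    s <- s + 1
    net <- random_net(n = 6 + (s %% 4), p = 0.2 + 0.3 * (s %% 3) / 3,
                      seed = 3000 + s)
    if (!igraph_connected(net, net$nodes)) next
    n_done <- n_done + 1
    h <- run_heuristic(net)
    expect_true(is_dominating_set(net, h$genes))
    expect_true(igraph_connected(net, h$genes))
    opt <- solve_mcds_ilp(net)$size
    expect_gte(h$size, opt)
    infl <- c(infl, h$size / opt)
  }
  expect_true(mean(infl) >= 1)
})
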