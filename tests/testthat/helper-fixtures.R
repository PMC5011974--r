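# Fixture builders and independent oracles shared by the test files.
# Everything here stays independent of the package code paths it checks:
# reachability by boolean-matrix squaring, connectivity via igraph, and an
# explicit binomial-coefficient sum for the hypergeometric tail.

toy_fig_a <- function() {
  # two regulators jointly covering three targets, linked through C
  regulatory_network(c("A", "A", "B", "B", "C"),
                     c("C", "E", "C", "D", "B"))
}

directed_path <- function(ids = c("a", "b", "c")) {
  regulatory_network(ids[-length(ids)], ids[-1])
}

out_star <- function(n_leaves = 5) {
  regulatory_network(rep("center", n_leaves), paste0("l", seq_len(n_leaves)))
}

random_net <- function(n, p, seed) {
  generate_network("erdos-renyi-np", n = n, p = p, seed = seed)
}

# first weakly connected ER digraph at or after `seed`
random_connected_net <- function(n, p, seed) {
  for (s in seed + 0:500) {
    net <- random_net(n, p, s)
    if (igraph_connected(net, net$nodes)) return(net)
  }
  stop("no connected instance found")
}

net_to_igraph <- function(net) {
  igraph::graph_from_data_frame(net$arcs[, c("from", "to")],
                                directed = TRUE,
                                vertices = data.frame(name = net$nodes))
}

# reachability closure by repeated boolean squaring (SCC oracle)
reachability_closure <- function(net) {
  n <- n_nodes(net)
  A <- diag(TRUE, n)
  for (r in seq_len(nrow(net$arcs))) {
    i <- match(net$arcs$from[r], net$nodes)
    j <- match(net$arcs$to[r], net$nodes)
    A[i, j] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A > 0)) break
    A <- A2
  }
  A > 0
}

# SCC partition from the closure: mutual reachability classes
oracle_scc_partition <- function(net) {
  R <- reachability_closure(net)
  mutual <- R & t(R)
  memb <- integer(n_nodes(net))
  cls <- 0L
  for (i in seq_len(n_nodes(net))) {
    if (memb[i] == 0L) {
      cls <- cls + 1L
      memb[mutual[i, ]] <- cls
    }
  }
  split(net$nodes, memb)
}

# independent connectivity check of a node subset (igraph route)
igraph_connected <- function(net, selected) {
  g <- igraph::as_undirected(net_to_igraph(net), mode = "collapse")
  sub <- igraph::induced_subgraph(g, selected)
  igraph::components(sub)$no == 1
}

# exact hypergeometric upper tail by direct binomial-coefficient summation
hyper_tail_bruteforce <- function(M, k, N, x) {
  i <- x:min(N, k)
  sum(choose(k, i) * choose(M - k, N - i)) / choose(M, N)
}
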