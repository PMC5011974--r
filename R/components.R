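#' Network components and the density-based selection rule
#'
#' A connected dominating set only exists inside a connected piece of the
#' network, so MCDS computations are run on one component. The package
#' decomposes a network into strongly connected components (SCC: mutual
#' directed reachability) and weakly connected components (WCC: connectivity
#' of the underlying undirected graph) and, when the network is not weakly
#' connected, chooses between the largest WCC ("LCC") and the largest SCC
#' ("LSCC") by component density
#' \deqn{\rho = |E| / (|V| (|V|-1)),}
#' the fraction of possible directed arcs realised inside the component
#' (self-loops excluded; singletons get density 0). Denser components need
#' fewer connector genes, so the denser of the two is selected; a density tie
#' prefers the LCC (larger coverage of the network).
#'
#' @name components
NULL

new_component <- function(net, members, kind) {
  members <- net$nodes[sort(node_id(net, members))]
  keep <- net$arcs$from %in% members & net$arcs$to %in% members
  arcs <- net$arcs[keep, , drop = FALSE]
  n <- length(members)
  m <- sum(arcs$from != arcs$to)  # self-loops never count towards density
  structure(list(members = members, kind = kind,
                 induced_arcs = arcs,
                 density = if (n >= 2) m / (n * (n - 1)) else 0,
                 net = induced_subnetwork(net, members)),
            class = "network_component")
}

#' @export
print.network_component <- function(x, ...) {
  cat(sprintf("network_component (%s): %d nodes, %d arcs, density %.4g\n",
              x$kind, length(x$members), nrow(x$induced_arcs), x$density))
  invisible(x)
}

# shared: membership vector -> list of components sorted by size desc,
# ties by smallest first-appearance index
group_components <- function(net, membership, kind) {
  idx <- seq_along(net$nodes)
  groups <- split(idx, membership)
  first <- vapply(groups, min, numeric(1))
  sizes <- lengths(groups)
  groups <- unname(groups[order(-sizes, first)])
  lapply(groups, function(g) new_component(net, net$nodes[g], kind))
}

#' Strongly connected components
#'
#' Decomposition into maximal sets of mutually reachable nodes (Tarjan-style
#' linear-time decomposition, via igraph). Components are sorted by size
#' descending, ties by the smallest first-appearance node index.
#'
#' @param net a [regulatory_network()].
#' @return list of `network_component` objects with `kind = "SCC"`.
#' @export
strongly_connected_components <- function(net) {
  if (n_nodes(net) == 0) return(list())
  memb <- igraph::components(as_igraph(net), mode = "strong")$membership
  group_components(net, memb, "SCC")
}

#' Weakly connected components
#'
#' Components of the underlying undirected graph, sorted as in
#' [strongly_connected_components()].
#'
#' @param net a [regulatory_network()].
#' @return list of `network_component` objects with `kind = "WCC"`.
#' @export
weakly_connected_components <- function(net) {
  if (n_nodes(net) == 0) return(list())
  memb <- igraph::components(as_igraph(net), mode = "weak")$membership
  group_components(net, memb, "WCC")
}

#' Select the component on which to compute an MCDS
#'
#' If the network is weakly connected the whole network is used. Otherwise
#' the largest WCC (LCC) and largest SCC (LSCC) are compared by density and
#' the denser one is chosen; ties prefer the LCC. See [components].
#'
#' @param net a [regulatory_network()].
#' @return a `network_component` whose `selection` element records the
#'   rationale: `"whole"`, `"lcc"` or `"lscc"`.
#' @export
select_component <- function(net) {
  if (n_nodes(net) == 0)
    stop("cannot select a component of an empty network", call. = FALSE)
  wcc <- weakly_connected_components(net)
  if (length(wcc) == 1) {
    comp <- wcc[[1]]
    comp$selection <- "whole"
    return(comp)
  }
  lcc <- wcc[[1]]
  lscc <- strongly_connected_components(net)[[1]]
  if (lscc$density > lcc$density) {
    lscc$selection <- "lscc"
    lscc
  } else {
    lcc$selection <- "lcc"
    lcc
  }
}

# Resolve a user-facing component policy to a concrete component.
resolve_component <- function(net, policy = c("auto", "whole", "lcc", "lscc")) {
  policy <- match.arg(policy)
  if (n_nodes(net) == 0)
    stop("empty network", call. = FALSE)
  comp <- switch(policy,
    auto = select_component(net),
    whole = {
      c0 <- new_component(net, net$nodes, "WCC")
      c0$selection <- "whole"
      c0
    },
    lcc = {
      c0 <- weakly_connected_components(net)[[1]]
      c0$selection <- "lcc"
      c0
    },
    lscc = {
      c0 <- strongly_connected_components(net)[[1]]
      c0$selection <- "lscc"
      c0
    })
  comp
}
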