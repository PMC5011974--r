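#' Three-phase greedy heuristic for directed MCDS
#'
#' A colouring algorithm over the component: all nodes start *white*
#' (uncovered). Phase 1 repeatedly picks a dominator and colours it *black*,
#' its uncovered targets *gray*, until no white node remains. Phase 2 grows
#' the black set into one weakly connected structure by colouring connector
#' nodes *dark gray*. Phase 3 prunes the structure, removing members as long
#' as domination and connectivity both survive. Black members are reported
#' as dominators, dark-gray members as connectors.
#'
#' Every choice is deterministic via a fixed tie cascade ending in the order
#' of first appearance in the input, so identical input gives byte-identical
#' output.
#'
#' @name mcds_heuristic
NULL

# Internal colouring state: integer codes over component nodes.
# 0 white, 1 gray, 2 black, 3 darkgray.
new_coloring <- function(net) {
  structure(list(net = net, color = rep(0L, n_nodes(net))),
            class = "coloring_state")
}

#' @export
print.coloring_state <- function(x, ...) {
  tab <- table(factor(x$color, levels = 0:3,
                      labels = c("white", "gray", "black", "darkgray")))
  cat("coloring_state:", paste(names(tab), tab, collapse = ", "), "\n")
  invisible(x)
}

#' Phase 1: greedy choice of dominators
#'
#' Repeatedly selects the white node covering the most still-white targets
#' (out-neighbours), colours it black and its white targets gray. By default
#' the ranking is the *coverage gain* (white out-neighbours); with
#' `rank = "static"` it is the static out-degree, the literal reading that
#' can stall on nodes covering nothing new. Ties go to the higher total
#' in-degree (a proxy for connectivity to the rest of the structure), then
#' to first-appearance order.
#'
#' @param net a [regulatory_network()] (usually a selected component's
#'   network).
#' @param rank `"coverage"` (default) or `"static"`.
#' @return a `coloring_state` with no white nodes.
#' @export
phase1_dominators <- function(net, rank = c("coverage", "static")) {
  rank <- match.arg(rank)
  st <- new_coloring(net)
  n <- n_nodes(net)
  indeg <- unname(in_degrees(net))
  outdeg <- unname(out_degrees(net))
  while (any(st$color == 0L)) {
    white <- which(st$color == 0L)
    gain <- vapply(white, function(v)
      sum(st$color[net$out_idx[[v]]] == 0L), integer(1))
    score <- if (rank == "coverage") gain else outdeg[white]
    pick <- white[order(-score, -indeg[white], white)][1]
    st$color[pick] <- 2L
    covered <- net$out_idx[[pick]]
    st$color[covered[st$color[covered] == 0L]] <- 1L
  }
  st
}

#' Phase 2: connect the dominators
#'
#' While the structure (black plus dark-gray nodes) falls into two or more
#' weakly connected pieces, the outside node adjacent (either arc direction)
#' to the most structure nodes is coloured dark gray and added. Ties go to
#' higher out-degree, then higher in-degree, then first appearance. The
#' underlying component must be weakly connected or no sequence of
#' connectors can ever finish.
#'
#' @param state a `coloring_state` after [phase1_dominators()].
#' @param net the same network.
#' @return the updated `coloring_state`; black and dark-gray nodes induce
#'   one weakly connected subgraph.
#' @export
phase2_connectors <- function(state, net) {
  ug <- underlying_undirected(net)
  if (length(check_weak_connectivity(net$nodes, ug)) != 1)
    stop("component is not weakly connected; connectors cannot join it",
         call. = FALSE)
  n <- n_nodes(net)
  indeg <- unname(in_degrees(net))
  outdeg <- unname(out_degrees(net))
  # undirected adjacency index lists
  adj <- vector("list", n)
  for (r in seq_len(nrow(ug$edges))) {
    u <- ug$edges[r, 1]; v <- ug$edges[r, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  repeat {
    members <- which(state$color >= 2L)
    if (length(check_weak_connectivity(net$nodes[members], ug)) <= 1) break
    outside <- which(state$color < 2L)
    count <- vapply(outside, function(v)
      sum(state$color[adj[[v]]] >= 2L), integer(1))
    pick <- outside[order(-count, -outdeg[outside], -indeg[outside],
                          outside)][1]
    state$color[pick] <- 3L
  }
  state
}

#' Phase 3: prune the connected dominating set
#'
#' Members are scanned in ascending static out-degree (ties: higher
#' in-degree, then first appearance); a member is removed when the remainder
#' still dominates the component and still induces one weakly connected
#' subgraph. After each removal the scan restarts. The fixed point is
#' returned as a [dominating_set_result()] with black members as dominators
#' and dark-gray members as connectors.
#'
#' @param state a `coloring_state` after phases 1 and 2.
#' @param net the same network.
#' @return a [dominating_set_result()].
#' @export
phase3_prune <- function(state, net) {
  ug <- underlying_undirected(net)
  indeg <- unname(in_degrees(net))
  outdeg <- unname(out_degrees(net))
  removed <- 0L
  repeat {
    members <- which(state$color >= 2L)
    if (length(members) <= 1) break
    cand <- members[order(outdeg[members], -indeg[members], members)]
    dropped <- FALSE
    for (v in cand) {
      rest <- setdiff(members, v)
      rest_ids <- net$nodes[rest]
      if (is_dominating_set(net, rest_ids) &&
          length(check_weak_connectivity(rest_ids, ug)) == 1) {
        state$color[v] <- 1L  # back to dominated
        removed <- removed + 1L
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  members <- which(state$color >= 2L)
  dominating_set_result(net$nodes[members],
                        ifelse(state$color[members] == 2L, "dominator",
                               "connector"),
                        method = "mcds-heuristic", status = "heuristic",
                        meta = list(n_pruned = removed))
}

#' Run the full MCDS heuristic
#'
#' Chains component selection ([select_component()] under the default
#' `"auto"` policy), [phase1_dominators()], [phase2_connectors()] and
#' [phase3_prune()].
#'
#' @param net a [regulatory_network()].
#' @param component_policy `"auto"` (density rule), `"whole"`, `"lcc"` or
#'   `"lscc"`.
#' @param rank phase-1 ranking, see [phase1_dominators()].
#' @return a [dominating_set_result()] whose metadata records the per-phase
#'   tallies (`n_phase1_black`, `n_phase2_darkgray`, `n_pruned`) and the
#'   selected component's size and density.
#' @examples
#' star <- regulatory_network(rep("hub", 4), paste0("t", 1:4))
#' run_heuristic(star)
#' @export
run_heuristic <- function(net, component_policy = "auto",
                          rank = c("coverage", "static")) {
  rank <- match.arg(rank)
  comp <- resolve_component(net, component_policy)
  cnet <- comp$net
  st <- phase1_dominators(cnet, rank = rank)
  n1 <- sum(st$color == 2L)
  st <- phase2_connectors(st, cnet)
  n2 <- sum(st$color == 3L)
  res <- phase3_prune(st, cnet)
  res$component_kind <- comp$kind
  res$selection <- comp$selection
  res$meta <- c(res$meta,
                list(n_phase1_black = n1, n_phase2_darkgray = n2,
                     component_size = length(comp$members),
                     component_density = comp$density, rank = rank))
  res
}
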