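#' Validity checks for dominating sets
#'
#' `is_dominating_set()` checks the directed covering condition: every node
#' is selected or has a selected in-neighbour (self-loops never count).
#' `induces_connected_subgraph()` checks that the selection induces one
#' weakly connected piece of the underlying undirected graph.
#'
#' @param net a [regulatory_network()].
#' @param selected character vector of node ids.
#' @return logical scalar.
#' @export
is_dominating_set <- function(net, selected) {
  if (!length(selected)) return(n_nodes(net) == 0)
  sel <- logical(n_nodes(net))
  sel[node_id(net, selected)] <- TRUE
  for (u in seq_len(n_nodes(net))) {
    if (sel[u]) next
    if (!any(sel[net$in_idx[[u]]])) return(FALSE)
  }
  TRUE
}

#' @rdname is_dominating_set
#' @export
induces_connected_subgraph <- function(net, selected) {
  if (!length(selected)) return(FALSE)
  length(check_weak_connectivity(selected, underlying_undirected(net))) == 1
}

#' Brute-force dominating-set oracles
#'
#' Reference implementations that certify the solvers on small instances by
#' plain enumeration of node subsets in increasing cardinality: the first
#' cardinality with a feasible subset is optimal, and all optimal subsets
#' are collected. No pruning beyond the cardinality ordering — clarity over
#' speed, hence the hard size guards (15 nodes for MDS, 12 for MCDS).
#'
#' @param net a [regulatory_network()]; for [brute_force_mcds()] it must be
#'   weakly connected.
#' @return an `oracle_result`: `size` (the optimum), `witnesses` (all
#'   optimal sets, lexicographically sorted), `examined` (subsets tested).
#' @examples
#' path <- regulatory_network(c("a", "b"), c("b", "c"))
#' brute_force_mds(path)$witnesses
#' @export
brute_force_mds <- function(net) {
  if (n_nodes(net) == 0 || n_nodes(net) > 15)
    stop("brute_force_mds is guarded to 1..15 nodes", call. = FALSE)
  brute_force_search(net, check_connectivity = FALSE)
}

#' @rdname brute_force_mds
#' @export
brute_force_mcds <- function(net) {
  if (n_nodes(net) == 0 || n_nodes(net) > 12)
    stop("brute_force_mcds is guarded to 1..12 nodes", call. = FALSE)
  if (!induces_connected_subgraph(net, net$nodes))
    stop("brute_force_mcds requires weakly connected input", call. = FALSE)
  brute_force_search(net, check_connectivity = TRUE)
}

brute_force_search <- function(net, check_connectivity) {
  n <- n_nodes(net)
  ug <- if (check_connectivity) underlying_undirected(net)
  examined <- 0L
  for (k in seq_len(n)) {
    witnesses <- list()
    sets <- combn(n, k)
    for (c_i in seq_len(ncol(sets))) {
      ids <- net$nodes[sets[, c_i]]
      examined <- examined + 1L
      ok <- is_dominating_set(net, ids) &&
        (!check_connectivity ||
           length(check_weak_connectivity(ids, ug)) == 1)
      if (ok) witnesses[[length(witnesses) + 1]] <- ids
    }
    if (length(witnesses)) {
      key <- vapply(witnesses, paste, "", collapse = "\r")
      witnesses <- witnesses[order(key)]
      return(structure(list(size = k, witnesses = witnesses,
                            examined = examined),
                       class = "oracle_result"))
    }
  }
  stop("internal error: the full node set must be feasible", call. = FALSE)
}

#' @export
print.oracle_result <- function(x, ...) {
  cat(sprintf("oracle_result: optimum %d, %d optimal set(s), %d subsets examined\n",
              x$size, length(x$witnesses), x$examined))
  invisible(x)
}
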