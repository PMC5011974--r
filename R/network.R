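#' Construct a regulatory network
#'
#' A `regulatory_network` is a directed graph over gene identifiers with arcs
#' pointing from regulator to target. Arcs are a set (duplicates collapse);
#' node identity is the verbatim, case-sensitive string. Self-loops
#' (autoregulation) are retained as data but are excluded from in-/out-
#' neighbourhoods, degrees, undirected edges and densities: an autoregulatory
#' arc cannot make a non-selected gene dominated, and keeping it in the
#' covering constraints would make them vacuous.
#'
#' The global node order is the order of first appearance (scanning each arc
#' regulator-then-target, then any extra isolated nodes); it is the final
#' tie-break of every deterministic rule in the package.
#'
#' @param from,to character vectors of equal length: regulator and target of
#'   each arc.
#' @param sign optional per-arc label (e.g. activation/inhibition); carried
#'   through, never used by the solvers.
#' @param nodes optional character vector of node ids, used to declare
#'   isolated nodes and/or impose a first-appearance order; arc endpoints not
#'   listed are appended in order of appearance.
#' @param is_tf optional named logical vector flagging transcription factors.
#' @return an object of class `regulatory_network` with elements `nodes`,
#'   `arcs` (data.frame `from`, `to`, `sign`), and `is_tf`.
#' @examples
#' net <- regulatory_network(c("A", "A", "B", "B", "C"),
#'                           c("C", "E", "C", "D", "B"))
#' n_nodes(net); n_arcs(net)
#' @export
regulatory_network <- function(from = character(), to = character(),
                               sign = NULL, nodes = NULL, is_tf = NULL) {
  from <- as.character(from)
  to <- as.character(to)
  if (length(from) != length(to))
    stop("`from` and `to` must have the same length", call. = FALSE)
  if (is.null(sign)) sign <- rep(NA_character_, length(from))
  sign <- as.character(sign)
  if (length(sign) != length(from))
    stop("`sign` must match the number of arcs", call. = FALSE)
  if (anyNA(from) || anyNA(to) || any(from == "") || any(to == ""))
    stop("arc endpoints must be non-empty strings", call. = FALSE)

  keep <- if (length(from)) !duplicated(paste0(from, "\r", to))
          else logical(0)
  arcs <- data.frame(from = from[keep], to = to[keep], sign = sign[keep],
                     stringsAsFactors = FALSE)

  seen <- as.character(nodes)
  appear <- as.vector(rbind(arcs$from, arcs$to))
  all_nodes <- unique(c(seen, appear))

  tf <- rep(NA, length(all_nodes))
  names(tf) <- all_nodes
  if (!is.null(is_tf)) {
    if (is.null(names(is_tf)))
      stop("`is_tf` must be a named logical vector", call. = FALSE)
    known <- intersect(names(is_tf), all_nodes)
    tf[known] <- as.logical(is_tf[known])
  }

  net <- structure(list(nodes = all_nodes, arcs = arcs, is_tf = tf),
                   class = "regulatory_network")
  net <- build_adjacency(net)
  net
}

# Precompute index-based adjacency with self-loops excluded.
build_adjacency <- function(net) {
  n <- length(net$nodes)
  idx <- seq_len(n)
  names(idx) <- net$nodes
  fi <- idx[net$arcs$from]
  ti <- idx[net$arcs$to]
  ns <- fi != ti
  net$node_index <- idx
  net$out_idx <- unname(split(ti[ns], factor(fi[ns], levels = idx)))
  net$in_idx <- unname(split(fi[ns], factor(ti[ns], levels = idx)))
  net$out_idx <- lapply(net$out_idx, function(v) sort(unique(v)))
  net$in_idx <- lapply(net$in_idx, function(v) sort(unique(v)))
  net$has_self_loop <- idx %in% fi[!ns]
  net
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("regulatory_network: %d nodes, %d arcs (%d self-loops)\n",
              n_nodes(x), n_arcs(x), sum(x$arcs$from == x$arcs$to)))
  if (any(!is.na(x$is_tf)))
    cat(sprintf("  TFs flagged: %d\n", sum(x$is_tf %in% TRUE)))
  invisible(x)
}

#' Number of nodes / arcs
#' @param net a [regulatory_network()].
#' @return integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_arcs <- function(net) nrow(net$arcs)

node_id <- function(net, v) {
  i <- net$node_index[v]
  if (anyNA(i)) stop("unknown node: ", paste(v[is.na(i)], collapse = ", "),
                     call. = FALSE)
  unname(i)
}

#' In- and out-neighbourhoods
#'
#' `in_neighbors()` returns the regulators of `v` (the set written
#' \eqn{\delta^-(v)} in the covering constraints); `out_neighbors()` its
#' targets. Self-loops are excluded from both.
#'
#' @param net a [regulatory_network()].
#' @param v a node identifier.
#' @return character vector of node ids, in global node order.
#' @export
in_neighbors <- function(net, v) net$nodes[net$in_idx[[node_id(net, v)]]]

#' @rdname in_neighbors
#' @export
out_neighbors <- function(net, v) net$nodes[net$out_idx[[node_id(net, v)]]]

#' Static degrees (self-loops excluded)
#' @param net a [regulatory_network()].
#' @return integer vector named by node.
#' @export
out_degrees <- function(net) {
  d <- vapply(net$out_idx, length, integer(1))
  names(d) <- net$nodes
  d
}

#' @rdname out_degrees
#' @export
in_degrees <- function(net) {
  d <- vapply(net$in_idx, length, integer(1))
  names(d) <- net$nodes
  d
}

#' Underlying undirected graph
#'
#' Forgets arc direction, merges antiparallel arc pairs into one edge and
#' drops self-loops. This is the graph in which the connectivity of an MCDS
#' is assessed.
#'
#' @param net a [regulatory_network()].
#' @return object of class `undirected_graph`: `nodes` plus an `edges`
#'   two-column matrix of node indices `u < v` (0-row matrix when edgeless).
#' @export
underlying_undirected <- function(net) {
  fi <- unname(net$node_index[net$arcs$from])
  ti <- unname(net$node_index[net$arcs$to])
  ns <- fi != ti
  u <- pmin(fi[ns], ti[ns])
  v <- pmax(fi[ns], ti[ns])
  keep <- !duplicated(u * (length(net$nodes) + 1) + v)
  e <- cbind(u = u[keep], v = v[keep])
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  structure(list(nodes = net$nodes, edges = e), class = "undirected_graph")
}

#' @export
print.undirected_graph <- function(x, ...) {
  cat(sprintf("undirected_graph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Restrict a network to a node subset
#'
#' Induced subnetwork: keeps the listed nodes (in global order) and every arc
#' with both endpoints inside.
#'
#' @param net a [regulatory_network()].
#' @param members character vector of node ids.
#' @return a [regulatory_network()].
#' @export
induced_subnetwork <- function(net, members) {
  members <- net$nodes[sort(node_id(net, unique(members)))]
  keep <- net$arcs$from %in% members & net$arcs$to %in% members
  regulatory_network(net$arcs$from[keep], net$arcs$to[keep],
                     sign = net$arcs$sign[keep], nodes = members,
                     is_tf = net$is_tf[members])
}
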