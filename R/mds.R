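#' Exact minimum dominating set for a directed network
#'
#' Solves the covering integer program with one binary indicator \eqn{x_v}
#' per gene and one constraint per gene,
#' \deqn{\min \sum_v x_v \quad \mathrm{s.t.}\quad
#'       x_u + \sum_{v \in \delta^-(u)} x_v \ge 1 \;\; \forall u,}
#' where \eqn{\delta^-(u)} are the regulators of \eqn{u} (self-loops
#' excluded). A gene is dominated when it is selected or one of its
#' regulators is. The program is always feasible (the full node set
#' dominates); isolated genes and pure targets with no regulators are forced
#' into the solution by their own constraint, with no preprocessing.
#'
#' @param net a [regulatory_network()] (or a `network_component`).
#' @param time_limit optional wall-clock limit in seconds; when hit with an
#'   incumbent the result has `status = "feasible"`, otherwise an error of
#'   class `netdom_timeout` is thrown.
#' @param tf_only restrict candidate dominators to genes flagged `is_tf`
#'   (errors if that makes domination infeasible). Default `FALSE`: every
#'   gene is eligible.
#' @return a [dominating_set_result()]; all members have role `dominator`.
#' @examples
#' star <- regulatory_network(rep("hub", 4), paste0("t", 1:4))
#' solve_mds(star)$genes
#' @export
solve_mds <- function(net, time_limit = NULL, tf_only = FALSE) {
  if (inherits(net, "network_component")) net <- net$net
  stopifnot(inherits(net, "regulatory_network"))
  if (n_nodes(net) == 0)
    stop("cannot solve MDS on an empty network", call. = FALSE)
  model <- build_mds_model(net, tf_only = tf_only)
  ord <- order(-out_degrees(net), seq_len(n_nodes(net)))
  sol <- bip_solve(model, branch_order = ord, time_limit = time_limit)
  if (sol$status == "infeasible")
    stop(if (tf_only)
           "no dominating set exists with dominators restricted to TFs"
         else "internal error: MDS model reported infeasible",
         call. = FALSE)
  if (sol$status == "nosolution")
    stop(structure(class = c("netdom_timeout", "error", "condition"),
                   list(message = "MDS time limit hit before any incumbent",
                        call = NULL)))
  genes <- net$nodes[sol$solution == 1L]
  dominating_set_result(genes, rep("dominator", length(genes)),
                        method = "mds-ilp", status = sol$status,
                        meta = list(nodes_explored = sol$nodes,
                                    tf_only = tf_only))
}

# One variable per node, one covering row per node. With tf_only, non-TF
# indicators are clamped to zero (their own covering row may then force
# infeasibility, which solve_mds reports).
build_mds_model <- function(net, tf_only = FALSE) {
  n <- n_nodes(net)
  model <- bip_model(n)
  for (u in seq_len(n))
    model <- bip_add_row(model, cols = c(u, net$in_idx[[u]]),
                         coefs = rep(1, 1 + length(net$in_idx[[u]])),
                         lb = 1)
  if (tf_only) {
    non_tf <- which(!(net$is_tf %in% TRUE))
    for (v in non_tf)
      model <- bip_add_row(model, cols = v, coefs = 1, ub = 0)
  }
  model
}
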