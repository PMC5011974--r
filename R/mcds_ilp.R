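#' Exact minimum weakly-connected dominating set via cut generation
#'
#' The connected variant is modelled with binary node indicators \eqn{y_v}
#' and binary edge indicators \eqn{x_e} over the edges of the underlying
#' undirected graph (antiparallel arcs merged, self-loops dropped):
#' \deqn{\min \sum_v y_v} subject to
#' \itemize{
#'   \item \eqn{\sum_e x_e = \sum_i y_i - 1} (selected edges have spanning-
#'     tree cardinality),
#'   \item \eqn{y_u + \sum_{v \in \delta^-(u)} y_v \ge 1} for every node
#'     (directed domination),
#'   \item \eqn{x_e \le y_u,\; x_e \le y_v} for every edge \eqn{e=\{u,v\}}
#'     (an edge may only be selected between selected nodes),
#'   \item and, generated lazily, \eqn{\sum_{e \in E(S)} x_e \le
#'     \sum_{i \in S\setminus\{j\}} y_i} for vertex subsets \eqn{S} and
#'     \eqn{j \in S} (edges inside \eqn{S} must form a forest "rooted"
#'     outside \eqn{j}, which forbids disconnected selections).
#' }
#' The subset constraints are exponential in number, so the solver starts
#' without them, solves the relaxed 0/1 program, and checks whether the
#' selected nodes induce one connected piece of the underlying undirected
#' graph. If not, a cut is added for every connected component \eqn{S} of
#' the incumbent and every \eqn{j \in S}, and the strengthened program is
#' re-solved. Cuts accumulate across iterations; each iteration adds at
#' least one previously absent cut from a finite family, so the loop
#' terminates.
#'
#' @param x a weakly connected [regulatory_network()] or a
#'   `network_component` (see [select_component()]); disconnected input is
#'   an error directing the caller to component selection.
#' @param time_limit optional per-solve wall-clock limit in seconds.
#' @param max_iterations cap on cut-generation rounds (default 100); hitting
#'   it returns the best incumbent with `status = "timeout"`.
#' @return a [dominating_set_result()] with roles split into dominators and
#'   connectors (see Details) and metadata `iterations`, `n_cuts`,
#'   `nodes_explored`.
#'
#' @details A member is labelled `connector` when it is kept only for
#' connectivity: dropping it leaves the rest still dominating but breaks the
#' induced subgraph apart; every other member is a `dominator`.
#'
#' @examples
#' path <- regulatory_network(c("a", "b"), c("b", "c"))
#' solve_mcds_ilp(path)$genes   # a, b
#' @export
solve_mcds_ilp <- function(x, time_limit = NULL, max_iterations = 100) {
  comp <- as_connected_component(x)
  net <- comp$net
  n <- n_nodes(net)
  if (n == 1) {
    return(dominating_set_result(net$nodes, "dominator",
                                 method = "mcds-ilp", status = "optimal",
                                 component_kind = comp$kind,
                                 selection = comp$selection %||% NA_character_,
                                 meta = list(iterations = 0L, n_cuts = 0L,
                                             nodes_explored = 0)))
  }
  state <- mcds_ilp_state(net)
  incumbent <- NULL
  status <- "timeout"
  total_nodes <- 0
  repeat {
    if (state$iterations >= max_iterations) break
    state$iterations <- state$iterations + 1L
    sol <- bip_solve(state$model, branch_order = state$branch_order,
                     time_limit = time_limit)
    total_nodes <- total_nodes + sol$nodes
    if (sol$status %in% c("nosolution", "infeasible"))
      stop(structure(class = c("netdom_timeout", "error", "condition"),
                     list(message = paste0("MCDS solve stopped without an ",
                                           "incumbent (", sol$status, ")"),
                          call = NULL)))
    selected <- net$nodes[sol$solution[seq_len(n)] == 1L]
    incumbent <- selected
    pieces <- check_weak_connectivity(selected, state$ug)
    if (length(pieces) == 1) {
      status <- sol$status  # optimal, or feasible under a time limit
      break
    }
    state <- add_component_cuts(state, pieces)
  }
  roles <- split_roles_ilp(incumbent, net)
  dominating_set_result(incumbent, roles, method = "mcds-ilp",
                        status = status, component_kind = comp$kind,
                        selection = comp$selection %||% NA_character_,
                        meta = list(iterations = state$iterations,
                                    n_cuts = length(state$cut_keys),
                                    nodes_explored = total_nodes))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce solver input to a weakly connected component.
as_connected_component <- function(x) {
  if (inherits(x, "network_component")) {
    comp <- x
  } else if (inherits(x, "regulatory_network")) {
    if (n_nodes(x) == 0) stop("empty network", call. = FALSE)
    comp <- new_component(x, x$nodes, "WCC")
    comp$selection <- "whole"
  } else stop("expected a regulatory_network or network_component",
              call. = FALSE)
  if (length(check_weak_connectivity(comp$net$nodes,
                                     underlying_undirected(comp$net))) != 1)
    stop("input is not weakly connected; run select_component() (or pick ",
         "a component) first", call. = FALSE)
  comp
}

#' Constraint bookkeeping for the MCDS cut-generation loop
#'
#' Builds the initial 0/1 program: variables `y` (nodes, cost 1) then `x`
#' (undirected edges, cost 0); the spanning-tree cardinality equality, one
#' domination row per node, and the valid inequalities `x_e <= y_u`,
#' `x_e <= y_v`. Cuts are appended by [add_component_cuts()].
#'
#' @param net a weakly connected [regulatory_network()].
#' @return object of class `mcds_ilp_state`.
#' @keywords internal
#' @export
mcds_ilp_state <- function(net) {
  n <- n_nodes(net)
  ug <- underlying_undirected(net)
  m <- nrow(ug$edges)
  model <- bip_model(n + m, obj = c(rep(1, n), rep(0, m)))
  # sum_e x_e - sum_i y_i = -1
  model <- bip_add_row(model, cols = c(n + seq_len(m), seq_len(n)),
                       coefs = c(rep(1, m), rep(-1, n)), lb = -1, ub = -1)
  for (u in seq_len(n))
    model <- bip_add_row(model, cols = c(u, net$in_idx[[u]]),
                         coefs = rep(1, 1 + length(net$in_idx[[u]])), lb = 1)
  for (e in seq_len(m)) {
    model <- bip_add_row(model, cols = c(n + e, ug$edges[e, 1]),
                         coefs = c(1, -1), ub = 0)
    model <- bip_add_row(model, cols = c(n + e, ug$edges[e, 2]),
                         coefs = c(1, -1), ub = 0)
  }
  structure(list(net = net, ug = ug, model = model,
                 branch_order = c(order(-out_degrees(net),
                                        seq_len(n)), n + seq_len(m)),
                 iterations = 0L, cut_keys = character(0),
                 cut_log = data.frame(iteration = integer(0),
                                      set_size = integer(0),
                                      j = character(0),
                                      stringsAsFactors = FALSE)),
            class = "mcds_ilp_state")
}

#' @export
print.mcds_ilp_state <- function(x, ...) {
  cat(sprintf("mcds_ilp_state: %d y-vars, %d x-vars, %d rows (%d cuts), %d iterations\n",
              n_nodes(x$net), nrow(x$ug$edges), length(x$model$rows),
              length(x$cut_keys), x$iterations))
  invisible(x)
}

#' Connected pieces of a node selection in the underlying undirected graph
#'
#' Breadth-first search restricted to `selected`, used by the cut loop to
#' decide whether an incumbent is connected (hand-written so it can be
#' cross-checked against an independent implementation).
#'
#' @param selected nonempty character vector of node ids.
#' @param graph an [underlying_undirected()] graph containing them.
#' @return list of character vectors, the components of the induced
#'   subgraph, ordered by smallest node index.
#' @export
check_weak_connectivity <- function(selected, graph) {
  if (!length(selected)) stop("empty selection", call. = FALSE)
  idx <- match(selected, graph$nodes)
  if (anyNA(idx)) stop("selection contains unknown nodes", call. = FALSE)
  idx <- sort(idx)
  inset <- logical(length(graph$nodes))
  inset[idx] <- TRUE
  adj <- vector("list", length(graph$nodes))
  e <- graph$edges
  keep <- inset[e[, 1]] & inset[e[, 2]]
  for (r in which(keep)) {
    adj[[e[r, 1]]] <- c(adj[[e[r, 1]]], e[r, 2])
    adj[[e[r, 2]]] <- c(adj[[e[r, 2]]], e[r, 1])
  }
  seen <- logical(length(graph$nodes))
  out <- list()
  for (s in idx) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; comp <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    out[[length(out) + 1]] <- graph$nodes[sort(comp)]
  }
  out
}

#' Add connectivity cuts for a disconnected incumbent
#'
#' For every component `S` of the incumbent and every vertex `j` in `S`,
#' appends the constraint \eqn{\sum_{e \in E(S)} x_e \le
#' \sum_{i \in S\setminus\{j\}} y_i} to the pool (duplicates are skipped;
#' cuts are never dropped). Singleton components yield a vacuous but logged
#' cut — a defensive branch, since the tree-cardinality equality excludes
#' them for selections of two or more nodes.
#'
#' @param state an [mcds_ilp_state()].
#' @param components list of at least two node subsets (from
#'   [check_weak_connectivity()]).
#' @return the updated state.
#' @export
add_component_cuts <- function(state, components) {
  if (length(components) < 2)
    stop("cut generation requires >= 2 components; the loop should have ",
         "terminated", call. = FALSE)
  net <- state$net
  n <- n_nodes(net)
  e <- state$ug$edges
  for (S in components) {
    si <- sort(match(S, net$nodes))
    key_s <- paste(si, collapse = ",")
    inS <- logical(n); inS[si] <- TRUE
    es <- which(inS[e[, 1]] & inS[e[, 2]])  # E(S)
    for (j in si) {
      key <- paste0(key_s, "|", j)
      if (key %in% state$cut_keys) next
      others <- setdiff(si, j)
      cols <- c(n + es, others)
      coefs <- c(rep(1, length(es)), rep(-1, length(others)))
      # a singleton S has empty E(S) and empty S\{j}: the cut is vacuous
      # (0 <= 0) and is logged but not posted as a row
      if (length(cols))
        state$model <- bip_add_row(state$model, cols = cols, coefs = coefs,
                                   ub = 0)
      state$cut_keys <- c(state$cut_keys, key)
      state$cut_log <- rbind(state$cut_log,
                             data.frame(iteration = state$iterations,
                                        set_size = length(si),
                                        j = net$nodes[j],
                                        stringsAsFactors = FALSE))
    }
  }
  state
}

# Role split for ILP solutions: v is a connector iff the others still
# dominate but fall apart without it.
split_roles_ilp <- function(D, net) {
  if (length(D) <= 1) return(rep("dominator", length(D)))
  ug <- underlying_undirected(net)
  vapply(D, function(v) {
    rest <- setdiff(D, v)
    if (is_dominating_set(net, rest) &&
        length(check_weak_connectivity(rest, ug)) > 1)
      "connector" else "dominator"
  }, character(1))
}
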