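#' Dominating-set results
#'
#' All solvers return a `dominating_set_result`: the selected genes with
#' per-gene roles (`dominator` for coverage, `connector` for members kept
#' only to hold the set together), the method that produced it, its
#' optimality status (`optimal`, `feasible`, or `timeout`), the component it
#' was computed on, and method-specific metadata (iteration counts, search
#' nodes, per-phase tallies).
#'
#' @param genes character vector of selected gene ids (component order).
#' @param roles character vector, same length, of `"dominator"`/`"connector"`.
#' @param method one of `"mds-ilp"`, `"mcds-ilp"`, `"mcds-heuristic"`,
#'   `"oracle"`.
#' @param status solver status string.
#' @param component_kind `"SCC"`, `"WCC"` or `NA`.
#' @param selection component-selection rationale (`"whole"|"lcc"|"lscc"`).
#' @param meta list of method-specific details.
#' @return object of class `dominating_set_result`.
#' @keywords internal
#' @export
dominating_set_result <- function(genes, roles, method, status,
                                  component_kind = NA_character_,
                                  selection = NA_character_, meta = list()) {
  stopifnot(length(genes) == length(roles),
            all(roles %in% c("dominator", "connector")))
  structure(list(genes = genes, roles = roles, size = length(genes),
                 method = method, status = status,
                 component_kind = component_kind, selection = selection,
                 meta = meta),
            class = "dominating_set_result")
}

#' @export
print.dominating_set_result <- function(x, ...) {
  cat(sprintf("%s solution: %d genes (%d dominators, %d connectors), status %s\n",
              x$method, x$size, sum(x$roles == "dominator"),
              sum(x$roles == "connector"), x$status))
  if (!is.na(x$component_kind))
    cat(sprintf("  component: %s (selection: %s)\n", x$component_kind,
                x$selection))
  cat("  genes:", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.dominating_set_result <- function(x, ...) {
  ord <- order(match(x$roles, c("dominator", "connector")),
               seq_along(x$genes))
  data.frame(gene = x$genes[ord], role = x$roles[ord], method = x$method,
             component_kind = rep(x$component_kind, length(x$genes)),
             stringsAsFactors = FALSE)
}

#' Jaccard index between two gene sets
#'
#' \eqn{|A \cap B| / |A \cup B|}; 1 for two empty sets.
#'
#' @param a,b character vectors.
#' @return numeric in \[0, 1\].
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}
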