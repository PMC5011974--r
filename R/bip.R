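# Thin R interface to the internal branch-and-bound 0/1 backend.
#
# A model is a list: n (variables), obj (costs >= 0), rows (list of
# list(cols, coefs, lb, ub)). Rows use 1-based column indices; senses are
# encoded through the [lb, ub] range (ub = Inf for ">=", lb = -Inf for
# "<=", lb = ub for "=").

bip_model <- function(n, obj = rep(1, n)) {
  stopifnot(length(obj) == n, all(obj >= 0))
  list(n = n, obj = as.numeric(obj), rows = list())
}

bip_add_row <- function(model, cols, coefs, lb = -Inf, ub = Inf) {
  stopifnot(length(cols) == length(coefs), all(cols >= 1),
            all(cols <= model$n))
  model$rows[[length(model$rows) + 1L]] <-
    list(cols = as.integer(cols), coefs = as.numeric(coefs),
         lb = as.numeric(lb), ub = as.numeric(ub))
  model
}

# branch_order: variable indices, most promising first. time_limit in
# seconds (NULL = none); node_limit caps search nodes (0 = none).
bip_solve <- function(model, branch_order = seq_len(model$n),
                      time_limit = NULL, node_limit = 0) {
  nr <- length(model$rows)
  rptr <- integer(nr + 1)
  cols <- integer(0); coefs <- numeric(0)
  rlb <- numeric(nr); rub <- numeric(nr)
  if (nr) {
    lens <- vapply(model$rows, function(r) length(r$cols), integer(1))
    rptr <- c(0L, cumsum(lens))
    cols <- unlist(lapply(model$rows, `[[`, "cols"), use.names = FALSE) - 1L
    coefs <- unlist(lapply(model$rows, `[[`, "coefs"), use.names = FALSE)
    rlb <- vapply(model$rows, `[[`, numeric(1), "lb")
    rub <- vapply(model$rows, `[[`, numeric(1), "ub")
  }
  res <- .bip_solve_cpp(model$n, model$obj, rptr, cols, coefs, rlb, rub,
                        as.integer(branch_order) - 1L,
                        if (is.null(time_limit)) -1 else as.numeric(time_limit),
                        as.numeric(node_limit))
  res
}
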