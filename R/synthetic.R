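#' Seeded generators for benchmark digraphs
#'
#' Every solver in the package is testable without external downloads via
#' seeded synthetic networks. Four models are provided:
#' \describe{
#'   \item{`erdos-renyi-np`}{each ordered pair `(u, v)`, `u != v`, becomes an
#'     arc independently with probability `p` — the classic random digraph
#'     used to benchmark solver scaling across sizes and densities.}
#'   \item{`erdos-renyi-nm`}{exactly `m` distinct arcs sampled uniformly.}
#'   \item{`tf-target-bipartite`}{`n_tf` regulators, `n - n_tf` targets;
#'     arcs only from TFs to targets (each pair with probability `p`), and
#'     every target is guaranteed at least one regulator — the shape of a
#'     curated TF-target GRN.}
#'   \item{`planted-hub`}{one hub with arcs to every other node plus noise
#'     arcs among the others with probability `p`; the known MDS/MCDS is the
#'     hub, giving fixtures with planted ground truth.}
#' }
#' Self-loops are never generated. All sampling runs under a local RNG
#' scoped to `seed` (the caller's random state is untouched), so the same
#' spec yields a byte-identical edge list.
#'
#' @param model one of the four model names.
#' @param n node count.
#' @param p arc probability (`erdos-renyi-np`, bipartite, hub noise).
#' @param m arc count (`erdos-renyi-nm`).
#' @param n_tf regulator count (`tf-target-bipartite`).
#' @param seed integer seed; required for reproducibility.
#' @return a [regulatory_network()] (bipartite model sets `is_tf`).
#' @examples
#' net <- generate_network("erdos-renyi-np", n = 20, p = 0.2, seed = 1)
#' n_arcs(net)
#' @export
generate_network <- function(model = c("erdos-renyi-np", "erdos-renyi-nm",
                                       "tf-target-bipartite", "planted-hub"),
                             n, p = NULL, m = NULL, n_tf = NULL, seed = 1L) {
  model <- match.arg(model)
  if (!is.numeric(n) || n < 1 || n != round(n))
    stop("n must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  if (model %in% c("erdos-renyi-np", "tf-target-bipartite", "planted-hub")) {
    if (model == "planted-hub" && is.null(p)) p <- 0.05
    if (is.null(p) || p < 0 || p > 1)
      stop("p must lie in [0, 1]", call. = FALSE)
  }
  if (model == "erdos-renyi-nm" &&
      (is.null(m) || m < 0 || m > n * (n - 1)))
    stop("m must lie in [0, n*(n-1)]", call. = FALSE)
  with_local_seed(seed, switch(model,
    "erdos-renyi-np" = gen_er_np(n, p),
    "erdos-renyi-nm" = gen_er_nm(n, as.integer(m)),
    "tf-target-bipartite" = gen_bipartite(n, p, n_tf),
    "planted-hub" = gen_planted_hub(n, p)))
}

# Run expr under set.seed(seed) without disturbing the caller's RNG.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# ordered node pairs in fixed row-major order (u, then v), no diagonal
ordered_pairs <- function(n) {
  u <- rep(seq_len(n), each = n - 1)
  v <- unlist(lapply(seq_len(n), function(i) seq_len(n)[-i]))
  cbind(u, v)
}

gen_er_np <- function(n, p) {
  ids <- sprintf("g%d", seq_len(n))
  pr <- ordered_pairs(n)
  keep <- runif(nrow(pr)) < p
  regulatory_network(ids[pr[keep, 1]], ids[pr[keep, 2]], nodes = ids)
}

gen_er_nm <- function(n, m) {
  ids <- sprintf("g%d", seq_len(n))
  pr <- ordered_pairs(n)
  pick <- sample.int(nrow(pr), m)
  pick <- sort(pick)
  regulatory_network(ids[pr[pick, 1]], ids[pr[pick, 2]], nodes = ids)
}

gen_bipartite <- function(n, p, n_tf) {
  if (is.null(n_tf) || n_tf < 1 || n_tf >= n)
    stop("tf-target-bipartite needs 1 <= n_tf < n", call. = FALSE)
  n_tf <- as.integer(n_tf)
  tfs <- sprintf("TF%d", seq_len(n_tf))
  tg <- sprintf("G%d", seq_len(n - n_tf))
  pairs <- expand.grid(tf = seq_len(n_tf), g = seq_along(tg))
  keep <- runif(nrow(pairs)) < p
  from <- tfs[pairs$tf[keep]]
  to <- tg[pairs$g[keep]]
  uncovered <- setdiff(tg, unique(to))
  if (length(uncovered)) {
    extra_tf <- tfs[sample.int(n_tf, length(uncovered), replace = TRUE)]
    from <- c(from, extra_tf)
    to <- c(to, uncovered)
  }
  tfflag <- c(rep(TRUE, n_tf), rep(FALSE, length(tg)))
  names(tfflag) <- c(tfs, tg)
  regulatory_network(from, to, nodes = c(tfs, tg), is_tf = tfflag)
}

gen_planted_hub <- function(n, p) {
  ids <- c("hub", sprintf("g%d", seq_len(n - 1)))
  from <- rep("hub", n - 1)
  to <- ids[-1]
  if (n > 2 && p > 0) {
    pr <- ordered_pairs(n - 1)  # noise among non-hub nodes only
    keep <- runif(nrow(pr)) < p
    from <- c(from, ids[-1][pr[keep, 1]])
    to <- c(to, ids[-1][pr[keep, 2]])
  }
  regulatory_network(from, to, nodes = ids)
}

#' Benchmark grid over sizes, densities, seeds and methods
#'
#' Generates one `erdos-renyi-np` digraph per (size, density, seed) triple
#' and runs each requested method: `"mds-ilp"` on the whole network,
#' `"mcds-ilp"` and `"mcds-heuristic"` on the component chosen by the
#' density rule. Returns a long-format table with solution size, status and
#' iteration count; when both MCDS methods run on an instance, the
#' heuristic row also carries the Jaccard overlap with the ILP solution.
#' Timed-out rows are flagged by their `status`, never dropped.
#'
#' @param sizes,densities,seeds numeric vectors defining the grid.
#' @param methods subset of `c("mds-ilp", "mcds-ilp", "mcds-heuristic")`.
#' @param time_limit per-solve limit in seconds (passed to the ILP routes).
#' @param max_iterations cut-generation cap for [solve_mcds_ilp()].
#' @return a data.frame, one row per instance and method.
#' @export
benchmark_grid <- function(sizes, densities, seeds,
                           methods = c("mds-ilp", "mcds-ilp",
                                       "mcds-heuristic"),
                           time_limit = NULL, max_iterations = 100) {
  stopifnot(all(methods %in% c("mds-ilp", "mcds-ilp", "mcds-heuristic")))
  rows <- list()
  for (n in sizes) for (p in densities) for (s in seeds) {
    net <- generate_network("erdos-renyi-np", n = n, p = p, seed = s)
    sols <- list()
    for (meth in methods) {
      t0 <- proc.time()[["elapsed"]]
      res <- tryCatch(switch(meth,
        "mds-ilp" = solve_mds(net, time_limit = time_limit),
        "mcds-ilp" = solve_mcds_ilp(resolve_component(net, "auto"),
                                    time_limit = time_limit,
                                    max_iterations = max_iterations),
        "mcds-heuristic" = run_heuristic(net)),
        netdom_timeout = function(e) NULL)
      elapsed <- proc.time()[["elapsed"]] - t0
      sols[[meth]] <- res
      rows[[length(rows) + 1]] <- data.frame(
        n = n, p = p, seed = s, method = meth,
        size = if (is.null(res)) NA_integer_ else res$size,
        status = if (is.null(res)) "timeout" else res$status,
        iterations = if (!is.null(res) && !is.null(res$meta$iterations))
          res$meta$iterations else NA_integer_,
        jaccard_vs_ilp = NA_real_, elapsed = elapsed,
        stringsAsFactors = FALSE)
    }
    if (!is.null(sols[["mcds-heuristic"]]) && !is.null(sols[["mcds-ilp"]])) {
      i <- length(rows) - match("mcds-heuristic", rev(methods)) + 1
      rows[[i]]$jaccard_vs_ilp <-
        jaccard_index(sols[["mcds-heuristic"]]$genes,
                      sols[["mcds-ilp"]]$genes)
    }
  }
  do.call(rbind, rows)
}
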