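#' Hypergeometric enrichment test
#'
#' Tail probability of the observed overlap between a result set (e.g. an
#' MCDS) and an annotated gene class, under sampling without replacement:
#' from a network of `M` genes of which `k` carry the annotation, a sample
#' of size `N` is drawn and `x` annotated genes are observed.
#'
#' Two tail conventions are offered. The default, `"inclusive"`, is the
#' upper tail including the observation, \eqn{P(X \ge x) = 1 -
#' \sum_{i=0}^{x-1} \binom{k}{i}\binom{M-k}{N-i}/\binom{M}{N}} — the usual
#' enrichment p-value (the probability of an overlap at least as large as
#' observed). `"strict"` is the literal exclusive tail \eqn{P(X > x) = 1 -
#' \sum_{i=0}^{x}}, one term smaller. The computation uses the log-space
#' hypergeometric CDF and is clamped to \[0, 1\].
#'
#' @param M population size (genes in the network).
#' @param k annotated genes in the population.
#' @param N sample size (e.g. the MCDS size).
#' @param x annotated genes observed in the sample.
#' @param convention `"inclusive"` (default) or `"strict"`; see Details.
#' @return the p-value, a number in \[0, 1\].
#' @examples
#' hypergeom_pvalue(M = 176, k = 15, N = 29, x = 7)   # ~0.004
#' @export
hypergeom_pvalue <- function(M, k, N, x,
                             convention = c("inclusive", "strict")) {
  convention <- match.arg(convention)
  check_hypergeom_counts(M, k, N, x)
  q <- if (convention == "inclusive") x - 1 else x
  p <- phyper(q, m = k, n = M - k, k = N, lower.tail = FALSE)
  min(max(p, 0), 1)
}

check_hypergeom_counts <- function(M, k, N, x) {
  ok <- function(v) length(v) == 1 && is.finite(v) && v == round(v)
  if (!ok(M) || !ok(k) || !ok(N) || !ok(x))
    stop("M, k, N, x must be single integers", call. = FALSE)
  if (M < 0 || k < 0 || N < 0 || x < 0 || k > M || N > M || x > min(N, k))
    stop("invalid counts: need 0 <= x <= min(N, k), N <= M, k <= M",
         call. = FALSE)
  invisible(TRUE)
}

#' Benjamini-Hochberg adjustment
#'
#' False-discovery-rate adjustment of a p-value vector (step-up procedure),
#' for reporting several enrichment tests together.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")
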