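# Exact set statistics used throughout the package: upper-tail
# hypergeometric probability computed in log space, Benjamini-Hochberg
# step-up adjustment, and generic gene-set / protein-complex
# over-representation testing.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` objects
#' without replacement from a universe of `N` containing `K` marked ones.
#' The tail is an exact sum of log-space terms (lgamma-based binomial
#' coefficients), numerically stable for large universes.
#'
#' @param k Observed overlap (success count).
#' @param K Marked objects in the universe.
#' @param n Draw (query) size.
#' @param N Universe size.
#' @return Probability in `(0, 1]`.
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > n || k > K)
    stopf("inconsistent hypergeometric parameters (k=%g K=%g n=%g N=%g)",
          k, K, n, N)
  if (k == 0) return(1)
  x <- k:min(K, n)
  lp <- lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
  m <- max(lp)
  min(1, exp(m + log(sum(exp(lp - m)))))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q(i) = min_{j >= i} (m * p_(j) / j)` on the sorted p-values, clipped at
#' 1 and returned in the input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]` (NA allowed; NA in,
#'   NA out).
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  if (any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvalues))
  m <- length(p)
  if (m) {
    o <- order(p, decreasing = TRUE)
    q <- pmin(1, cummin(m / (m:1) * p[o]))
    out[ok] <- q[order(o)]
  }
  out
}

#' Gene-set over-representation analysis
#'
#' One upper-tail hypergeometric test per term set against a query within a
#' universe, with BH adjustment across the tested terms.  Term sets are
#' intersected with the universe before testing and must retain at least
#' `min_term_size` members to be tested (e.g. `min_term_size = 6` restricts
#' a protein-complex compendium to large complexes of more than 5 members).
#'
#' @param query Character vector, subset of `universe`.
#' @param term_sets Named list of member vectors.
#' @param universe Character vector of all eligible ids.
#' @param min_term_size Minimum post-intersection term size.
#' @return data.frame sorted by `p` (ties by `term_id`): `term_id`, `k`
#'   (overlap), `K` (term size), `n` (query size), `N` (universe size),
#'   `p`, `fdr`.
#' @export
gene_set_enrichment <- function(query, term_sets, universe,
                                min_term_size = 1) {
  universe <- unique(universe)
  if (!length(universe)) stopf("empty universe")
  query <- unique(query)
  if (length(setdiff(query, universe)))
    stopf("query must be a subset of the universe")
  sets <- lapply(term_sets, function(s) intersect(unique(s), universe))
  keep <- lengths(sets) >= min_term_size
  sets <- sets[keep]
  N <- length(universe); n <- length(query)
  res <- data.frame(
    term_id = names(sets),
    k = vapply(sets, function(s) length(intersect(s, query)), 0L),
    K = lengths(sets), n = n, N = N,
    stringsAsFactors = FALSE, row.names = NULL
  )
  res$p <- mapply(hypergeometric_tail, res$k, res$K,
                  MoreArgs = list(n = n, N = N))
  if (nrow(res) == 0) res$p <- numeric(0)
  res$fdr <- bh_adjust(res$p)
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
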