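# shared numerical helpers and structured filter logging

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(population N, successes K, draws n).
#' The convention used by every enrichment and motif test in the package.
#'
#' @param k observed success count in the draw.
#' @param K successes in the population.
#' @param N population size.
#' @param n draw size.
#' @return P(X >= k), exactly 1 when \code{k <= 0}.
#' @examples
#' hyperUpperTail(3, K = 4, N = 10, n = 5)  # 66/252
#' @export
hyperUpperTail <- function(k, K, N, n) {
    if (any(K > N) || any(n > N)) stop("K and n cannot exceed N")
    if (any(k > pmin(K, n))) stop("k exceeds min(K, n): invariant breach")
    stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, input order preserved, values clipped at 1.
#'
#' @param pvals numeric vector of p-values in [0,1].
#' @return adjusted p-values, same length and order.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.5))
#' @export
bhFdr <- function(pvals) {
    if (!length(pvals)) return(numeric(0))
    if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
        stop("p-values must lie in [0,1]")
    stats::p.adjust(pvals, method = "BH")
}

# one structured line per filter, mirroring before/after counts
logFilter <- function(stage, before, after, detail = "") {
    message(sprintf("[coregFFL] %-28s %6d -> %6d %s",
                    stage, before, after, detail))
    invisible(after)
}

# deterministic child RNG streams: derive a 31-bit sub-seed
subSeed <- function(seed, offset) {
    as.integer((as.numeric(seed) * 48271 + offset * 9973) %% 2147483647L)
}
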