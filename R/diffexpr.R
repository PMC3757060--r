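# Two-group differential expression with empirical-Bayes variance
# shrinkage. log2FC is always high minus low, so negative values mean
# down-regulated in the high group.

#' Keep the most variable features
#'
#' Retains \code{ceil(keep_fraction * n)} features of highest
#' across-sample variance; ties at the cut are broken by feature id
#' (lexicographically smaller kept) for determinism.
#'
#' @param expr an \code{\link{expressionMatrix}}.
#' @param keep_fraction fraction in (0, 1].
#' @return a filtered \code{ExpressionMatrix}.
#' @export
varianceFilter <- function(expr, keep_fraction = 0.75) {
    if (!nrow(expr$values)) stop("empty expression matrix")
    if (keep_fraction <= 0 || keep_fraction > 1)
        stop("keep_fraction must lie in (0,1]")
    v <- apply(expr$values, 1, stats::var)
    n_keep <- ceiling(keep_fraction * length(v))
    # order: variance descending, id ascending for ties
    o <- order(-v, rownames(expr$values))
    keep <- sort(o[seq_len(n_keep)])
    out <- expr
    out$values <- expr$values[keep, , drop = FALSE]
    logFilter("variance filter", nrow(expr$values), n_keep,
              sprintf("(keep %.0f%%)", 100 * keep_fraction))
    out
}

# trigamma inverse by Newton iteration (solves trigamma(y) = x)
trigammaInverse <- function(x) {
    vapply(x, function(xi) {
        if (!is.finite(xi) || xi <= 0) return(Inf)
        y <- 0.5 + 1 / xi
        for (i in 1:50) {
            tri <- trigamma(y)
            dif <- tri * (1 - tri / xi) / psigamma(y, 2)
            y <- y + dif
            if (abs(dif) < 1e-10 * y) break
        }
        y
    }, numeric(1))
}

#' Moderated two-sample t-test
#'
#' For each feature, computes log2FC = mean(high) - mean(low), a pooled
#' within-group variance s^2 on d residual degrees of freedom, shrinks it
#' toward a common prior via s~^2 = (d0 s0^2 + d s^2) / (d0 + d) with
#' (d0, s0^2) estimated from the marginal distribution of s^2 across
#' features by moment matching on log s^2 (digamma/trigamma), and reports a
#' moderated t on d0 + d degrees of freedom with a two-sided p-value. With a
#' single feature no moderation is possible and the ordinary two-sample
#' pooled t is used (d0 = 0); if the moment estimate of d0 is infinite the
#' shrunken variance equals s0^2.
#'
#' @param expr an \code{\link{expressionMatrix}} with both groups >= 2
#'   samples.
#' @return a \code{data.frame} (one row per feature) with columns
#'   \code{feature}, \code{log2fc}, \code{t}, \code{p}, \code{fdr},
#'   \code{direction}, \code{mean_high}, \code{mean_low}.
#' @export
moderatedT <- function(expr) {
    vals <- expr$values
    hi <- expr$groups == "high"
    lo <- expr$groups == "low"
    n1 <- sum(hi); n2 <- sum(lo)
    if (n1 < 2 || n2 < 2) stop("each group needs >=2 samples")
    mean_high <- rowMeans(vals[, hi, drop = FALSE])
    mean_low <- rowMeans(vals[, lo, drop = FALSE])
    lfc <- mean_high - mean_low
    ss1 <- rowSums((vals[, hi, drop = FALSE] - mean_high)^2)
    ss2 <- rowSums((vals[, lo, drop = FALSE] - mean_low)^2)
    d <- n1 + n2 - 2
    s2 <- (ss1 + ss2) / d

    m <- length(s2)
    pos <- s2 > 0
    if (m >= 2 && sum(pos) >= 2) {
        # moment matching on z = log s^2: E z = log s0^2 + digamma(d0/2)
        # - log(d0/2) + digamma(d/2) - log(d/2) reversed for the F mixture;
        # var z = trigamma(d/2) + trigamma(d0/2)
        z <- log(s2[pos])
        e <- z - digamma(d / 2) + log(d / 2)
        ebar <- mean(e)
        vexcess <- stats::var(e) - trigamma(d / 2)
        if (is.finite(vexcess) && vexcess > 0) {
            d0 <- 2 * trigammaInverse(vexcess)
            s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
        } else {
            d0 <- Inf
            s02 <- exp(ebar)
        }
    } else {
        d0 <- 0
        s02 <- NA_real_
    }

    if (is.infinite(d0)) {
        s2_tilde <- rep(s02, m)
    } else if (d0 > 0) {
        s2_tilde <- (d0 * s02 + d * s2) / (d0 + d)
    } else {
        s2_tilde <- s2
    }
    df_total <- if (is.infinite(d0)) Inf else d0 + d
    se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
    tstat <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
    p <- if (is.finite(df_total))
        ifelse(is.finite(tstat), 2 * stats::pt(-abs(tstat), df = df_total), 0)
    else
        ifelse(is.finite(tstat), 2 * stats::pnorm(-abs(tstat)), 0)
    p[se == 0 & lfc == 0] <- 1
    data.frame(
        feature = rownames(vals),
        log2fc = unname(lfc),
        t = unname(tstat),
        p = unname(p),
        fdr = bhFdr(unname(p)),
        direction = ifelse(lfc >= 0, "up", "down"),
        mean_high = unname(mean_high),
        mean_low = unname(mean_low),
        stringsAsFactors = FALSE
    )
}

#' Filter a differential-expression table
#'
#' Applies the printed operators: strict \code{<} on the p-quantity and
#' inclusive \code{>=} on |log2FC|.
#'
#' @param de a \code{\link{moderatedT}} table.
#' @param p_kind \code{"fdr"} or \code{"raw"}.
#' @param p_max strict upper bound on the chosen p-quantity.
#' @param abs_lfc_min inclusive lower bound on |log2FC|.
#' @return the retained subset, same columns.
#' @export
filterDE <- function(de, p_kind = c("fdr", "raw"), p_max, abs_lfc_min) {
    p_kind <- match.arg(p_kind)
    stopifnot(p_max > 0, abs_lfc_min > 0)
    pq <- if (p_kind == "fdr") de$fdr else de$p
    keep <- pq < p_max & abs(de$log2fc) >= abs_lfc_min
    out <- de[keep, , drop = FALSE]
    logFilter(sprintf("DE filter (%s<%g, |lfc|>=%g)", p_kind, p_max,
                      abs_lfc_min), nrow(de), nrow(out))
    rownames(out) <- NULL
    out
}
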