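# Fuzzy clustering directly on a dissimilarity matrix (FANNY), with the
# Dunn partition coefficient and Dunn separation index used for model
# selection over a fuzziness/cluster-number grid.

fannyObjective <- function(U, d, r) {
    Ur <- U^r
    sum(vapply(seq_len(ncol(U)), function(v) {
        uv <- Ur[, v]
        (uv %*% d %*% uv) / (2 * sum(uv))
    }, numeric(1)))
}

fannyIterate <- function(U, d, r, max_iter = 500, tol = 1e-9) {
    n <- nrow(U); k <- ncol(U)
    obj <- fannyObjective(U, d, r)
    for (it in seq_len(max_iter)) {
        Ur <- U^r
        Bv <- colSums(Ur)                       # = B_v / 2
        E <- matrix(0, n, k)
        for (v in seq_len(k)) {
            uv <- Ur[, v]
            num <- as.numeric(d %*% uv)         # sum_j u_jv^r d_ij
            Av <- sum(uv * num) / 2
            E[, v] <- num / (2 * Bv[v]) - Av / (2 * Bv[v]^2)
        }
        Unew <- matrix(0, n, k)
        for (i in seq_len(n)) {
            e <- E[i, ]
            if (any(e <= 1e-12)) {
                # moving fully into the most attractive cluster only helps
                Unew[i, which.min(e)] <- 1
            } else {
                # log-space keeps small fuzziness exponents finite
                lw <- -log(e) / (r - 1)
                w <- exp(lw - max(lw))
                Unew[i, ] <- w / sum(w)
            }
        }
        obj_new <- fannyObjective(Unew, d, r)
        if (obj_new > obj + 1e-12) break        # monotonicity safeguard
        delta <- (obj - obj_new) / max(obj, .Machine$double.eps)
        U <- Unew; obj <- obj_new
        if (delta < tol) break
    }
    list(U = U, objective = obj)
}

farthestPointSeeds <- function(d, k) {
    n <- nrow(d)
    seeds <- which.max(rowSums(d))
    while (length(seeds) < k) {
        md <- apply(d[, seeds, drop = FALSE], 1, min)
        md[seeds] <- -1
        seeds <- c(seeds, which.max(md))
    }
    seeds
}

initMembership <- function(d, k, r, seeds) {
    n <- nrow(d)
    U <- matrix(0, n, k)
    expo <- 1 / (r - 1)
    for (i in seq_len(n)) {
        di <- d[i, seeds] + 1e-6
        w <- (1 / di)^pmin(expo, 50)
        U[i, ] <- w / sum(w)
    }
    U
}

#' FANNY fuzzy clustering on a dissimilarity matrix
#'
#' Minimizes the FANNY objective
#' \deqn{\sum_v \frac{\sum_{i,j} u_{iv}^r u_{jv}^r d_{ij}}{2 \sum_j u_{jv}^r}}
#' by iterative membership updates (objective non-increasing by
#' construction; iteration stops at relative change < 1e-9 or 500
#' iterations). The first start is deterministic (farthest-point seeding
#' from the dissimilarity matrix); further random restarts are controlled
#' by \code{seed} and the best objective is kept.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal.
#' @param k number of clusters (2 <= k < n).
#' @param r fuzziness exponent (> 1).
#' @param seed integer seed for the random restarts.
#' @param restarts total number of starts (first is deterministic).
#' @return a \linkS4class{FuzzyClustering}.
#' @export
fannyClust <- function(d, k, r = 1.1, seed = 1, restarts = 5) {
    d <- as.matrix(d)
    n <- nrow(d)
    if (k < 2) stop("k must be >= 2")
    if (k >= n) stop("k must be smaller than the number of items")
    if (r <= 1) stop("fuzziness exponent r must be > 1")
    if (any(abs(d - t(d)) > 1e-8) || any(diag(d) != 0))
        stop("d must be symmetric with zero diagonal")
    best <- NULL
    old <- .Random.seed.save(); on.exit(.Random.seed.restore(old))
    for (s in seq_len(restarts)) {
        if (s == 1) {
            U0 <- initMembership(d, k, r, farthestPointSeeds(d, k))
        } else {
            set.seed(subSeed(seed, s))
            U0 <- matrix(stats::runif(n * k), n, k)
            U0 <- U0 / rowSums(U0)
        }
        fit <- fannyIterate(U0, d, r)
        if (is.null(best) || fit$objective < best$objective) best <- fit
    }
    U <- best$U
    rownames(U) <- rownames(d)
    labels <- apply(U, 1, which.max)
    fc <- dunnCoefficient(U)
    di <- tryCatch(dunnIndex(labels, d), error = function(e) NA_real_)
    new("FuzzyClustering", membership = U, fuzziness = r, k = k,
        dunn_coeff = fc[["fc"]], dunn_coeff_norm = fc[["fc_norm"]],
        dunn_index = di, labels = as.integer(labels),
        strength = apply(U, 1, max), objective = best$objective)
}

#' Dunn partition coefficient
#'
#' Fc = mean of squared membership rows (1 for a crisp partition, 1/k for a
#' maximally fuzzy one) and its normalization Fc' = (k Fc - 1) / (k - 1).
#'
#' @param U membership matrix (rows sum to 1).
#' @return named vector \code{c(fc=..., fc_norm=...)}.
#' @export
dunnCoefficient <- function(U) {
    k <- ncol(U)
    if (k < 2) stop("Dunn coefficient needs k >= 2")
    fc <- mean(rowSums(U^2))
    c(fc = fc, fc_norm = (k * fc - 1) / (k - 1))
}

#' Dunn separation index
#'
#' Minimum between-cluster dissimilarity divided by the maximum
#' within-cluster diameter. Values > 1 indicate well-separated clusters.
#' If every cluster is a singleton (all diameters zero) the index is
#' +Inf when clusters are separated and an error when items coincide.
#'
#' @param labels integer cluster labels (>= 2 non-empty clusters).
#' @param d dissimilarity matrix.
#' @return the Dunn index.
#' @export
dunnIndex <- function(labels, d) {
    d <- as.matrix(d)
    cl <- sort(unique(labels))
    if (length(cl) < 2) stop("Dunn index needs >= 2 non-empty clusters")
    diam <- vapply(cl, function(v) {
        ix <- which(labels == v)
        if (length(ix) < 2) 0 else max(d[ix, ix])
    }, numeric(1))
    sep <- Inf
    for (a in seq_along(cl)) for (b in seq_along(cl)) {
        if (a < b) {
            ia <- which(labels == cl[a]); ib <- which(labels == cl[b])
            sep <- min(sep, min(d[ia, ib]))
        }
    }
    if (max(diam) == 0) {
        if (sep == 0) stop("degenerate clustering: identical items split")
        return(Inf)
    }
    sep / max(diam)
}

#' Select fuzziness and cluster number over a grid
#'
#' Runs \code{\link{fannyClust}} for every (r, k) combination. The selected
#' fuzziness r* is the smallest r whose normalized Dunn coefficient exceeds
#' 0.5 for every k in the grid (falling back to the largest r with a
#' warning when none qualifies); the cluster number k* maximizes the Dunn
#' index at r*. A warning is raised when no k reaches a Dunn index > 1.
#'
#' @param d dissimilarity matrix.
#' @param r_grid candidate fuzziness exponents.
#' @param k_grid candidate cluster numbers.
#' @param seed integer seed passed to \code{\link{fannyClust}}.
#' @return list with \code{r_star}, \code{k_star}, \code{clustering} (the
#'   fit at (r*, k*)) and \code{diagnostics} (one row per grid point:
#'   r, k, fc, fc_norm, dunn_index; NA where k >= n).
#' @export
selectParameters <- function(d, r_grid = seq(1.1, 1.5, by = 0.1),
                             k_grid = 2:15, seed = 1) {
    if (!length(r_grid) || !length(k_grid)) stop("grids must be non-empty")
    n <- nrow(as.matrix(d))
    rows <- list()
    fits <- list()
    for (r in r_grid) for (k in k_grid) {
        if (k >= n) {
            rows[[length(rows) + 1]] <- data.frame(
                r = r, k = k, fc = NA_real_, fc_norm = NA_real_,
                dunn_index = NA_real_)
            next
        }
        fit <- fannyClust(d, k = k, r = r, seed = seed)
        fits[[paste(r, k)]] <- fit
        rows[[length(rows) + 1]] <- data.frame(
            r = r, k = k, fc = fit@dunn_coeff,
            fc_norm = fit@dunn_coeff_norm, dunn_index = fit@dunn_index)
    }
    diag_tab <- do.call(rbind, rows)
    ok_k <- k_grid[k_grid < n]
    qualifies <- vapply(r_grid, function(r) {
        sub <- diag_tab[diag_tab$r == r & diag_tab$k %in% ok_k, ]
        nrow(sub) > 0 && all(sub$fc_norm > 0.5)
    }, logical(1))
    if (any(qualifies)) {
        r_star <- min(r_grid[qualifies])
    } else {
        r_star <- max(r_grid)
        warning("no fuzziness value keeps the normalized Dunn coefficient ",
                "above 0.5 for all cluster numbers; using r = ", r_star)
    }
    sub <- diag_tab[diag_tab$r == r_star & diag_tab$k %in% ok_k, ]
    k_star <- sub$k[which.max(sub$dunn_index)]
    if (all(is.na(sub$dunn_index)) || max(sub$dunn_index, na.rm = TRUE) <= 1)
        warning("no cluster number reaches a Dunn index > 1; ",
                "the clustering structure is weak")
    list(r_star = r_star, k_star = k_star,
         clustering = fits[[paste(r_star, k_star)]],
         diagnostics = diag_tab)
}
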