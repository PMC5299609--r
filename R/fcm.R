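#' Standardize temporal expression profiles
#'
#' Collapses replicates to per-time-point means and standardizes each gene's
#' profile to mean 0, standard deviation 1. Genes with (near) zero temporal
#' variance cannot be standardized; they are excluded and reported via the
#' \code{"excluded"} attribute rather than raising an error.
#'
#' @param y expression matrix (genes x samples), e.g. log2-cpm.
#' @param timepoint per-sample time point labels.
#' @param levels time point ordering (default: order of first appearance).
#' @return genes x T standardized profile matrix with attribute
#'   \code{excluded} (character vector of flagged genes).
#' @export
standardizeProfiles <- function(y, timepoint, levels = unique(timepoint)) {
    if (length(levels) < 2) stop("need at least 2 time points")
    prof <- vapply(levels, function(tp)
        rowMeans(y[, timepoint == tp, drop = FALSE]), numeric(nrow(y)))
    rownames(prof) <- rownames(y)
    mu <- rowMeans(prof)
    sd_ <- apply(prof, 1, stats::sd)
    keep <- sd_ > 1e-12
    z <- (prof[keep, , drop = FALSE] - mu[keep]) / sd_[keep]
    attr(z, "excluded") <- rownames(prof)[!keep]
    z
}

## Deterministic maximin (farthest-point) seeding: the first centroid is the
## profile farthest from the grand mean, each next one maximizes its minimal
## distance to the chosen set. Depends only on the data values, so permuting
## gene order permutes nothing but row order of the output.
.fcmInit <- function(x, c) {
    d2all <- function(v) colSums((t(x) - v)^2)
    chosen <- matrix(0, c, ncol(x))
    first <- which.max(d2all(colMeans(x)))
    chosen[1, ] <- x[first, ]
    if (c > 1) {
        mind <- d2all(chosen[1, ])
        for (k in 2:c) {
            nxt <- which.max(mind)
            chosen[k, ] <- x[nxt, ]
            mind <- pmin(mind, d2all(chosen[k, ]))
        }
    }
    chosen
}

.fcmMembership <- function(d2, m) {
    n <- nrow(d2); c <- ncol(d2)
    u <- matrix(0, n, c)
    zero <- d2 < 1e-12
    hasZero <- rowSums(zero) > 0
    if (any(hasZero))                       # tie-break: equal split
        u[hasZero, ] <- zero[hasZero, , drop = FALSE] /
            rowSums(zero[hasZero, , drop = FALSE])
    if (any(!hasZero)) {
        w <- d2[!hasZero, , drop = FALSE]^(-1 / (m - 1))
        u[!hasZero, ] <- w / rowSums(w)
    }
    u
}

#' Fit fuzzy c-means clusters
#'
#' Minimizes J = sum_i sum_j u_ij^m ||x_i - v_j||^2 by alternating
#' membership and centroid updates (u_ij proportional to
#' d_ij^(-2/(m-1)); v_j the u^m-weighted mean) until the objective change
#' drops below \code{tol}. Initialization is a deterministic farthest-point
#' scheme, so repeated fits are identical. The objective is checked to be
#' non-increasing at every iteration. Points coinciding with several
#' centroids receive equal membership among the tied centroids.
#'
#' @param x profiles matrix (genes x T), typically standardized.
#' @param centers number of clusters c (>= 2, <= number of rows).
#' @param m fuzzifier (> 1); default 2.057216.
#' @param tol convergence tolerance on the objective.
#' @param maxIter maximal iterations.
#' @param seed accepted for interface stability; the fit is deterministic.
#' @return A \linkS4class{FuzzyClustering}.
#' @examples
#' x <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 5), 20, 2))
#' fit <- fcmFit(x, centers = 2, m = 2)
#' table(clusterAssignments(fit))
#' @export
fcmFit <- function(x, centers, m = 2.057216, tol = 1e-9, maxIter = 500,
                   seed = NULL) {
    x <- as.matrix(x)
    if (m <= 1) stop("fuzzifier m must exceed 1")
    if (centers < 1 || centers > nrow(x))
        stop("centers must lie between 1 and the number of profiles")
    v <- .fcmInit(x, centers)
    Jtrace <- numeric(0)
    for (it in seq_len(maxIter)) {
        d2 <- outer(rowSums(x^2), rowSums(v^2), "+") - 2 * x %*% t(v)
        d2 <- pmax(d2, 0)
        u <- .fcmMembership(d2, m)
        J <- sum(u^m * d2)
        if (length(Jtrace) && J > utils::tail(Jtrace, 1) + 1e-8)
            stop("internal error: objective increased")
        Jtrace <- c(Jtrace, J)
        if (length(Jtrace) > 1 &&
            abs(Jtrace[length(Jtrace) - 1] - J) < tol) break
        um <- u^m
        v <- crossprod(um, x) / colSums(um)
    }
    rownames(u) <- rownames(x)
    dm <- if (centers > 1) min(stats::dist(v)) else Inf
    new("FuzzyClustering", centroids = unname(v), membership = u,
        m = m, objective = Jtrace, dmin = dm)
}

#' Scan cluster numbers with the Dmin validity index
#'
#' Fits fuzzy c-means over a grid of cluster counts and reports the minimum
#' pairwise centroid distance (Dmin) for each; a sharp drop in Dmin past the
#' true structure size marks the elbow. The choice of c remains with the
#' analyst.
#'
#' @param x profiles matrix.
#' @param cRange integer vector of cluster counts to test.
#' @param m fuzzifier.
#' @param ... passed to \code{\link{fcmFit}}.
#' @return data.frame with columns c, dmin, objective.
#' @export
scanClusterNumbers <- function(x, cRange = 2:8, m = 2.057216, ...) {
    rows <- lapply(cRange, function(c) {
        fit <- fcmFit(x, centers = c, m = m, ...)
        data.frame(c = c, dmin = dmin(fit),
                   objective = utils::tail(fit@objective, 1))
    })
    do.call(rbind, rows)
}

#' Core cluster members at a membership cutoff
#'
#' Genes whose maximal membership reaches the cutoff are assigned to their
#' argmax cluster ("core"); the remainder are reported as peripheral.
#'
#' @param fc a \linkS4class{FuzzyClustering}.
#' @param cutoff membership threshold in [0, 1] (default 0.5).
#' @return list with per-cluster core gene vectors (\code{clusters}) and
#'   the \code{peripheral} genes.
#' @export
coreMembers <- function(fc, cutoff = 0.5) {
    u <- membership(fc)
    top <- apply(u, 1, max)
    a <- clusterAssignments(fc)
    core <- top >= cutoff
    clusters <- lapply(seq_len(ncol(u)), function(j)
        rownames(u)[core & a == j])
    names(clusters) <- paste0("cluster", seq_len(ncol(u)))
    list(clusters = clusters, peripheral = rownames(u)[!core])
}
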