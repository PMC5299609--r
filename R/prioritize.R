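## Candidate-regulator prioritization: cross-panel marker correlation,
## z-score summaries, correspondence analysis, Fisher term enrichment and
## evidence integration.

#' Per-TF Pearson correlation with a marker gene across a panel
#'
#' Computes, for every TF probe, the Pearson product-moment correlation of
#' its expression with the marker's across the panel samples, with a
#' correlation-test p-value adjusted (BH) across all TF probes.
#' Probe-level correlations are averaged to gene level after correlation.
#' Zero-variance probes get NA with a flag instead of an error.
#'
#' @param panel probes x samples expression matrix; probe names are either
#'   gene ids or "gene_p1", "gene_p2", ... for multi-probe genes.
#' @param marker marker gene id (e.g. "Ucp1"); multiple marker probes are
#'   averaged before correlating.
#' @param tfs optional TF gene ids to restrict to (default: all non-marker
#'   genes).
#' @return list with \code{probes} (probe-level data.frame: probe, gene, r,
#'   p, padj, meanExpr, flag) and \code{genes} (gene-level: gene, r,
#'   meanExpr).
#' @export
panelCorrelations <- function(panel, marker, tfs = NULL) {
    if (ncol(panel) < 3) stop("need at least 3 panel samples")
    probeGene <- sub("_p[0-9]+$", "", rownames(panel))
    mIdx <- which(probeGene == marker)
    if (!length(mIdx)) stop("marker '", marker, "' not in panel")
    mk <- colMeans(panel[mIdx, , drop = FALSE])
    keep <- probeGene != marker
    if (!is.null(tfs)) keep <- keep & probeGene %in% tfs
    probes <- rownames(panel)[keep]
    gene <- probeGene[keep]
    n <- ncol(panel)
    r <- p <- rep(NA_real_, length(probes))
    flag <- rep("", length(probes))
    for (i in seq_along(probes)) {
        x <- panel[probes[i], ]
        if (stats::sd(x) < 1e-12 || stats::sd(mk) < 1e-12) {
            flag[i] <- "zero_variance"
            next
        }
        r[i] <- stats::cor(x, mk)
        tt <- r[i] * sqrt((n - 2) / max(1e-12, 1 - r[i]^2))
        p[i] <- 2 * stats::pt(-abs(tt), df = n - 2)
    }
    padj <- rep(NA_real_, length(probes))
    ok <- !is.na(p)
    padj[ok] <- bhAdjust(p[ok])
    probeDf <- data.frame(probe = probes, gene = gene, r = r, p = p,
                          padj = padj, meanExpr = rowMeans(panel[probes, ,
                                                                 drop = FALSE]),
                          flag = flag, stringsAsFactors = FALSE)
    geneDf <- do.call(rbind, lapply(split(probeDf, probeDf$gene),
        function(d) data.frame(gene = d$gene[1],
                               r = mean(d$r, na.rm = TRUE),
                               meanExpr = mean(d$meanExpr),
                               stringsAsFactors = FALSE)))
    rownames(geneDf) <- NULL
    list(probes = probeDf, genes = geneDf)
}

#' Row-normalized z-score summary across panels
#'
#' Builds TF x panel matrices of mean expression and mean marker
#' correlation and z-scores each row across panels using the sample
#' standard deviation (n - 1).
#'
#' @param geneResults named list (one entry per panel) of gene-level
#'   data.frames from \code{\link{panelCorrelations}}.
#' @return list with matrices \code{zExpr} and \code{zR} (TFs x panels).
#' @export
zscoreSummary <- function(geneResults) {
    if (length(geneResults) < 2)
        stop("z-scores across panels need at least 2 panels")
    tfs <- Reduce(intersect, lapply(geneResults, function(d) d$gene))
    get <- function(col) vapply(geneResults, function(d)
        d[[col]][match(tfs, d$gene)], numeric(length(tfs)))
    zrow <- function(m) {
        sd_ <- apply(m, 1, stats::sd)
        z <- (m - rowMeans(m)) / ifelse(sd_ > 1e-12, sd_, Inf)
        rownames(z) <- tfs
        z
    }
    list(zExpr = zrow(get("meanExpr")), zR = zrow(get("r")))
}

#' Correspondence analysis of a non-negative table
#'
#' Chi-square-standardized residual decomposition by singular values: the
#' total inertia equals the Pearson chi-square statistic divided by the
#' grand total, and row/column principal coordinates place samples and
#' genes in a common low-dimensional space.
#'
#' @param x non-negative matrix with positive row and column margins.
#' @return list with \code{rowCoords}, \code{colCoords} (principal
#'   coordinates), \code{singularValues}, \code{inertia} (total) and
#'   \code{explained} (per-axis inertia fractions).
#' @export
correspondenceAnalysis <- function(x) {
    x <- as.matrix(x)
    if (any(x < 0)) stop("entries must be non-negative")
    rs <- rowSums(x); cs <- colSums(x)
    if (any(rs == 0))
        stop("zero row margin: ",
             paste(rownames(x)[rs == 0], collapse = ", "))
    if (any(cs == 0))
        stop("zero column margin: ",
             paste(colnames(x)[cs == 0], collapse = ", "))
    n <- sum(x)
    P <- x / n
    r <- rs / n; c <- cs / n
    S <- (P - outer(r, c)) / sqrt(outer(r, c))
    sv <- svd(S)
    k <- min(nrow(x), ncol(x)) - 1L
    d <- sv$d[seq_len(k)]
    F <- sweep(sv$u[, seq_len(k), drop = FALSE], 1, sqrt(r), "/") %*%
        diag(d, k)
    G <- sweep(sv$v[, seq_len(k), drop = FALSE], 1, sqrt(c), "/") %*%
        diag(d, k)
    dimnames(F) <- list(rownames(x), paste0("axis", seq_len(k)))
    dimnames(G) <- list(colnames(x), paste0("axis", seq_len(k)))
    inertia <- sum(sv$d^2)
    list(rowCoords = F, colCoords = G, singularValues = d,
         inertia = inertia,
         explained = if (inertia > 0) d^2 / inertia else rep(0, k))
}

#' Fisher exact term overrepresentation
#'
#' One-sided (overrepresentation) Fisher exact test of a gene set against
#' a gene universe for every annotation term.
#'
#' @param genes gene set (must be a subset of \code{universe}).
#' @param universe background gene universe.
#' @param termMap named list: term -> annotated genes.
#' @param alpha significance flag cutoff (default 0.01).
#' @return data.frame (term, inSet, inTerm, oddsRatio, p, significant),
#'   ordered by p.
#' @export
fisherTermEnrichment <- function(genes, universe, termMap, alpha = 0.01) {
    if (!all(genes %in% universe))
        stop("genes must be a subset of the universe")
    N <- length(universe); n <- length(genes)
    rows <- lapply(names(termMap), function(term) {
        tg <- intersect(termMap[[term]], universe)
        k <- length(intersect(genes, tg)); K <- length(tg)
        tab <- matrix(c(k, K - k, n - k, N - K - n + k), 2, 2)
        ft <- stats::fisher.test(tab, alternative = "greater")
        data.frame(term = term, inSet = k, inTerm = K,
                   oddsRatio = unname(ft$estimate), p = ft$p.value,
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    res$significant <- res$p < alpha
    res <- res[order(res$p, res$term), ]
    rownames(res) <- NULL
    res
}

#' Integrate evidence into a ranked candidate table
#'
#' Combines trend-cluster membership, cross-panel marker correlation and
#' motif enrichment into per-TF evidence flags and a transparent rank:
#' candidates are ordered by the number of satisfied flags, then by mean
#' panel correlation, then lexically. The composite is deliberately plain
#' bookkeeping — every underlying value is carried in the output.
#'
#' @param clusterTable data.frame with columns tf, cluster, membership.
#' @param panelGenes named list (per panel) of gene-level correlation
#'   data.frames from \code{\link{panelCorrelations}}.
#' @param motifTable data.frame with columns tf, regionClass ("pre" /
#'   "mature"), q — minimal motif q-value per TF and region class.
#' @param targetCluster the trend cluster of interest (default 1, the
#'   rising cluster).
#' @param membershipCutoff core-membership cutoff (default 0.5).
#' @param rThreshold per-panel correlation threshold (default 0.5).
#' @param qThreshold motif significance threshold (default 0.01).
#' @return data.frame with flags, flag count, meanR and rank (1 = top).
#' @export
integrateCandidates <- function(clusterTable, panelGenes, motifTable,
                                targetCluster = 1, membershipCutoff = 0.5,
                                rThreshold = 0.5, qThreshold = 0.01) {
    tfs <- sort(unique(clusterTable$tf))
    rmat <- vapply(panelGenes, function(d)
        d$r[match(tfs, d$gene)], numeric(length(tfs)))
    rmat <- matrix(rmat, nrow = length(tfs))
    meanR <- rowMeans(rmat, na.rm = TRUE)
    idx <- match(tfs, clusterTable$tf)
    inCluster <- clusterTable$cluster[idx] == targetCluster &
        clusterTable$membership[idx] >= membershipCutoff
    corAll <- apply(rmat >= rThreshold, 1, all)
    corAll[is.na(corAll)] <- FALSE
    qOf <- function(cls) {
        sub <- motifTable[motifTable$regionClass == cls, , drop = FALSE]
        sub$q[match(tfs, sub$tf)]
    }
    motifPre <- !is.na(qOf("pre")) & qOf("pre") < qThreshold
    motifMature <- !is.na(qOf("mature")) & qOf("mature") < qThreshold
    flags <- cbind(inCluster, corAll, motifPre, motifMature)
    nFlags <- rowSums(flags)
    ord <- order(-nFlags, -meanR, tfs)
    out <- data.frame(tf = tfs, inCluster = inCluster, corAll = corAll,
                      motifPre = motifPre, motifMature = motifMature,
                      nFlags = nFlags, meanR = meanR,
                      stringsAsFactors = FALSE)
    out <- out[ord, ]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
}
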