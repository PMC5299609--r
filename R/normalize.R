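#' Filter features by expression level
#'
#' Two filtering rules used in the pipeline: \code{fpkm_all_timepoints}
#' removes genes whose FPKM falls below the threshold at any time point
#' (per-time-point FPKM is the mean over replicates), and
#' \code{cpm_min_samples} keeps features with counts-per-million above the
#' threshold in strictly more than \code{minSamples} samples.
#'
#' @param tc a \linkS4class{TimecourseCounts}.
#' @param mode "fpkm_all_timepoints" or "cpm_min_samples".
#' @param threshold FPKM or cpm threshold (default 1).
#' @param minSamples minimum sample count for cpm mode (default 20;
#'   "more than" is strict).
#' @param lengths named per-feature lengths in bp, required for FPKM mode.
#' @return Filtered \linkS4class{TimecourseCounts}; library sizes are kept
#'   from the input so downstream cpm stays on the original scale. The
#'   number of removed features is stored in
#'   \code{metadata(x)$filter_removed}.
#' @export
filterExpressed <- function(tc, mode = c("fpkm_all_timepoints",
                                         "cpm_min_samples"),
                            threshold = 1, minSamples = 20, lengths = NULL) {
    mode <- match.arg(mode)
    m <- counts(tc)
    lib <- libSizes(tc)
    if (mode == "fpkm_all_timepoints") {
        if (is.null(lengths)) stop("FPKM filtering requires feature lengths")
        miss <- setdiff(rownames(m), names(lengths))
        if (length(miss))
            stop("missing length for feature(s): ",
                 paste(miss, collapse = ", "))
        len <- lengths[rownames(m)]
        fpkm <- sweep(m, 2, lib, "/") * 1e9 / len
        tps <- unique(timepoints(tc))
        tpMean <- vapply(tps, function(tp)
            rowMeans(fpkm[, timepoints(tc) == tp, drop = FALSE]),
            numeric(nrow(m)))
        keep <- apply(tpMean >= threshold, 1, all)
    } else {
        cpm <- sweep(m, 2, lib, "/") * 1e6
        keep <- rowSums(cpm > threshold) > minSamples
    }
    out <- tc[keep, ]
    metadata(out)$filter_removed <- sum(!keep)
    out
}

#' Trimmed-mean-of-M-values scaling factors
#'
#' Computes per-sample library scaling factors by the TMM method: per-gene
#' log2 ratios (M) against a reference sample are doubly trimmed (on M and
#' on average log intensity A), then combined by a precision-weighted mean
#' with weights from the delta-method binomial variance of M. Factors are
#' rescaled to have geometric mean 1. The reference sample is the one whose
#' 75th count-percentile (relative to library size) is closest to the mean
#' across samples.
#'
#' @param x a \linkS4class{TimecourseCounts} or a count matrix.
#' @param logratioTrim fraction trimmed from each tail of M (default 0.30).
#' @param sumTrim fraction trimmed from each tail of A (default 0.05).
#' @param refColumn optional reference sample index.
#' @param libSize optional library sizes when \code{x} is a matrix.
#' @return Named numeric vector of scaling factors, geometric mean 1.
#' @export
tmmFactors <- function(x, logratioTrim = 0.30, sumTrim = 0.05,
                       refColumn = NULL, libSize = NULL) {
    if (methods::is(x, "TimecourseCounts")) {
        libSize <- libSizes(x)
        x <- counts(x)
    }
    x <- as.matrix(x)
    if (ncol(x) < 2) stop("need at least 2 samples")
    if (is.null(libSize)) libSize <- colSums(x)
    if (any(libSize == 0)) stop("all-zero sample column")
    if (is.null(refColumn)) {
        f75 <- apply(x, 2, stats::quantile, probs = 0.75) / libSize
        refColumn <- which.min(abs(f75 - mean(f75)))
    }
    ref <- x[, refColumn]
    nr <- libSize[refColumn]
    f <- vapply(seq_len(ncol(x)), function(j) {
        obs <- x[, j]; no <- libSize[j]
        ok <- obs > 0 & ref > 0
        if (!any(ok)) stop("sample ", j, " shares no expressed feature ",
                           "with the reference")
        o <- obs[ok]; r <- ref[ok]
        M <- log2((o / no) / (r / nr))
        A <- 0.5 * log2((o / no) * (r / nr))
        v <- (no - o) / (no * o) + (nr - r) / (nr * r)
        if (max(abs(M)) < 1e-6) return(1)
        n <- length(M)
        loM <- floor(n * logratioTrim) + 1; hiM <- n + 1 - loM
        loA <- floor(n * sumTrim) + 1; hiA <- n + 1 - loA
        rM <- rank(M); rA <- rank(A)
        keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
        if (!any(keep)) return(1)
        2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
    }, numeric(1))
    f <- f / exp(mean(log(f)))
    names(f) <- colnames(x)
    f
}

#' Log2 counts-per-million with moderated offset
#'
#' \code{log2((count + 0.5) / (effective library size + 1) * 1e6)} where the
#' effective library size is the raw size times the TMM factor.
#'
#' @param tc a \linkS4class{TimecourseCounts} or count matrix.
#' @param normFactors optional per-sample scaling factors (default 1).
#' @param libSize optional library sizes when \code{tc} is a matrix.
#' @return Numeric matrix of log2-cpm values.
#' @export
logCpm <- function(tc, normFactors = NULL, libSize = NULL) {
    if (methods::is(tc, "TimecourseCounts")) {
        libSize <- libSizes(tc)
        tc <- counts(tc)
    }
    if (is.null(libSize)) libSize <- colSums(tc)
    if (is.null(normFactors)) normFactors <- rep(1, ncol(tc))
    eff <- libSize * normFactors
    log2(sweep(tc + 0.5, 2, eff + 1, "/") * 1e6)
}

#' Condition-aware location/scale batch adjustment
#'
#' Removes additive per-feature batch effects while protecting the
#' biological condition: each feature is modelled as condition means plus
#' sum-to-zero batch offsets, the batch offsets are subtracted, and
#' residual spread within each batch is standardized toward the pooled
#' residual standard deviation. This is a deliberate simplification of
#' full empirical-Bayes batch correction: no cross-feature shrinkage of the
#' batch parameters is applied.
#'
#' @param mat numeric matrix (e.g. log2-cpm), features x samples.
#' @param batch per-sample batch labels (>= 2 batches of >= 2 samples each,
#'   unless a single batch is supplied, which is the identity transform).
#' @param condition per-sample biological condition labels (protected).
#' @return Adjusted matrix of the same dimensions.
#' @export
batchAdjust <- function(mat, batch, condition) {
    batch <- as.factor(batch)
    condition <- as.factor(condition)
    if (nlevels(batch) < 2) return(mat)
    if (any(table(batch) < 2))
        stop("each batch needs at least 2 samples")
    C <- stats::model.matrix(~ 0 + condition)
    old <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(old))
    B <- stats::model.matrix(~ batch)[, -1, drop = FALSE]
    X <- cbind(C, B)
    if (qr(X)$rank < ncol(X))
        stop("batch is confounded with condition; effects inestimable")
    XtXi <- solve(crossprod(X))
    coefs <- mat %*% X %*% XtXi            # features x (cond + batch) coefs
    bcols <- seq(ncol(C) + 1, ncol(X))
    adj <- mat - coefs[, bcols, drop = FALSE] %*% t(B)
    ## scale step: align within-batch residual sd to the pooled sd
    fitted_cond <- coefs[, seq_len(ncol(C)), drop = FALSE] %*% t(C)
    res <- adj - fitted_cond
    pooled <- sqrt(rowMeans(res^2))
    for (b in levels(batch)) {
        idx <- which(batch == b)
        sb <- sqrt(rowMeans(res[, idx, drop = FALSE]^2))
        fac <- ifelse(sb > 1e-12 & pooled > 1e-12, pooled / sb, 1)
        res[, idx] <- res[, idx, drop = FALSE] * fac
    }
    fitted_cond + res
}
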