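## Precision-weighted moderated differential testing. The mean-variance
## trend weighting and the empirical-Bayes variance moderation are authored
## here; they follow the standard scaled-inverse-chi-square formulation with
## hyperparameters obtained by moment matching on the log residual
## variances.

#' Benjamini-Hochberg adjusted p-values
#'
#' Validating front-end for the step-up false discovery rate adjustment.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order as \code{p}.
#' @export
bhAdjust <- function(p) {
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Design matrix over time points
#'
#' One-hot (means) parameterization: one column per time point.
#'
#' @param timepoint per-sample time point labels.
#' @param levels optional ordering of the time points.
#' @return Design matrix with one column per time point.
#' @export
timepointDesign <- function(timepoint, levels = unique(timepoint)) {
    f <- factor(timepoint, levels = levels)
    d <- stats::model.matrix(~ 0 + f)
    colnames(d) <- levels
    d
}

#' Contrast vectors for time-point comparisons
#'
#' \code{oneVsRestContrast} contrasts one time point against the mean of all
#' others ("enriched at one time point relative to all the others");
#' \code{pairwiseContrast} contrasts two time points directly.
#'
#' @param levels time point labels in design-column order.
#' @param tp,tpA,tpB time point(s) to contrast.
#' @return Named numeric contrast vector over the design columns.
#' @export
oneVsRestContrast <- function(levels, tp) {
    ct <- stats::setNames(rep(-1 / (length(levels) - 1), length(levels)),
                          levels)
    ct[tp] <- 1
    ct
}

#' @rdname oneVsRestContrast
#' @export
pairwiseContrast <- function(levels, tpA, tpB) {
    ct <- stats::setNames(rep(0, length(levels)), levels)
    ct[tpA] <- 1
    ct[tpB] <- -1
    ct
}

#' Mean-variance trend precision weights
#'
#' Fits per-feature linear models on log2-cpm, smooths the square-root
#' residual standard deviation against average log2 count with a locally
#' weighted regression (tricube weights, default span 0.5, 2 robustness
#' iterations) and returns per-observation weights equal to the inverse
#' fourth power of the trend predicted at each observation's fitted log2
#' count.
#'
#' @param tc a \linkS4class{TimecourseCounts}.
#' @param design design matrix (samples x coefficients).
#' @param normFactors optional TMM factors.
#' @param span lowess span.
#' @param iterations lowess robustness iterations.
#' @return list with \code{logCpm}, \code{weights} (both features x
#'   samples) and \code{trend} (the smoothed curve, for QC plots).
#' @export
precisionWeights <- function(tc, design, normFactors = NULL,
                             span = 0.5, iterations = 2) {
    m <- counts(tc)
    if (nrow(m) < 2) stop("mean-variance trend needs at least 2 features")
    if (ncol(m) < ncol(design) + 1)
        stop("fewer samples than residual degrees of freedom require")
    lib <- libSizes(tc)
    if (is.null(normFactors)) normFactors <- rep(1, ncol(m))
    eff <- lib * normFactors
    y <- log2(sweep(m + 0.5, 2, eff + 1, "/") * 1e6)
    X <- design
    H <- X %*% solve(crossprod(X))
    coefs <- y %*% H                       # features x p
    fitted <- coefs %*% t(X)
    df <- ncol(m) - ncol(X)
    sigma <- sqrt(rowSums((y - fitted)^2) / df)
    sx <- rowMeans(y) + mean(log2(eff + 1)) - log2(1e6)
    sy <- sqrt(sigma)
    lo <- stats::lowess(sx, sy, f = span, iter = iterations)
    trendFun <- stats::approxfun(lo$x, lo$y, rule = 2, ties = mean)
    fitted.cpm <- 2^fitted
    fitted.count <- 1e-6 * sweep(fitted.cpm, 2, eff + 1, "*")
    fitted.logcount <- log2(fitted.count)
    w <- 1 / pmax(trendFun(fitted.logcount), 1e-4)^4
    dim(w) <- dim(y)
    dimnames(w) <- dimnames(y)
    list(logCpm = y, weights = w, trend = lo)
}

.trigammaInverse <- function(x) {
    y <- 0.5 + 1 / x
    for (i in 1:50) {
        tri <- trigamma(y)
        dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
        y <- y + dif
        if (max(abs(dif / y)) < 1e-10) break
    }
    y
}

## Moment matching of a scaled inverse chi-square prior on the residual
## variances: returns prior df (possibly Inf) and prior variance.
.fitVariancePrior <- function(s2, df) {
    s2 <- pmax(s2, 1e-10)
    e <- log(s2) - digamma(df / 2) + log(df / 2)
    emean <- mean(e)
    evar <- stats::var(e) - trigamma(df / 2)
    if (is.na(evar) || evar <= 0)
        return(list(df = Inf, s2 = exp(emean)))
    df0 <- 2 * .trigammaInverse(evar)
    list(df = df0,
         s2 = exp(emean + digamma(df0 / 2) - log(df0 / 2)))
}

#' Precision-weighted moderated differential test
#'
#' Per-feature weighted least squares followed by empirical-Bayes variance
#' moderation: residual variances are shrunk toward a common prior
#' (scaled inverse chi-square, hyperparameters by moment matching on the log
#' residual variances), yielding moderated t statistics with augmented
#' degrees of freedom, two-sided p-values and Benjamini-Hochberg adjusted
#' p-values.
#'
#' @param y log2-expression matrix (features x samples).
#' @param design design matrix (samples x coefficients).
#' @param contrast numeric contrast vector over design columns.
#' @param weights optional precision weights (same shape as \code{y});
#'   omit for unweighted fits.
#' @param label contrast label carried into the result.
#' @return data.frame with columns id, log2fc, aveExpr, t, p, padj,
#'   contrast, ordered as the input features.
#' @export
moderatedTest <- function(y, design, contrast, weights = NULL,
                          label = "contrast") {
    X <- as.matrix(design)
    n <- ncol(y); p <- ncol(X)
    df <- n - p
    if (df < 1) stop("zero residual degrees of freedom")
    ct <- as.numeric(contrast)
    if (length(ct) != p) stop("contrast length must match design columns")
    G <- nrow(y)
    est <- se2.unscaled <- s2 <- numeric(G)
    if (is.null(weights)) weights <- matrix(1, G, n)
    for (g in seq_len(G)) {
        w <- weights[g, ]
        A <- crossprod(X, X * w)
        Ai <- solve(A)
        beta <- Ai %*% crossprod(X, w * y[g, ])
        r <- y[g, ] - X %*% beta
        s2[g] <- sum(w * r^2) / df
        est[g] <- sum(ct * beta)
        se2.unscaled[g] <- drop(t(ct) %*% Ai %*% ct)
    }
    prior <- .fitVariancePrior(s2, df)
    if (is.finite(prior$df)) {
        s2.post <- (prior$df * prior$s2 + df * s2) / (prior$df + df)
        df.total <- df + prior$df
    } else {
        s2.post <- rep(prior$s2, G)
        df.total <- Inf
    }
    tstat <- est / sqrt(s2.post * se2.unscaled)
    pval <- 2 * stats::pt(-abs(tstat), df = df.total)
    data.frame(id = rownames(y), log2fc = est, aveExpr = rowMeans(y),
               t = tstat, p = pval, padj = bhAdjust(pval),
               contrast = label, row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Run the full differential pipeline on a time-course count object
#'
#' TMM scaling, optional batch adjustment, precision weights and moderated
#' tests for a set of contrasts. Applied identically to gene counts and
#' region counts.
#'
#' @param tc a \linkS4class{TimecourseCounts}.
#' @param contrasts named list of contrast vectors over the time points (in
#'   order of first appearance); defaults to one-vs-rest for every time
#'   point plus all ordered pairwise contrasts.
#' @param useBatch include a batch adjustment step when more than one batch
#'   is present.
#' @param useWeights use mean-variance precision weights.
#' @return Named list of \code{moderatedTest} result data.frames.
#' @export
deTimecourse <- function(tc, contrasts = NULL, useBatch = TRUE,
                         useWeights = TRUE) {
    tps <- unique(timepoints(tc))
    design <- timepointDesign(timepoints(tc), tps)
    if (is.null(contrasts)) {
        contrasts <- list()
        for (tp in tps)
            contrasts[[paste0(tp, ".vs.rest")]] <- oneVsRestContrast(tps, tp)
        for (a in tps) for (b in tps) if (a != b)
            contrasts[[paste0(a, ".vs.", b)]] <- pairwiseContrast(tps, a, b)
    }
    nf <- tmmFactors(tc)
    if (useWeights) {
        pw <- precisionWeights(tc, design, normFactors = nf)
        y <- pw$logCpm; w <- pw$weights
    } else {
        y <- logCpm(tc, normFactors = nf); w <- NULL
    }
    if (useBatch && length(unique(batches(tc))) > 1)
        y <- batchAdjust(y, batches(tc), timepoints(tc))
    out <- lapply(names(contrasts), function(nm)
        moderatedTest(y, design, contrasts[[nm]], weights = w, label = nm))
    names(out) <- names(contrasts)
    out
}

#' Call significant features at the stringent pipeline thresholds
#'
#' @param res a \code{moderatedTest} result data.frame.
#' @param lfc absolute log2 fold-change cutoff (default 2).
#' @param alpha adjusted p-value cutoff (default 0.01).
#' @param direction "up", "down" or "both".
#' @return Character vector of significant feature ids.
#' @export
significantFeatures <- function(res, lfc = 2, alpha = 0.01,
                                direction = c("both", "up", "down")) {
    direction <- match.arg(direction)
    sig <- res$padj <= alpha & switch(direction,
                                      both = abs(res$log2fc) >= lfc,
                                      up = res$log2fc >= lfc,
                                      down = res$log2fc <= -lfc)
    res$id[sig]
}
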