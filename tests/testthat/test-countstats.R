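test_that("expression filters implement the FPKM and cpm rules", {
    ## gene g2 has FPKM < 1 at time point D4 -> removed under the
    ## all-time-points rule
    m <- matrix(c(2000, 2000, 2000,
                  2000, 2000, 1), 2, 3, byrow = TRUE,
                dimnames = list(c("g1", "g2"), paste0("s", 1:3)))
    tc <- TimecourseCounts(m, timepoint = c("D0", "D0", "D4"),
                           replicate = c(1, 2, 1),
                           libSize = rep(2e6, 3))
    lens <- c(g1 = 1000, g2 = 1000)
    kept <- filterExpressed(tc, "fpkm_all_timepoints", threshold = 1,
                            lengths = lens)
    expect_identical(rownames(kept), "g1")
    expect_equal(metadata(kept)$filter_removed, 1)
    expect_error(filterExpressed(tc, "fpkm_all_timepoints",
                                 lengths = c(g1 = 1000)), "g2")

    ## all-zero matrix -> nothing survives
    z <- TimecourseCounts(matrix(0, 2, 3), timepoint = c("a", "a", "b"),
                          replicate = 1:3, libSize = rep(1, 3))
    expect_equal(nrow(filterExpressed(z, "cpm_min_samples",
                                      minSamples = 0)), 0)

    ## cpm > 1 in 21 of 23 samples passes "more than 20"; 20 of 23 fails
    n <- 23
    mk <- function(nHigh) {
        cm <- matrix(1000, 2, n)            # carrier gene fixes lib size
        cm <- rbind(cm, c(rep(100, nHigh), rep(0, n - nHigh)))
        rownames(cm) <- c("c1", "c2", "gx")
        TimecourseCounts(cm, timepoint = rep("t", n), replicate = 1:n)
    }
    expect_true("gx" %in% rownames(
        filterExpressed(mk(21), "cpm_min_samples", 1, 20)))
    expect_false("gx" %in% rownames(
        filterExpressed(mk(20), "cpm_min_samples", 1, 20)))
})

test_that("TMM factors are unit for identical and proportional libraries", {
    m <- matrix(rpois(600, 50) + 1, 100, 6)
    expect_equal(unname(tmmFactors(cbind(m[, 1], m[, 1]))), c(1, 1))
    expect_equal(unname(tmmFactors(cbind(m[, 1], 2 * m[, 1]))), c(1, 1))
})

test_that("TMM matches a hand-computed trimmed weighted mean on a fixture", {
    ## 8 genes, sample B doubles one gene; reference forced to column 1
    a <- c(100, 200, 300, 400, 500, 600, 700, 800)
    b <- a; b[3] <- 8 * a[3]
    x <- cbind(a = a, b = b)
    la <- sum(a); lb <- sum(b)
    M <- log2((b / lb) / (a / la))
    A <- 0.5 * log2((b / lb) * (a / la))
    v <- (lb - b) / (lb * b) + (la - a) / (la * a)
    n <- 8
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
            rank(A) >= loA & rank(A) <= hiA
    fB <- 2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
    expected <- c(1 / sqrt(fB), fB / sqrt(fB))   # geometric mean 1
    got <- tmmFactors(x, refColumn = 1)
    expect_equal(unname(got), unname(expected), tolerance = 1e-12)
    ## the inflated gene must have been trimmed away
    expect_false(keep[3])
})

test_that("TMM agrees with the edgeR reference implementation", {
    skip_if_not_installed("edgeR")
    set.seed(21)
    x <- matrix(rnbinom(200 * 6, mu = 80, size = 5) + 1, 200, 6)
    mine <- tmmFactors(x)
    ref <- edgeR::calcNormFactors(x, method = "TMM")
    expect_equal(unname(mine), unname(ref), tolerance = 1e-6)
})

test_that("TMM errors on degenerate input", {
    expect_error(tmmFactors(matrix(5, 3, 1)), "2 samples")
    x <- cbind(c(5, 0, 0), c(0, 3, 4))
    expect_error(tmmFactors(x, refColumn = 1), "no expressed feature")
})

test_that("batch adjustment removes location shifts and guards confounding", {
    set.seed(31)
    y <- matrix(rnorm(50 * 8), 50, 8)
    batch <- rep(c("A", "B"), each = 4)
    cond <- rep(c("c1", "c2"), 4)
    y2 <- y; y2[, batch == "B"] <- y2[, batch == "B"] + 2
    adj <- batchAdjust(y2, batch, cond)
    bm <- abs(rowMeans(adj[, batch == "A"]) - rowMeans(adj[, batch == "B"]))
    expect_lt(max(bm), 1e-6)

    ## single batch is the identity
    expect_equal(batchAdjust(y, rep("A", 8), cond), y)
    ## batch confounded 1:1 with condition is inestimable
    expect_error(batchAdjust(y, batch, rep(c("c1", "c2"), each = 4)),
                 "confounded")
    expect_error(batchAdjust(y, c("A", rep("B", 7)), cond), "2 samples")
})

test_that("batch-adjusted estimates recover planted fold changes", {
    ## ~10% of the transcriptome changes, as in realistic time courses;
    ## much larger planted fractions bias any global scaling method
    spec <- data.frame(pattern = c("rising", "flat"),
                       amplitude = c(2, 0), n_genes = c(60, 540))
    sim <- simulateTimecourseCounts(spec, timepoints = c("D0", "D4"),
                                    replicates = 4, dispersion = 0.05,
                                    batchOfReplicate = c(1, 1, 2, 2),
                                    batchFactors = c(`1` = 1, `2` = 2.5),
                                    seed = 13)
    res <- deTimecourse(sim$counts, contrasts = list(
        d4 = pairwiseContrast(c("D0", "D4"), "D4", "D0")))$d4
    est <- mean(res$log2fc[sim$truth$pattern == "rising"])
    expect_lt(abs(est - 2), 0.15)
})

test_that("precision weights track the mean-variance trend", {
    set.seed(41)
    design <- timepointDesign(rep(c("a", "b"), each = 3))
    ## near-homoscedastic counts: flat trend, bounded weight range
    m <- matrix(rpois(300 * 6, lambda = 1000), 300, 6)
    tc <- TimecourseCounts(m, timepoint = rep(c("a", "b"), each = 3),
                           replicate = rep(1:3, 2))
    w <- precisionWeights(tc, design)$weights
    expect_lt(max(w) / min(w), 2)

    ## variance decreasing in the mean: weights increase with the mean
    lo <- matrix(rnbinom(200 * 6, mu = 20, size = 1), 200, 6)
    hi <- matrix(rnbinom(200 * 6, mu = 5000, size = 50), 200, 6)
    tc2 <- TimecourseCounts(rbind(lo, hi),
                            timepoint = rep(c("a", "b"), each = 3),
                            replicate = rep(1:3, 2))
    w2 <- precisionWeights(tc2, design)$weights
    expect_gt(mean(w2[201:400, ]), mean(w2[1:200, ]))

    one <- TimecourseCounts(m[1, , drop = FALSE],
                            timepoint = rep(c("a", "b"), each = 3),
                            replicate = rep(1:3, 2))
    expect_error(precisionWeights(one, design), "2 features")
})

test_that("moderated test matches the limma reference on unweighted data", {
    skip_if_not_installed("limma")
    set.seed(51)
    y <- matrix(rnorm(400 * 6, sd = rep(runif(400, 0.5, 2), 6)), 400, 6)
    rownames(y) <- paste0("g", 1:400)
    design <- timepointDesign(rep(c("a", "b"), each = 3))
    ct <- pairwiseContrast(c("a", "b"), "b", "a")
    mine <- moderatedTest(y, design, ct)
    fit <- limma::lmFit(y, design)
    fit <- limma::contrasts.fit(fit, ct)
    eb <- limma::eBayes(fit)
    expect_equal(mine$t, unname(eb$t[, 1]), tolerance = 1e-8)
    expect_equal(mine$p, unname(eb$p.value[, 1]), tolerance = 1e-8)
    expect_equal(mine$log2fc, unname(fit$coefficients[, 1]),
                 tolerance = 1e-10)
})

test_that("null features reject at the nominal rate", {
    set.seed(61)
    y <- matrix(rnorm(2000 * 6), 2000, 6)
    rownames(y) <- paste0("g", 1:2000)
    design <- timepointDesign(rep(c("a", "b"), each = 3))
    res <- moderatedTest(y, design, pairwiseContrast(c("a", "b"), "b", "a"))
    rate <- mean(res$p < 0.05)
    se <- sqrt(0.05 * 0.95 / 2000)
    expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("permuting condition labels keeps the rejection rate at alpha", {
    spec <- data.frame(pattern = "flat", amplitude = 0, n_genes = 800)
    sim <- simulateTimecourseCounts(spec, timepoints = c("D0", "D4"),
                                    replicates = 3, seed = 71)
    tc <- sim$counts
    set.seed(72)
    perm <- sample(timepoints(tc))
    design <- timepointDesign(perm, c("D0", "D4"))
    pw <- precisionWeights(tc, design, normFactors = tmmFactors(tc))
    res <- moderatedTest(pw$logCpm, design,
                         pairwiseContrast(c("D0", "D4"), "D4", "D0"),
                         weights = pw$weights)
    alpha <- 0.05
    expect_lt(mean(res$p < alpha),
              alpha + 3 * sqrt(alpha * (1 - alpha) / nrow(res)))
})

test_that("BH adjustment equals the brute-force step-up oracle", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    expect_equal(bhAdjust(0.2), 0.2)
    set.seed(81)
    for (i in 1:10) {
        p <- runif(sample(5:1000, 1))
        expect_equal(bhAdjust(p), bhOracle(p))
    }
    expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})
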