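## Shared fixtures and independent oracles for the test suite. Every oracle
## here is a brute-force or closed-form computation kept independent of the
## package's implementation path.

library(GenomicRanges)

## tiny deterministic count object
toyCounts <- function() {
    m <- matrix(c(10, 20, 30,
                  40, 50, 60,
                  5,  5,  5,
                  100, 80, 90), 4, 3, byrow = TRUE,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
    TimecourseCounts(m, timepoint = c("D0", "D0", "D4"),
                     replicate = c(1, 2, 1))
}

## near-deterministic PWM for a given consensus
consensusPwm <- function(consensus, name = "toy", certainty = 0.997) {
    p <- vapply(strsplit(consensus, "")[[1]], function(b) {
        v <- rep((1 - certainty) / 3, 4)
        v[match(b, c("A", "C", "G", "T"))] <- certainty
        v
    }, numeric(4))
    PositionWeightMatrix(name, p)
}

## per-base membership oracle for interval algebra on toy chromosomes
baseVector <- function(gr, chrom, len) {
    v <- logical(len)
    sub <- gr[as.character(seqnames(gr)) == chrom]
    for (i in seq_along(sub)) v[start(sub)[i]:end(sub)[i]] <- TRUE
    v
}

randomRegionSet <- function(n, chroms = c("c1", "c2"), len = 2000) {
    s <- sample.int(len - 60, n, replace = TRUE)
    w <- sample(5:50, n, replace = TRUE)
    sort(GRanges(sample(chroms, n, replace = TRUE),
                 IRanges(s, width = w)))
}

## brute-force hypergeometric upper tail: P(X >= k)
hyperTailOracle <- function(k, whites, blacks, draws) {
    kk <- k:min(whites, draws)
    sum(exp(lchoose(whites, kk) + lchoose(blacks, draws - kk) -
            lchoose(whites + blacks, draws)))
}

## brute-force Benjamini-Hochberg step-up
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(m)
    out[o] <- pmin(adj, 1)
    out
}

## exact signed-rank p by full 2^n sign enumeration (two-sided)
wilcoxonEnumOracle <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- as.vector(signs %*% r)
    p_ge <- mean(v_all >= v_obs)
    p_le <- mean(v_all <= v_obs)
    min(1, 2 * min(p_ge, p_le))
}

## deterministic gene x sample truth for the barcoded screen
toyScreenTruth <- function(markerDrop = c(kd_A = 0.3, kd_B = 1)) {
    genes <- c("Ucp1", "TFa", "TFb", paste0("hk", 1:7))
    samples <- c(names(markerDrop), "ctrl1", "ctrl2")
    base <- c(50, 40, 40, 30, 60, 25, 45, 35, 55, 20)
    tc <- matrix(rep(base, length(samples)), length(genes),
                 dimnames = list(genes, samples))
    tc["TFa", "kd_A"] <- 8
    tc["TFb", "kd_B"] <- 8
    for (s in names(markerDrop))
        tc["Ucp1", s] <- round(tc["Ucp1", s] * markerDrop[[s]])
    storage.mode(tc) <- "integer"
    tc
}

mkGr <- function(starts, ends, chrom = "chr1") {
    GRanges(chrom, IRanges(starts, ends))
}

## Hand fixture: 8 regions with fully specified per-contrast calls. The
## expected catalog is enumerated from the subsetting rules by hand:
##   r1: up at D0 vs each mature tp            -> pre-specific
##   r2: up at D1, D2 and D4 vs D0             -> mature-specific
##   r3: up only at D4 vs D0                   -> mature-specific ("any")
##   r4: up at D0 vs each mature AND at D4 vsD0-> excluded from both
##   r5: up in D1 vs rest only                 -> D1-enriched
##   r6: nothing significant                   -> nowhere
##   r7: up at D0 vs D1 only (not D2/D4)       -> not pre-specific
##   r8: gain from D2 to D4                    -> consecutive gain only
daFixture <- function() {
    tps <- c("D0", "D1", "D2", "D4")
    regions <- mkGr(seq(101, by = 1000, length.out = 8),
                    seq(600, by = 1000, length.out = 8))
    names(regions) <- paste0("r", 1:8)
    blank <- function() data.frame(id = names(regions), log2fc = 0,
                                   aveExpr = 1, t = 0, p = 1, padj = 1,
                                   contrast = "x",
                                   stringsAsFactors = FALSE)
    hit <- function(df, ids, lfc = 3) {
        df$log2fc[df$id %in% ids] <- lfc
        df$padj[df$id %in% ids] <- 1e-4
        df$p[df$id %in% ids] <- 1e-5
        df
    }
    res <- list()
    for (a in tps) for (b in tps) if (a != b)
        res[[paste0(a, ".vs.", b)]] <- blank()
    for (tp in tps) res[[paste0(tp, ".vs.rest")]] <- blank()
    for (tp in c("D1", "D2", "D4"))
        res[[paste0("D0.vs.", tp)]] <- hit(res[[paste0("D0.vs.", tp)]],
                                           c("r1", "r4"))
    res[["D0.vs.D1"]] <- hit(res[["D0.vs.D1"]], "r7")
    for (tp in c("D1", "D2", "D4"))
        res[[paste0(tp, ".vs.D0")]] <- hit(res[[paste0(tp, ".vs.D0")]], "r2")
    res[["D4.vs.D0"]] <- hit(res[["D4.vs.D0"]], c("r3", "r4"))
    res[["D1.vs.rest"]] <- hit(res[["D1.vs.rest"]], "r5")
    res[["D4.vs.D2"]] <- hit(res[["D4.vs.D2"]], "r8")
    list(results = res, regions = regions, tps = tps)
}

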