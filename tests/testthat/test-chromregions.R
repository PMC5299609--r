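mkGr <- function(starts, ends, chrom = "chr1") {
    GRanges(chrom, IRanges(starts, ends))
}

test_that("replicate consensus takes the span of overlapping peak pairs", {
    a <- mkGr(c(101, 1001), c(300, 1200))
    expect_identical(granges(replicateConsensus(a, a)), granges(a))
    b <- mkGr(5001, 5100)
    expect_length(replicateConsensus(a, b), 0)
    ## [100,300) vs [250,400) in BED terms -> [100,400)
    r1 <- mkGr(101, 300); r2 <- mkGr(251, 400)
    cons <- replicateConsensus(r1, r2)
    expect_equal(start(cons), 101)
    expect_equal(end(cons), 400)
    ## per-base oracle: consensus covers the union of every overlapping pair
    oracle <- logical(2000)
    oracle[101:400] <- TRUE
    expect_equal(baseVector(cons, "chr1", 2000), oracle)
})

test_that("tag quantification is half-open and per-sample", {
    regions <- mkGr(101, 200)            # BED [100, 200)
    names(regions) <- "r1"
    inside <- GRanges("chr1", IRanges(c(101, 150, 199, 200, 120), width = 1))
    boundary <- GRanges("chr1", IRanges(201, width = 1))  # BED position 200
    tc <- quantifyTags(regions, list(D0_r1 = inside, D0_r2 = boundary))
    expect_equal(unname(counts(tc)[1, ]), c(5, 0))
    ## no tags at all
    tc0 <- quantifyTags(regions, list(D0_r1 = GRanges()))
    expect_equal(unname(counts(tc0)[1, 1]), 0)
    ## tags on an unknown chromosome are ignored with a warning
    expect_warning(
        quantifyTags(regions, list(D0_r1 = GRanges("chrX",
                                                   IRanges(5, width = 1)))),
        "chrX")
    ## a tag inside two overlapping regions counts in both
    two <- mkGr(c(101, 151), c(200, 250))
    names(two) <- c("a", "b")
    t2 <- quantifyTags(two, list(D0_r1 = GRanges("chr1",
                                                 IRanges(175, width = 1))))
    expect_equal(unname(counts(t2)[, 1]), c(1, 1))
})

test_that("the DA catalog matches the enumerated fixture expectations", {
    fx <- daFixture()
    cat_ <- deriveDaCatalog(fx$results, fx$regions, fx$tps,
                            earlyTimepoints = character(0))
    expect_setequal(names(preSpecific(cat_)), "r1")
    expect_setequal(names(matureSpecific(cat_)), c("r2", "r3"))
    expect_setequal(names(timepointEnriched(cat_)$D1), "r5")
    expect_length(timepointEnriched(cat_)$D0, 0)
    gains <- consecutiveGains(cat_)
    expect_setequal(names(gains$D2_to_D4), "r8")
    expect_setequal(names(gains$D0_to_D1), "r2")

    ## "each" mode keeps only regions up at every mature time point
    each <- deriveDaCatalog(fx$results, fx$regions, fx$tps,
                            earlyTimepoints = character(0),
                            matureMode = "each")
    expect_setequal(names(matureSpecific(each)), "r2")

    ## missing contrast is named
    broken <- fx$results; broken[["D0.vs.D4"]] <- NULL
    expect_error(deriveDaCatalog(broken, fx$regions, fx$tps,
                                 earlyTimepoints = character(0)),
                 "D0.vs.D4")
})

test_that("an all-null result gives an empty catalog", {
    fx <- daFixture()
    nullRes <- lapply(fx$results, function(df) {
        df$log2fc <- 0; df$padj <- 1; df
    })
    cat_ <- deriveDaCatalog(nullRes, fx$regions, fx$tps,
                            earlyTimepoints = character(0))
    expect_length(preSpecific(cat_), 0)
    expect_length(matureSpecific(cat_), 0)
    expect_true(all(lengths(timepointEnriched(cat_)) == 0))
})

test_that("promoter annotation follows the strand-aware -1kb/+100bp window", {
    ann <- data.frame(gene_id = c("gp", "gm"),
                      chrom = c("chr1", "chr2"),
                      strand = c("+", "-"),
                      tss = c(10000, 10000))
    mkCenter <- function(center, chrom)
        GRanges(chrom, IRanges(center - 10, center + 9))  # center as defined
    ## + strand, center 9600: inside [TSS-1000, TSS+100)
    a <- annotateRegions(mkCenter(9600, "chr1"), ann)
    expect_equal(a$class, "proximal")
    expect_equal(a$distance, -400)
    ## + strand, center 10200: distal at +200
    b <- annotateRegions(mkCenter(10200, "chr1"), ann)
    expect_equal(b$class, "distal")
    expect_equal(b$distance, 200)
    ## - strand, center 10400: 400 bp upstream on the minus strand
    c_ <- annotateRegions(mkCenter(10400, "chr2"), ann)
    expect_equal(c_$class, "proximal")
    expect_equal(c_$distance, -400)
    ## strand-mirror oracle: a grid of centers classified by the mirrored
    ## window rule
    for (cen in seq(8800, 11200, by = 100)) {
        got <- annotateRegions(mkCenter(cen, "chr2"), ann)$class
        d <- 10000 - cen
        expect_equal(got, if (d >= -1000 && d < 100) "proximal"
                          else "distal")
    }
})

test_that("signal profiles bin correctly and conserve tag counts", {
    anchors <- GRanges("chr1", IRanges(10001, 10001))
    ## window 5000, bin 25 -> 400 columns
    p <- signalProfile(anchors, GRanges(), window = 5000, bin = 25)
    expect_equal(ncol(p), 400)
    expect_true(all(p == 0))
    ## single tag at the anchor center lands in the first bin right of it
    tag <- GRanges("chr1", IRanges(10001, width = 1))
    p1 <- signalProfile(anchors, tag, window = 500, bin = 5)
    expect_equal(ncol(p1), 200)
    expect_equal(unname(p1[1, 101]), 1)   # offset 0 -> bin 101 of 200
    expect_equal(sum(p1), 1)
    expect_error(signalProfile(anchors, tag, window = 500, bin = 7),
                 "divisible")

    ## minus-strand anchors are mirrored
    plus <- GRanges("chr1", IRanges(10001, 10001), strand = "+")
    minus <- GRanges("chr1", IRanges(10001, 10001), strand = "-")
    tagR <- GRanges("chr1", IRanges(10101, width = 1))   # +100 offset
    pp <- signalProfile(plus, tagR, window = 500, bin = 5)
    pm <- signalProfile(minus, tagR, window = 500, bin = 5)
    expect_equal(unname(which(pp[1, ] == 1)), 121)
    expect_equal(unname(which(pm[1, ] == 1)), 80)

    ## conservation: row sums equal direct window counts
    set.seed(9)
    tags <- GRanges("chr1", IRanges(sample(5000:15000, 300), width = 1))
    anch <- GRanges("chr1", IRanges(c(8000, 10000, 12000), width = 1))
    prof <- signalProfile(anch, tags, window = 1000, bin = 25)
    win <- GRanges("chr1", IRanges(start(anch) - 1000,
                                   start(anch) + 999))
    expect_equal(unname(rowSums(prof)), countOverlaps(win, tags))
})

test_that("paired Wilcoxon matches full enumeration and handles zeros", {
    set.seed(10)
    for (n in c(5, 8)) {
        a <- rnorm(n); b <- rnorm(n)
        got <- pairedWilcoxon(a, b)
        expect_equal(got$p.value, wilcoxonEnumOracle(a - b))
    }
    expect_warning(res <- pairedWilcoxon(1:4, 1:4), "zero")
    expect_equal(res$p.value, 1)
    ## all shifts on one side: strongly one-sided
    a <- rnorm(20)
    expect_lt(pairedWilcoxon(a + 1, a, alternative = "greater")$p.value,
              1e-4)
    expect_error(pairedWilcoxon(1:3, 1:4), "equal length")
})
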