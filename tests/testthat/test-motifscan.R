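test_that("log-odds scanning finds planted consensus hits on both strands", {
    pwm <- consensusPwm("AAACG")
    hits <- scanPwm(c(s1 = "TTAAACGTT"), pwm, threshold = 0.9)
    expect_equal(nrow(hits), 1)
    expect_equal(hits$offset, 3)
    expect_equal(hits$strand, "+")
    expect_equal(hits$score, maxScore(pwm))

    ## reverse-complement content is found on the minus strand
    hitsR <- scanPwm(c(s1 = "TTCGTTTGGG"), pwm, threshold = 0.9)
    expect_equal(hitsR$strand, "-")
    expect_equal(hitsR$offset, 3)

    ## ambiguous bases: windows touching N are skipped
    hitsN <- scanPwm(c(s1 = "TTNCGTAT"), pwm, threshold = 0.5)
    expect_equal(nrow(hitsN), 0)
})

test_that("hit calls over all 4-mers equal an exhaustive enumeration oracle", {
    set.seed(11)
    p <- matrix(rgamma(16, 1), 4, 4)
    p <- sweep(p, 2, colSums(p), "/")
    pwm <- PositionWeightMatrix("rand4", p)
    bases <- c("A", "C", "G", "T")
    kmers <- apply(expand.grid(bases, bases, bases, bases), 1, paste,
                   collapse = "")
    lom <- log2(pmax(p, 1e-10) / 0.25)
    rownames(lom) <- bases
    oracleScore <- function(km) {
        b <- strsplit(km, "")[[1]]
        fwd <- sum(lom[cbind(match(b, bases), 1:4)])
        rc <- rev(chartr("ACGT", "TGCA", b))
        rev_ <- sum(lom[cbind(match(rc, bases), 1:4)])
        c(fwd, rev_)
    }
    sc <- vapply(kmers, oracleScore, numeric(2))
    for (thr in c(-2, 0, 1, 3)) {
        hits <- scanPwm(stats::setNames(kmers, kmers), pwm,
                        threshold = thr, thresholdType = "bits")
        oracleN <- sum(sc[1, ] >= thr) + sum(sc[2, ] >= thr)
        expect_equal(nrow(hits), oracleN)
    }
})

test_that("scanning a sequence and its reverse complement mirrors hits", {
    set.seed(12)
    pwm <- consensusPwm("TTGACA", certainty = 0.7)
    seqs <- vapply(1:10, function(i)
        paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
              collapse = ""), character(1))
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs)))
    h1 <- scanPwm(stats::setNames(seqs, paste0("s", 1:10)), pwm, 0.7)
    h2 <- scanPwm(stats::setNames(rc, paste0("s", 1:10)), pwm, 0.7)
    expect_equal(nrow(h1), nrow(h2))
    expect_equal(sort(h1$score), sort(h2$score))
    ## a + hit at offset o maps to a - hit at L - o - w + 2 on the revcomp
    L <- 80; w <- pwmLength(pwm)
    key1 <- sort(paste(h1$seq, h1$offset, h1$strand))
    key2 <- sort(paste(h2$seq, L - h2$offset - w + 2,
                       ifelse(h2$strand == "+", "-", "+")))
    expect_equal(key1, key2)
})

test_that("enrichment p-values equal the brute-force hypergeometric tail", {
    pwm <- consensusPwm("ACGTACGTAC")
    withHit <- function(n, k, label) {
        base <- strrep("T", 40)
        s <- rep(base, n)
        s[seq_len(k)] <- paste0(strrep("T", 10), "ACGTACGTAC",
                                strrep("T", 20))
        stats::setNames(s, paste0(label, seq_len(n)))
    }
    fg <- withHit(20, 10, "f")
    bg <- withHit(200, 10, "b")
    res <- enrichMotifs(Biostrings::DNAStringSet(fg),
                        Biostrings::DNAStringSet(bg), list(pwm))
    expect_equal(res$fg_with_hit, 10)
    expect_equal(res$bg_with_hit, 10)
    expect_equal(res$p, hyperTailOracle(10, 20, 200, 20))

    ## equal hit proportions are not significant
    fg2 <- withHit(200, 20, "f")
    bg2 <- withHit(2000, 200, "b")
    res2 <- enrichMotifs(Biostrings::DNAStringSet(fg2),
                         Biostrings::DNAStringSet(bg2), list(pwm))
    expect_gt(res2$p, 0.2)

    ## brute-force tail equals phyper across random configurations
    set.seed(13)
    for (i in 1:20) {
        N <- sample(50:500, 1); n <- sample(10:40, 1)
        K <- sample(5:N, 1); k <- sample(0:min(K, n), 1)
        expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                     hyperTailOracle(k, K, N - K, n), tolerance = 1e-12)
    }
})

test_that("a PWM longer than every sequence is excluded with a flag", {
    pwm <- consensusPwm("ACGTACGTACGTACGTACGT")
    short <- Biostrings::DNAStringSet(c(a = "ACGT", b = "TTTT"))
    ok <- consensusPwm("AC", name = "short")
    res <- enrichMotifs(short, short, list(pwm, ok))
    expect_equal(res$pwm, "short")
    expect_equal(attr(res, "excluded"), "toy")
    expect_error(enrichMotifs(Biostrings::DNAStringSet(), short, list(ok)),
                 "non-empty")
})

test_that("background generators preserve composition or match GC", {
    fg <- Biostrings::DNAStringSet(c(a = "AAAACCCC", b = "GGGGTTTTAA"))
    sh <- generateBackground(fg, mode = "shuffled", seed = 3)
    expect_equal(nchar(as.character(sh)), nchar(as.character(fg)),
                 ignore_attr = TRUE)
    sortChars <- function(s) paste(sort(strsplit(s, "")[[1]]),
                                   collapse = "")
    expect_equal(vapply(as.character(sh), sortChars, character(1)),
                 vapply(as.character(fg), sortChars, character(1)),
                 ignore_attr = TRUE)

    set.seed(14)
    genome <- Biostrings::DNAStringSet(c(chr1 = paste(
        sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
        collapse = "")))
    fg2 <- Biostrings::DNAStringSet(stats::setNames(
        vapply(1:10, function(i) paste(
            sample(c("A", "C", "G", "T"), 200, replace = TRUE),
            collapse = ""), character(1)), paste0("f", 1:10)))
    gcOf <- function(s) {
        n <- nchar(s); (n - nchar(gsub("[GC]", "", s))) / n
    }
    bg <- generateBackground(fg2, genome, mode = "gc_matched_sampled",
                             seed = 4)
    dev <- abs(vapply(as.character(bg), gcOf, numeric(1)) -
               vapply(as.character(fg2), gcOf, numeric(1)))
    expect_true(all(dev <= 0.021))
    expect_error(generateBackground(fg2, Biostrings::DNAStringSet(),
                                    mode = "gc_matched_sampled"),
                 "genome")
})

test_that("summit centrality profiles recover planted central motifs", {
    ## 1 kb window, 5 bp bins -> 200 bins
    peaks <- GRanges("chr1", IRanges(seq(1, by = 3000, length.out = 50),
                                     width = 2000))
    mcols(peaks)$summit <- start(peaks) + 1000L
    set.seed(15)
    offs <- round(rnorm(500, 0, 50))
    hits <- GRanges("chr1",
                    IRanges(rep(mcols(peaks)$summit, each = 10) +
                            offs, width = 1))
    prof <- centralityProfile(peaks, hits, window = 500, bin = 5)
    expect_length(prof, 200)
    ## the maximum sits in the central decile (bins 91-110)
    expect_true(which.max(prof) %in% 91:110)
    expect_equal(sum(prof) * length(peaks), length(hits))

    empty <- centralityProfile(peaks, GRanges(), window = 500, bin = 5)
    expect_true(all(empty == 0))
    expect_error(centralityProfile(granges(peaks), hits), "summit")
})

test_that("co-localization intersects regions and keeps their coordinates", {
    set.seed(16)
    genome <- Biostrings::DNAStringSet(c(chr1 = paste(
        sample(c("A", "C", "G", "T"), 50000, replace = TRUE),
        collapse = "")))
    da <- GRanges("chr1", IRanges(c(1001, 11001, 21001), width = 1000))
    names(da) <- paste0("da", 1:3)
    pwm <- consensusPwm("ACGTAC")
    ## identical sets: foreground equals the DA regions
    res <- colocalization(da, da, list(pwm), genome, times = 2)
    expect_equal(res$fg_total, 3)
    ## disjoint sets: warning and empty result
    far <- GRanges("chr1", IRanges(40001, width = 500))
    expect_warning(resEmpty <- colocalization(da, far, list(pwm), genome),
                   "no overlap")
    expect_equal(nrow(resEmpty), 0)
})
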