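writeFq <- function(seqs, path) {
    writeLines(as.vector(rbind(sprintf("@r%03d", seq_along(seqs)), seqs,
                               "+", strrep("I", nchar(seqs)))), path)
    path
}

test_that("read structure validation enforces barcode separation", {
    ok <- readStructure(c(AAAAAA = "S1", TTTTTT = "S2"), maxMismatch = 1)
    expect_equal(ok$umiLen, 15)
    expect_error(readStructure(c(AAAAAA = "S1", AAAATT = "S2"),
                               maxMismatch = 1), "too close")
    expect_error(readStructure(c(AAAA = "S1")), "length 6")
})

test_that("demultiplexing assigns by barcode and conserves reads", {
    d <- withr::local_tempdir()
    wl <- c(AAAAAA = "S1", TTTTTT = "S2")
    r1 <- c(paste0("AAAAAA", strrep("G", 15), strrep("T", 30)),
            paste0("TTTTTT", strrep("C", 15), strrep("T", 30)),
            paste0("CCCCCC", strrep("A", 15), strrep("T", 30)))
    r2 <- c("ACGTACGT", "TTTTCCCC", "GGGGAAAA")
    f1 <- writeFq(r1, file.path(d, "r1.fq"))
    f2 <- writeFq(r2, file.path(d, "r2.fq"))
    dm <- demultiplex(f1, f2, readStructure(wl))
    expect_equal(dm$reads$sample, c("S1", "S2"))
    expect_equal(dm$reads$umi, c(strrep("G", 15), strrep("C", 15)))
    expect_equal(dm$reads$seq, r2[1:2])
    expect_equal(dm$unassigned, 1)
    expect_equal(nrow(dm$reads) + dm$unassigned, dm$stats$total)

    ## one mismatch rescued only when tolerated
    r1b <- paste0("AAAAAT", strrep("G", 15), strrep("T", 30))
    f1b <- writeFq(r1b, file.path(d, "r1b.fq"))
    f2b <- writeFq("ACGTACGT", file.path(d, "r2b.fq"))
    strict <- demultiplex(f1b, f2b, readStructure(wl, maxMismatch = 0))
    expect_equal(strict$unassigned, 1)
    loose <- demultiplex(f1b, f2b, readStructure(wl, maxMismatch = 1))
    expect_equal(loose$reads$sample, "S1")

    ## malformed inputs are reported with a record index
    f3 <- file.path(d, "bad.fq")
    writeLines(c("@r1", "ACGT", "+", "IIII", "notheader", "ACGT", "+",
                 "IIII"), f3)
    expect_error(demultiplex(f3, f3, readStructure(wl)), "record 2")
    expect_error(demultiplex(f1, f1b, readStructure(wl)),
                 "differ in read count")
})

test_that("UMI counting collapses duplicates to molecules", {
    tx <- Biostrings::DNAStringSet(c(geneA = strrep("ACGGT", 20),
                                     geneB = strrep("TTGCA", 20)))
    frag <- substr(as.character(tx[["geneA"]]), 1, 20)
    ## 10 reads, same sample/UMI/gene -> 1 molecule
    reads <- data.frame(sample = "S1", umi = strrep("A", 15), seq = frag)
    reads <- reads[rep(1, 10), ]
    uc <- umiCount(reads, tx)
    expect_equal(uc$table["geneA", "S1"], 1)
    expect_equal(uc$duplicationRate, 0.9)
    ## 10 distinct UMIs -> 10 molecules
    reads2 <- data.frame(sample = "S1",
                         umi = vapply(1:10, function(i)
                             paste(sample(c("A", "C", "G", "T"), 15,
                                          replace = TRUE),
                                   collapse = ""), character(1)),
                         seq = frag)
    expect_equal(umiCount(reads2, tx)$table["geneA", "S1"], 10)
    ## unmappable reads are dropped and counted
    reads3 <- rbind(reads2, data.frame(sample = "S1",
                                       umi = strrep("C", 15),
                                       seq = strrep("N", 20)))
    expect_equal(umiCount(reads3, tx)$unmapped, 1)
})

test_that("the simulated screen round-trips through the full kd pipeline", {
    d <- withr::local_tempdir()
    truth <- toyScreenTruth()
    wl <- stats::setNames(colnames(truth), names(makeBarcodeWhitelist(4)))
    sim <- simulateBarcodedFastq(truth, wl, duplicateRate = 0.5,
                                 unknownBarcodeReads = 7, dir = d,
                                 seed = 23)
    dm <- demultiplex(sim$fastq1, sim$fastq2, readStructure(wl))
    ## conservation, with the planted foreign barcodes unassigned
    expect_equal(nrow(dm$reads) + dm$unassigned, sim$nReads)
    expect_equal(dm$unassigned, 7)
    uc <- umiCount(dm$reads, sim$transcriptome,
                   samples = colnames(truth))
    ## UMI-collapsed counts equal the planted truth exactly
    expect_equal(uc$table, truth)
    expect_gt(sum(dm$stats$total - 7), sum(truth))   # raw exceeds molecules

    ## QC filter drops thin samples
    filtered <- sampleQcFilter(uc, minReads = 0)
    expect_equal(filtered$dropped, character(0))
    thin <- sampleQcFilter(uc, minReads = max(uc$readTotals) + 1)
    expect_equal(ncol(thin$table), 0)
})

test_that("the KD report recovers efficiency and marker response", {
    tab <- cbind(kdFull = c(Ucp1 = 100, TFa = 0, hk = 100),
                 kdNone = c(100, 50, 100),
                 ctrl1 = c(100, 50, 100),
                 ctrl2 = c(100, 50, 100))
    rep_ <- kdReport(tab, kdMap = c(kdFull = "TFa", kdNone = "TFa"),
                     controls = c("ctrl1", "ctrl2"), marker = "Ucp1",
                     nClusters = 2)
    ps <- rep_$perSample
    expect_equal(ps$efficiency[ps$sample == "kdFull"], 1)
    expect_equal(ps$efficiency[ps$sample == "kdNone"], 0)
    expect_equal(ps$markerLog2FC[ps$sample == "kdNone"], 0)
    expect_warning(kdReport(tab, kdMap = c(kdFull = "missing"),
                            controls = "ctrl1"), "absent")
    expect_error(kdReport(tab, kdMap = c(kdFull = "TFa"),
                          controls = character(0)), "control")
})

test_that("sample clustering matches hand-computed complete linkage", {
    set.seed(24)
    tab <- matrix(rexp(30, 1 / 50), 10, 3,
                  dimnames = list(paste0("g", 1:10), c("a", "b", "c")))
    rep_ <- kdReport(tab, kdMap = c(a = "g1"), controls = "c",
                     nClusters = 2)
    d <- 1 - cor(tab)
    ## complete linkage on three points: first join the closest pair, then
    ## the remaining point at the maximum of its two distances
    pairD <- c(ab = d["a", "b"], ac = d["a", "c"], bc = d["b", "c"])
    first <- min(pairD)
    second <- switch(names(which.min(pairD)),
                     ab = max(d["c", "a"], d["c", "b"]),
                     ac = max(d["b", "a"], d["b", "c"]),
                     bc = max(d["a", "b"], d["a", "c"]))
    expect_equal(rep_$hclust$height, c(first, second))
})
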