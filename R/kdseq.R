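## Multiplexed barcoded 3' mRNA-seq: demultiplexing, UMI-collapsed
## counting, QC filtering and the knockdown report.
##
## Read 1 layout: positions 1-6 sample barcode, 7-21 a 15-nt unique
## molecular identifier, then the oligo-dT stretch; read 2 carries the
## transcript fragment.

#' Define the barcoded read structure
#'
#' @param whitelist named character vector: names are the 6-nt sample
#'   barcodes, values the sample names. Barcodes must be unique with
#'   pairwise Hamming distance greater than twice the mismatch tolerance.
#' @param maxMismatch barcode mismatch tolerance (default 0).
#' @param barcodeLen,umiLen read-1 layout (defaults 6 and 15 nt).
#' @return list of class \code{read_structure}.
#' @export
readStructure <- function(whitelist, maxMismatch = 0, barcodeLen = 6,
                          umiLen = 15) {
    bcs <- names(whitelist)
    if (is.null(bcs) || anyDuplicated(bcs))
        stop("whitelist must be named by unique barcodes")
    if (any(nchar(bcs) != barcodeLen))
        stop("all barcodes must have length ", barcodeLen)
    if (length(bcs) > 1) {
        for (i in seq_len(length(bcs) - 1))
            for (j in seq(i + 1, length(bcs)))
                if (.hamming(bcs[i], bcs[j]) <= 2 * maxMismatch)
                    stop("barcodes ", bcs[i], " and ", bcs[j],
                         " are too close for tolerance ", maxMismatch)
    }
    structure(list(whitelist = whitelist, maxMismatch = maxMismatch,
                   barcodeLen = barcodeLen, umiLen = umiLen),
              class = "read_structure")
}

.checkFastq <- function(path) {
    lines <- readLines(path)
    if (length(lines) %% 4 != 0)
        stop("malformed FASTQ ", path, ": record ",
             length(lines) %/% 4 + 1, " is truncated")
    idx <- seq(1, length(lines), by = 4)
    badAt <- which(!startsWith(lines[idx], "@"))
    if (length(badAt))
        stop("malformed FASTQ record ", badAt[1], " in ", path,
             ": missing '@' header")
    badPlus <- which(!startsWith(lines[idx + 2], "+"))
    if (length(badPlus))
        stop("malformed FASTQ record ", badPlus[1], " in ", path,
             ": missing '+' separator")
    length(lines) %/% 4
}

#' Demultiplex paired barcoded reads
#'
#' Matches read-1 barcodes to the whitelist (within the mismatch
#' tolerance), extracts the UMI and attaches both to the mate sequence.
#' Reads with unmatched barcodes go to the unassigned bin; assigned plus
#' unassigned always equals the input read count.
#'
#' @param fastq1,fastq2 paths to the paired FASTQ files (equal record
#'   counts).
#' @param rs a \code{\link{readStructure}}.
#' @return list with \code{reads} (data.frame sample/umi/seq for assigned
#'   reads), \code{unassigned} (count) and \code{stats} (total, assigned,
#'   per-sample table).
#' @export
demultiplex <- function(fastq1, fastq2, rs) {
    n1 <- .checkFastq(fastq1); n2 <- .checkFastq(fastq2)
    if (n1 != n2)
        stop("paired files differ in read count (", n1, " vs ", n2, ")")
    r1 <- as.character(Biostrings::readDNAStringSet(fastq1,
                                                    format = "fastq"))
    r2 <- as.character(Biostrings::readDNAStringSet(fastq2,
                                                    format = "fastq"))
    bc <- substr(r1, 1, rs$barcodeLen)
    umi <- substr(r1, rs$barcodeLen + 1, rs$barcodeLen + rs$umiLen)
    wl <- rs$whitelist
    if (rs$maxMismatch == 0) {
        sample <- unname(wl[bc])
    } else {
        bcs <- names(wl)
        lut <- new.env()
        sample <- vapply(bc, function(b) {
            hit <- get0(b, envir = lut, ifnotfound = NULL)
            if (!is.null(hit)) return(hit)
            d <- vapply(bcs, .hamming, integer(1), b = b)
            res <- if (min(d) <= rs$maxMismatch)
                unname(wl[bcs[which.min(d)]]) else NA_character_
            assign(b, res, envir = lut)
            res
        }, character(1), USE.NAMES = FALSE)
    }
    assigned <- !is.na(sample)
    list(reads = data.frame(sample = sample[assigned],
                            umi = umi[assigned],
                            seq = unname(r2[assigned]),
                            stringsAsFactors = FALSE),
         unassigned = sum(!assigned),
         stats = list(total = n1, assigned = sum(assigned),
                      perSample = table(sample[assigned])))
}

#' UMI-collapsed gene x sample count table
#'
#' Assigns each read to a transcript by exact substring lookup against the
#' toy transcriptome (reads matching no transcript, or more than one, are
#' dropped and counted in the stats) and counts each distinct
#' (gene, sample, UMI) combination once, collapsing PCR duplicates to
#' molecules.
#'
#' @param reads assigned-read data.frame from \code{\link{demultiplex}}.
#' @param transcriptome named \code{DNAStringSet} of transcripts.
#' @param samples optional sample ordering for the table columns.
#' @return list with \code{table} (gene x sample molecule counts),
#'   \code{readTotals} (raw assigned reads per sample),
#'   \code{duplicationRate} (1 - molecules / mapped reads) and
#'   \code{unmapped} (dropped reads).
#' @export
umiCount <- function(reads, transcriptome, samples = NULL) {
    tx <- as.character(transcriptome)
    genes <- names(tx)
    uniq <- unique(reads$seq)
    hitMat <- vapply(tx, function(t)
        vapply(uniq, function(s) grepl(s, t, fixed = TRUE), logical(1)),
        logical(length(uniq)))
    hitMat <- matrix(hitMat, nrow = length(uniq))
    nhits <- rowSums(hitMat)
    geneOf <- rep(NA_character_, length(uniq))
    ok <- nhits == 1
    geneOf[ok] <- genes[apply(hitMat[ok, , drop = FALSE], 1, which.max)]
    gene <- geneOf[match(reads$seq, uniq)]
    mapped <- !is.na(gene)
    if (is.null(samples)) samples <- sort(unique(reads$sample))
    key <- paste(gene[mapped], reads$sample[mapped], reads$umi[mapped],
                 sep = "\r")
    mol <- !duplicated(key)
    tab <- table(factor(gene[mapped][mol], levels = genes),
                 factor(reads$sample[mapped][mol], levels = samples))
    tabM <- matrix(as.integer(tab), nrow = length(genes),
                   dimnames = list(genes, samples))
    readTotals <- table(factor(reads$sample, levels = samples))
    list(table = tabM,
         readTotals = stats::setNames(as.integer(readTotals), samples),
         duplicationRate = 1 - sum(mol) / max(1, sum(mapped)),
         unmapped = sum(!mapped))
}

#' Drop samples with insufficient reads
#'
#' @param umiResult result of \code{\link{umiCount}}.
#' @param minReads minimal raw read total per sample (default 1e6, the
#'   screening protocol's exclusion threshold).
#' @return The filtered \code{umiCount} result; dropped samples are listed
#'   in \code{$dropped}.
#' @export
sampleQcFilter <- function(umiResult, minReads = 1e6) {
    keep <- umiResult$readTotals >= minReads
    dropped <- names(umiResult$readTotals)[!keep]
    umiResult$table <- umiResult$table[, keep, drop = FALSE]
    umiResult$readTotals <- umiResult$readTotals[keep]
    umiResult$dropped <- dropped
    umiResult
}

#' Knockdown efficiency and marker response report
#'
#' For every knockdown sample: KD efficiency = 1 - target expression in the
#' KD sample / mean target expression in the controls (cpm scale), the
#' marker's log2 fold change versus the control mean, and a complete-
#' linkage hierarchical clustering of all samples on correlation distance
#' (1 - Pearson) over the full expression table, cut into
#' \code{nClusters} groups.
#'
#' @param cpmTable gene x sample normalized expression (cpm) matrix.
#' @param kdMap named character vector: sample -> targeted TF gene.
#' @param controls control sample names (>= 1).
#' @param marker marker gene (default "Ucp1").
#' @param nClusters clusters to cut the dendrogram into (default 3).
#' @return list with \code{perSample} data.frame (sample, target,
#'   efficiency, markerLog2FC, cluster) and \code{hclust} (the tree).
#' @export
kdReport <- function(cpmTable, kdMap, controls, marker = "Ucp1",
                     nClusters = 3) {
    if (!length(controls)) stop("need at least one control sample")
    miss <- setdiff(c(names(kdMap), controls), colnames(cpmTable))
    if (length(miss))
        stop("samples absent from the table: ", paste(miss, collapse = ", "))
    ctrlMean <- function(g) mean(cpmTable[g, controls])
    eff <- mlfc <- rep(NA_real_, length(kdMap))
    for (i in seq_along(kdMap)) {
        s <- names(kdMap)[i]; tgt <- kdMap[[i]]
        if (tgt %in% rownames(cpmTable)) {
            cm <- ctrlMean(tgt)
            if (cm > 0) eff[i] <- 1 - cpmTable[tgt, s] / cm
        } else {
            warning("target gene ", tgt, " absent from the table")
        }
        if (marker %in% rownames(cpmTable))
            mlfc[i] <- log2((cpmTable[marker, s] + 0.5) /
                            (ctrlMean(marker) + 0.5))
    }
    cc <- stats::cor(cpmTable)
    hc <- stats::hclust(stats::as.dist(1 - cc), method = "complete")
    cl <- stats::cutree(hc, k = min(nClusters, ncol(cpmTable)))
    list(perSample = data.frame(sample = names(kdMap),
                                target = unname(kdMap),
                                efficiency = eff, markerLog2FC = mlfc,
                                cluster = cl[names(kdMap)],
                                row.names = NULL,
                                stringsAsFactors = FALSE),
         clusters = cl, hclust = hc)
}

#' Counts-per-million
#' @param m count matrix.
#' @param libSize optional per-sample totals (default column sums).
#' @return cpm matrix.
#' @export
cpm <- function(m, libSize = NULL) {
    if (is.null(libSize)) libSize <- colSums(m)
    sweep(m, 2, pmax(libSize, 1), "/") * 1e6
}
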