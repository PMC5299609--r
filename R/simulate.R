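## Synthetic-data generators. Every generator is fully determined by its
## `seed` argument; negative binomial counts are parameterized by mean mu and
## dispersion phi with variance mu + phi * mu^2.

#' Canonical temporal trend shapes
#'
#' Five archetypal log2-scale trend shapes over the differentiation time
#' course (confluence through mature adipocyte): monotone rising, an early
#' spike that decays below baseline, a dip or a peak at the middle time
#' point, and flat. Shapes are defined on five canonical time points and
#' linearly interpolated for other course lengths; each is scaled so its
#' largest absolute excursion is 1.
#'
#' @param pattern one of "rising", "early-spike", "dip-at-mid",
#'   "peak-at-mid", "flat".
#' @param T number of time points (>= 2).
#' @return Numeric vector of length \code{T} in log2 units (unit amplitude).
#' @export
trendShape <- function(pattern = c("rising", "early-spike", "dip-at-mid",
                                   "peak-at-mid", "flat"), T = 5) {
    pattern <- match.arg(pattern)
    if (T < 2) stop("need at least 2 time points")
    base <- switch(pattern,
                   flat = c(0, 0, 0, 0, 0),
                   rising = c(0, 0.25, 0.5, 0.75, 1),
                   `early-spike` = c(0, 1, 0.4, 0.1, -0.2),
                   `dip-at-mid` = c(0, -0.3, -1, -0.3, 0),
                   `peak-at-mid` = c(0, 0.3, 1, 0.3, 0))
    stats::approx(seq(0, 1, length.out = 5), base,
                  xout = seq(0, 1, length.out = T))$y
}

#' Simulate a negative-binomial time-course count matrix
#'
#' Gene means follow planted temporal trend classes on the log2 scale,
#' multiplied by per-batch factors; counts are drawn from a negative
#' binomial with variance mu + phi mu^2. The returned truth table records
#' each gene's pattern, amplitude and the implied log2 fold change between
#' the last and first time point.
#'
#' @param trendSpecs data.frame with columns \code{pattern},
#'   \code{amplitude} (log2 units, >= 0) and \code{n_genes}.
#' @param timepoints time point labels (length >= 2).
#' @param replicates replicates per time point (>= 2).
#' @param dispersion negative-binomial dispersion phi.
#' @param baselineMean median baseline count.
#' @param baselineSdLog log-normal spread of per-gene baselines (sdlog).
#' @param batchOfReplicate batch label per replicate (default: one batch).
#' @param batchFactors named multiplicative factor per batch label.
#' @param seed integer seed; identical seeds give identical matrices.
#' @return list with \code{counts} (a \linkS4class{TimecourseCounts}) and
#'   \code{truth} (data.frame gene/pattern/amplitude/log2fc_last_vs_first).
#' @examples
#' sim <- simulateTimecourseCounts(
#'   data.frame(pattern = c("rising", "flat"), amplitude = c(3, 0),
#'              n_genes = c(5, 5)), seed = 1)
#' sim$truth[1:2, ]
#' @export
simulateTimecourseCounts <- function(trendSpecs,
                                     timepoints = c("D0", "h2", "D1",
                                                    "D2", "D4"),
                                     replicates = 3,
                                     dispersion = 0.1,
                                     baselineMean = 100,
                                     baselineSdLog = 0.7,
                                     batchOfReplicate = NULL,
                                     batchFactors = NULL,
                                     seed = 1) {
    T <- length(timepoints)
    if (T < 2) stop("need at least 2 time points")
    if (replicates < 2) stop("need at least 2 replicates per time point")
    if (any(trendSpecs$amplitude < 0)) stop("amplitudes must be >= 0")
    if (is.null(batchOfReplicate))
        batchOfReplicate <- rep("b1", replicates)
    if (is.null(batchFactors)) {
        batchFactors <- rep(1, length(unique(batchOfReplicate)))
        names(batchFactors) <- unique(batchOfReplicate)
    }
    set.seed(seed)
    n <- sum(trendSpecs$n_genes)
    pattern <- rep(as.character(trendSpecs$pattern), trendSpecs$n_genes)
    amplitude <- rep(trendSpecs$amplitude, trendSpecs$n_genes)
    genes <- sprintf("g%04d", seq_len(n))
    shapes <- vapply(unique(pattern), trendShape, numeric(T), T = T)
    base <- stats::rlnorm(n, meanlog = log(baselineMean),
                          sdlog = baselineSdLog)
    tp <- rep(timepoints, each = replicates)
    rep_id <- rep(seq_len(replicates), times = T)
    batch <- batchOfReplicate[rep_id]
    mu <- matrix(0, n, T * replicates)
    for (j in seq_len(T * replicates)) {
        t_idx <- match(tp[j], timepoints)
        mu[, j] <- base * 2^(amplitude * shapes[t_idx, pattern]) *
            batchFactors[batch[j]]
    }
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / dispersion),
                     n, ncol(mu))
    dimnames(counts) <- list(genes, paste(tp, rep_id, sep = "_r"))
    tc <- TimecourseCounts(counts, timepoint = tp, replicate = rep_id,
                           batch = batch)
    truth <- data.frame(gene = genes, pattern = pattern,
                        amplitude = amplitude,
                        log2fc_last_vs_first =
                            amplitude * (shapes[T, pattern] -
                                         shapes[1, pattern]))
    list(counts = tc, truth = truth)
}

#' Simulate a time-course region (ChIP-seq-like) experiment
#'
#' Plants constitutive and time-point-specific enhancer-like regions on a
#' two-chromosome toy genome, draws per-sample tag counts from a negative
#' binomial (specific regions reach \code{foldChange} at their time point),
#' scatters tag positions uniformly inside each region, and emits slightly
#' jittered per-replicate peak calls (with summits) plus replicate-private
#' noise peaks so that replicate consensus is exercised.
#'
#' @param nRegions number of planted regions.
#' @param regionWidth width of each region in bp.
#' @param timepoints time point labels.
#' @param replicates replicates per time point.
#' @param fracSpecific fraction of regions that are time-point specific.
#' @param foldChange enrichment of a specific region at its time point.
#' @param meanTags mean tag count per region per sample at baseline.
#' @param dispersion negative-binomial dispersion of tag counts.
#' @param chromSizes named chromosome lengths of the toy genome.
#' @param jitter maximal per-replicate peak boundary jitter in bp.
#' @param noisePeaksPerReplicate replicate-private spurious peaks.
#' @param seed integer seed.
#' @return list with \code{peaks} (nested list time point -> replicate ->
#'   GRanges with summits), \code{tags} (named list per sample of tag
#'   position GRanges), \code{truth} (GRanges of planted regions with class
#'   labels), and \code{counts} (TimecourseCounts of the drawn tag counts).
#' @export
simulateRegionExperiment <- function(nRegions = 150, regionWidth = 1000,
                                     timepoints = c("D0", "h2", "D1",
                                                    "D2", "D4"),
                                     replicates = 2,
                                     fracSpecific = 0.3,
                                     foldChange = 8,
                                     meanTags = 100,
                                     dispersion = 0.05,
                                     chromSizes = c(chr1 = 5e5, chr2 = 5e5),
                                     jitter = 25,
                                     noisePeaksPerReplicate = 3,
                                     seed = 1) {
    set.seed(seed)
    T <- length(timepoints)
    gap <- 2L * regionWidth
    slots_per_chrom <- floor((chromSizes - gap) / (regionWidth + gap))
    if (sum(slots_per_chrom) < nRegions)
        stop("toy genome too small for ", nRegions, " regions")
    chrom <- character(0); slot <- integer(0)
    for (ch in names(chromSizes)) {
        take <- min(slots_per_chrom[[ch]], nRegions - length(chrom))
        if (take <= 0) break
        chrom <- c(chrom, rep(ch, take))
        slot <- c(slot, seq_len(take))
    }
    starts <- (slot - 1L) * (regionWidth + gap) + gap %/% 2L
    truth <- GRanges(chrom, IRanges(starts + 1L, starts + regionWidth))
    nSpec <- round(nRegions * fracSpecific)
    cls <- c(rep(timepoints, length.out = nSpec),
             rep("constitutive", nRegions - nSpec))
    cls <- cls[sample.int(nRegions)]
    mcols(truth)$class <- cls
    mcols(truth)$id <- sprintf("r%03d", seq_len(nRegions))
    names(truth) <- mcols(truth)$id
    samples <- expand.grid(rep = seq_len(replicates), tp = timepoints,
                           stringsAsFactors = FALSE)
    sample_names <- paste(samples$tp, samples$rep, sep = "_r")
    countsM <- matrix(0L, nRegions, nrow(samples),
                      dimnames = list(names(truth), sample_names))
    tags <- vector("list", nrow(samples))
    names(tags) <- sample_names
    for (j in seq_len(nrow(samples))) {
        mu <- ifelse(cls == samples$tp[j], meanTags * foldChange, meanTags)
        cnt <- stats::rnbinom(nRegions, mu = mu, size = 1 / dispersion)
        countsM[, j] <- cnt
        pos <- unlist(lapply(seq_len(nRegions), function(i) {
            if (cnt[i] == 0) return(integer(0))
            start(truth)[i] + sample.int(regionWidth, cnt[i],
                                         replace = TRUE) - 1L
        }))
        ch <- rep(chrom, cnt)
        o <- order(ch, pos)
        tags[[j]] <- GRanges(ch[o], IRanges(pos[o], width = 1L))
    }
    peaks <- lapply(timepoints, function(tp) {
        lapply(seq_len(replicates), function(r) {
            d1 <- sample.int(2L * jitter + 1L, nRegions,
                             replace = TRUE) - jitter - 1L
            d2 <- sample.int(2L * jitter + 1L, nRegions,
                             replace = TRUE) - jitter - 1L
            gr <- GRanges(chrom,
                          IRanges(pmax(1L, start(truth) + d1),
                                  end(truth) + d2))
            mcols(gr)$summit <- start(truth) + regionWidth %/% 2L +
                sample.int(2L * jitter + 1L, nRegions,
                           replace = TRUE) - jitter - 1L
            if (noisePeaksPerReplicate > 0) {
                npos <- sample.int(as.integer(chromSizes[1]) - 200L,
                                   noisePeaksPerReplicate)
                noise <- GRanges(names(chromSizes)[1],
                                 IRanges(npos, width = 150L))
                mcols(noise)$summit <- npos + 75L
                gr <- c(gr, noise)
            }
            sort(gr)
        })
    })
    names(peaks) <- timepoints
    list(peaks = peaks, tags = tags, truth = truth,
         counts = TimecourseCounts(countsM, timepoint = samples$tp,
                                   replicate = samples$rep))
}

#' Sample a sequence instance from a PWM
#' @noRd
.samplePwmInstance <- function(pwm) {
    p <- pwm@probs
    paste(vapply(seq_len(ncol(p)), function(j)
        sample(rownames(p), 1, prob = p[, j]), character(1)), collapse = "")
}

#' Simulate foreground/background sequence sets with planted motif instances
#'
#' Foreground sequences carry one planted PWM instance with probability
#' \code{fgRate}; the instance center is placed with a Gaussian offset
#' around the sequence center to emulate summit-centrality of true binding
#' sites. Background sequences are planted at the (low) \code{bgRate} at
#' uniform positions.
#'
#' @param pwm a \linkS4class{PositionWeightMatrix}.
#' @param nForeground,nBackground sequence counts.
#' @param length sequence length in bp.
#' @param fgRate,bgRate planting probabilities in [0, 1].
#' @param offsetSd standard deviation (bp) of the planted center offset.
#' @param seed integer seed.
#' @return list with \code{fg}, \code{bg} (DNAStringSets) and \code{truth}
#'   (data.frame seq/planted/start of the planted instance, 1-based).
#' @export
simulateMotifSequences <- function(pwm, nForeground = 200, nBackground = 2000,
                                   length = 1000, fgRate = 0.6,
                                   bgRate = 0.05, offsetSd = 50, seed = 1) {
    stopifnot(fgRate >= 0, fgRate <= 1, bgRate >= 0, bgRate <= 1)
    set.seed(seed)
    L <- pwmLength(pwm)
    if (length < L) stop("sequences shorter than the motif")
    bgfreq <- pwm@background
    rand_seq <- function(n)
        vapply(seq_len(n), function(i)
            paste(sample(names(bgfreq), length, replace = TRUE,
                         prob = bgfreq), collapse = ""), character(1))
    plant <- function(seqs, rate, central) {
        n <- base::length(seqs)
        planted <- stats::runif(n) < rate
        startv <- rep(NA_integer_, n)
        for (i in which(planted)) {
            if (central) {
                cen <- round(length / 2 +
                             stats::rnorm(1, 0, offsetSd))
                s <- cen - L %/% 2L
            } else {
                s <- sample.int(length - L + 1L, 1)
            }
            s <- min(max(s, 1L), length - L + 1L)
            substr(seqs[i], s, s + L - 1L) <- .samplePwmInstance(pwm)
            startv[i] <- s
        }
        list(seqs = seqs, planted = planted, start = startv)
    }
    fg <- plant(rand_seq(nForeground), fgRate, central = TRUE)
    bg <- plant(rand_seq(nBackground), bgRate, central = FALSE)
    fgSet <- Biostrings::DNAStringSet(fg$seqs)
    names(fgSet) <- sprintf("fg_%04d", seq_len(nForeground))
    bgSet <- Biostrings::DNAStringSet(bg$seqs)
    names(bgSet) <- sprintf("bg_%04d", seq_len(nBackground))
    truth <- data.frame(
        seq = c(names(fgSet), names(bgSet)),
        set = rep(c("fg", "bg"), c(nForeground, nBackground)),
        planted = c(fg$planted, bg$planted),
        start = c(fg$start, bg$start))
    list(fg = fgSet, bg = bgSet, truth = truth)
}

#' Simulate an expression panel with controlled marker correlation
#'
#' Each TF probe is constructed as r * z + sqrt(1 - r^2) * noise where z is
#' the standardized marker profile, so the population Pearson correlation
#' with the marker equals the requested value (exactly 1 when r = 1).
#'
#' @param tfCor named numeric vector of target correlations per TF, in
#'   [-1, 1].
#' @param nSamples number of panel samples (mice / cell lines).
#' @param marker marker gene id (row name of the marker profile).
#' @param probesPerTf probes per TF (probe rows named TF_p1, TF_p2, ...).
#' @param seed integer seed.
#' @return list with \code{panel} (probes x samples matrix; first row is the
#'   marker) and \code{truth} (the \code{tfCor} vector).
#' @export
simulatePanel <- function(tfCor, nSamples = 100, marker = "Ucp1",
                          probesPerTf = 1, seed = 1) {
    stopifnot(all(tfCor >= -1 & tfCor <= 1))
    set.seed(seed)
    z <- stats::rnorm(nSamples)
    z <- (z - mean(z)) / stats::sd(z)
    rows <- list()
    rows[[marker]] <- 8 + 2 * z
    for (tf in names(tfCor)) {
        r <- tfCor[[tf]]
        for (p in seq_len(probesPerTf)) {
            eps <- stats::rnorm(nSamples)
            eps <- stats::residuals(stats::lm(eps ~ z))
            eps <- eps / stats::sd(eps)
            x <- r * z + sqrt(max(0, 1 - r^2)) * eps
            nm <- if (probesPerTf == 1) tf else paste0(tf, "_p", p)
            rows[[nm]] <- 8 + 2 * x
        }
    }
    panel <- do.call(rbind, rows)
    colnames(panel) <- sprintf("s%03d", seq_len(nSamples))
    list(panel = panel, truth = tfCor)
}

.randomKmers <- function(n, k) {
    vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
              collapse = ""), character(1))
}

#' Default sample barcode whitelist
#'
#' Deterministically generates 6-nt sample barcodes with pairwise Hamming
#' distance >= 3 (greedy selection from a seeded random pool), so one
#' mismatch can be tolerated without ambiguity.
#'
#' @param n number of barcodes.
#' @param seed integer seed.
#' @return Named character vector barcode -> sample name (S1, S2, ...).
#' @export
makeBarcodeWhitelist <- function(n, seed = 99) {
    set.seed(seed)
    pool <- unique(.randomKmers(50 * n, 6))
    chosen <- character(0)
    for (bc in pool) {
        if (all(vapply(chosen, function(x) .hamming(x, bc) >= 3,
                       logical(1)))) {
            chosen <- c(chosen, bc)
            if (base::length(chosen) == n) break
        }
    }
    if (base::length(chosen) < n) stop("could not build whitelist")
    stats::setNames(paste0("S", seq_len(n)), chosen)
}

.hamming <- function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

#' Simulate paired barcoded 3' mRNA-seq reads
#'
#' Read 1 carries a 6-nt sample barcode, a 15-nt unique molecular identifier
#' and an oligo-dT remainder; read 2 is a fragment of a toy transcript. Each
#' planted molecule gets one read pair plus a duplicate pair with
#' probability \code{duplicateRate}, so UMI-collapsed counts recover the
#' truth while raw read counts exceed it.
#'
#' @param truthCounts gene x sample integer matrix of molecule counts.
#' @param whitelist named vector barcode -> sample (names are barcodes);
#'   must cover all columns of \code{truthCounts}.
#' @param duplicateRate probability a molecule is sequenced twice.
#' @param unknownBarcodeReads extra read pairs carrying a barcode absent
#'   from the whitelist (they should end up unassigned).
#' @param readLength read 2 fragment length.
#' @param transcriptLength toy transcript length.
#' @param dir output directory for the two FASTQ files.
#' @param seed integer seed.
#' @return list with \code{fastq1}, \code{fastq2} (paths),
#'   \code{transcriptome} (DNAStringSet), \code{truth} (the input matrix)
#'   and \code{nReads} (total read pairs written).
#' @export
simulateBarcodedFastq <- function(truthCounts, whitelist,
                                  duplicateRate = 0,
                                  unknownBarcodeReads = 0,
                                  readLength = 50, transcriptLength = 200,
                                  dir = tempdir(), seed = 1) {
    set.seed(seed)
    genes <- rownames(truthCounts)
    samples <- colnames(truthCounts)
    bc_of <- stats::setNames(names(whitelist), unname(whitelist))
    miss <- setdiff(samples, names(bc_of))
    if (base::length(miss))
        stop("whitelist lacks sample(s): ", paste(miss, collapse = ", "))
    ## toy transcriptome with unique fragments
    repeat {
        tx <- .randomKmers(base::length(genes), transcriptLength)
        all_frag <- unlist(lapply(tx, function(s)
            substring(s, 1:(transcriptLength - readLength + 1),
                      readLength:transcriptLength)))
        if (!anyDuplicated(all_frag)) break
    }
    names(tx) <- genes
    r1 <- character(0); r2 <- character(0)
    for (s in samples) {
        for (g in genes) {
            k <- truthCounts[g, s]
            if (k == 0) next
            umis <- character(0)
            while (base::length(umis) < k)
                umis <- unique(c(umis, .randomKmers(k, 15)))
            umis <- umis[seq_len(k)]
            dup <- stats::runif(k) < duplicateRate
            reps <- 1L + as.integer(dup)
            starts <- sample.int(transcriptLength - readLength + 1L, k,
                                 replace = TRUE)
            frag <- substring(tx[[g]], starts, starts + readLength - 1L)
            r1 <- c(r1, rep(paste0(bc_of[s], umis,
                                   strrep("T", 30), "AA"), reps))
            r2 <- c(r2, rep(frag, reps))
        }
    }
    if (unknownBarcodeReads > 0) {
        bad <- "GGGGGG"
        while (any(vapply(names(whitelist), function(x)
            .hamming(x, bad) < 3, logical(1))))
            bad <- .randomKmers(1, 6)
        g <- genes[1]
        r1 <- c(r1, rep(paste0(bad, strrep("A", 15), strrep("T", 30), "AA"),
                        unknownBarcodeReads))
        r2 <- c(r2, rep(substr(tx[[g]], 1, readLength), unknownBarcodeReads))
    }
    o <- sample.int(base::length(r1))      # shuffle read order
    r1 <- r1[o]; r2 <- r2[o]
    fq <- function(seqs, path) {
        ids <- sprintf("@read%06d", seq_along(seqs))
        writeLines(as.vector(rbind(ids, seqs, "+",
                                   strrep("I", nchar(seqs)))), path)
        path
    }
    f1 <- file.path(dir, "sim_R1.fastq")
    f2 <- file.path(dir, "sim_R2.fastq")
    fq(r1, f1); fq(r2, f2)
    list(fastq1 = f1, fastq2 = f2,
         transcriptome = Biostrings::DNAStringSet(tx),
         truth = truthCounts, nReads = base::length(r1))
}
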