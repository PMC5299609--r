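## PWM log-odds scanning and region-level motif overrepresentation.

.logOddsMatrix <- function(pwm) {
    log2(pmax(pwm@probs, 1e-10) / pwm@background)
}

.revcompLogOdds <- function(lom) {
    lom[4:1, rev(seq_len(ncol(lom))), drop = FALSE]
}

.scanOne <- function(codes, lom) {
    L <- ncol(lom)
    nw <- length(codes) - L + 1L
    if (nw < 1) return(numeric(0))
    sc <- numeric(nw)
    for (j in seq_len(L))
        sc <- sc + lom[cbind(codes[seq_len(nw) + j - 1L], j)]
    sc                                      # NA where a window has ambiguity
}

#' Scan sequences for PWM matches
#'
#' Scores every window on both strands with the log2 odds of the PWM versus
#' its background model and reports windows at or above the threshold.
#' Windows containing ambiguous bases are skipped.
#'
#' @param seqs \code{DNAStringSet} or named character vector.
#' @param pwm a \linkS4class{PositionWeightMatrix}.
#' @param threshold scan threshold; by default a fraction of the maximal
#'   achievable score (0.8), or absolute bits with
#'   \code{thresholdType = "bits"}.
#' @param thresholdType "fraction" or "bits".
#' @return data.frame with columns pwm, seq, offset (1-based window start
#'   on the forward sequence), strand, score.
#' @export
scanPwm <- function(seqs, pwm, threshold = 0.8,
                    thresholdType = c("fraction", "bits")) {
    thresholdType <- match.arg(thresholdType)
    thr <- if (thresholdType == "fraction") threshold * maxScore(pwm)
           else threshold
    if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
    if (is.null(names(seqs))) names(seqs) <- paste0("seq_", seq_along(seqs))
    lom <- .logOddsMatrix(pwm)
    lomRc <- .revcompLogOdds(lom)
    out <- vector("list", length(seqs))
    for (i in seq_along(seqs)) {
        codes <- match(strsplit(seqs[[i]], "")[[1]], c("A", "C", "G", "T"))
        fwd <- .scanOne(codes, lom)
        rev <- .scanOne(codes, lomRc)
        hitF <- which(!is.na(fwd) & fwd >= thr)
        hitR <- which(!is.na(rev) & rev >= thr)
        if (length(hitF) + length(hitR) == 0) next
        out[[i]] <- data.frame(
            pwm = pwmName(pwm), seq = names(seqs)[i],
            offset = c(hitF, hitR),
            strand = rep(c("+", "-"), c(length(hitF), length(hitR))),
            score = c(fwd[hitF], rev[hitR]),
            stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    if (is.null(res))
        res <- data.frame(pwm = character(0), seq = character(0),
                          offset = integer(0), strand = character(0),
                          score = numeric(0))
    res
}

.hitSequences <- function(seqs, pwm, threshold, thresholdType) {
    hits <- scanPwm(seqs, pwm, threshold, thresholdType)
    unique(hits$seq)
}

#' Motif overrepresentation in foreground versus background sequences
#'
#' ZOOPS counting (a sequence counts once however many matches it carries)
#' with a one-sided hypergeometric test for foreground overrepresentation
#' and Benjamini-Hochberg adjustment over the PWM collection.
#'
#' @param fg,bg foreground / background \code{DNAStringSet}s.
#' @param pwms list of \linkS4class{PositionWeightMatrix} objects.
#' @param threshold,thresholdType scan threshold, see \code{\link{scanPwm}}.
#' @param qCutoff significance flag threshold on q (default 0.01).
#' @return data.frame (one row per scannable PWM, ordered by p) with hit
#'   counts, p, q, log2 enrichment ratio and a \code{significant} flag;
#'   PWMs longer than every sequence are excluded and listed in the
#'   \code{"excluded"} attribute.
#' @export
enrichMotifs <- function(fg, bg, pwms, threshold = 0.8,
                         thresholdType = "fraction", qCutoff = 0.01) {
    if (!length(fg) || !length(bg))
        stop("foreground and background must be non-empty")
    if (methods::is(pwms, "PositionWeightMatrix")) pwms <- list(pwms)
    maxLen <- max(c(Biostrings::width(Biostrings::DNAStringSet(fg)),
                    Biostrings::width(Biostrings::DNAStringSet(bg))))
    scannable <- vapply(pwms, pwmLength, integer(1)) <= maxLen
    excluded <- vapply(pwms[!scannable], pwmName, character(1))
    rows <- lapply(pwms[scannable], function(pwm) {
        kf <- length(.hitSequences(fg, pwm, threshold, thresholdType))
        kb <- length(.hitSequences(bg, pwm, threshold, thresholdType))
        nf <- length(fg); nb <- length(bg)
        p <- stats::phyper(kf - 1, kf + kb, nf + nb - kf - kb, nf,
                           lower.tail = FALSE)
        data.frame(pwm = pwmName(pwm), fg_with_hit = kf, fg_total = nf,
                   bg_with_hit = kb, bg_total = nb, p = p,
                   log2_ratio = log2(((kf + 0.5) / (nf + 1)) /
                                     ((kb + 0.5) / (nb + 1))),
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    if (is.null(res))
        stop("no PWM fits within the sequence lengths")
    res$q <- bhAdjust(res$p)
    res$significant <- res$q < qCutoff
    res <- res[order(res$p, res$pwm), ]
    rownames(res) <- NULL
    attr(res, "excluded") <- excluded
    res
}

#' Generate background sequence sets
#'
#' Two strategies: \code{"shuffled"} permutes the letters of each
#' foreground sequence (preserving composition and length), and
#' \code{"gc_matched_sampled"} draws genome windows of matching length
#' whose GC fraction lies within +/- 2 percentage points of the
#' corresponding foreground sequence.
#'
#' @param fg foreground \code{DNAStringSet}.
#' @param genome \code{DNAStringSet} of chromosome sequences (required for
#'   sampling mode).
#' @param mode "shuffled" or "gc_matched_sampled".
#' @param times background sequences generated per foreground sequence.
#' @param gcTol GC matching tolerance (fraction, default 0.02).
#' @param seed integer seed.
#' @return \code{DNAStringSet} of background sequences.
#' @export
generateBackground <- function(fg, genome = NULL,
                               mode = c("shuffled", "gc_matched_sampled"),
                               times = 1, gcTol = 0.02, seed = 1) {
    mode <- match.arg(mode)
    set.seed(seed)
    fgc <- as.character(fg)
    if (mode == "shuffled") {
        out <- unlist(lapply(seq_len(times), function(t)
            vapply(fgc, function(s)
                paste(sample(strsplit(s, "")[[1]]), collapse = ""),
                character(1))))
    } else {
        if (is.null(genome) || !length(genome))
            stop("sampling mode requires a genome")
        gseq <- as.character(genome)
        glen <- nchar(gseq)
        gc <- function(s) {
            n <- nchar(s)
            (n - nchar(gsub("[GCgc]", "", s))) / n
        }
        fgGc <- vapply(fgc, gc, numeric(1))
        out <- character(0)
        for (t in seq_len(times)) for (i in seq_along(fgc)) {
            L <- nchar(fgc[i])
            best <- NULL; bestDev <- Inf
            for (try in seq_len(1000)) {
                ch <- sample(seq_along(gseq), 1,
                             prob = pmax(glen - L + 1, 0))
                s0 <- sample.int(glen[ch] - L + 1L, 1)
                cand <- substr(gseq[ch], s0, s0 + L - 1L)
                dev <- abs(gc(cand) - fgGc[i])
                if (dev <= gcTol) { best <- cand; break }
                if (dev < bestDev) { best <- cand; bestDev <- dev }
            }
            out <- c(out, best)
        }
    }
    bs <- Biostrings::DNAStringSet(out)
    names(bs) <- sprintf("bg_%05d", seq_along(bs))
    bs
}

#' Motif density around peak summits
#'
#' Bins motif hit positions into fixed-width offset bins across +/-
#' \code{window} bp of each peak summit and averages over peaks, giving the
#' summit-centrality profile of a motif (a centered peak in this profile is
#' the signature of direct binding).
#'
#' @param peaks \code{GRanges} with an \code{mcols()$summit} position.
#' @param hitPositions \code{GRanges} of motif hit genomic positions
#'   (width-1).
#' @param window half-width in bp (default 500).
#' @param bin bin width in bp (default 5).
#' @return Numeric vector of mean hits per peak per bin, length
#'   2 * window / bin, named by bin start offset.
#' @export
centralityProfile <- function(peaks, hitPositions, window = 500, bin = 5) {
    if (!"summit" %in% colnames(mcols(peaks)))
        stop("peaks need a 'summit' metadata column")
    anchors <- GRanges(seqnames(peaks),
                       IRanges(mcols(peaks)$summit, width = 1L))
    prof <- signalProfile(anchors, hitPositions, window = window, bin = bin)
    colMeans(prof)
}

#' Extract fixed-width sequences centered on regions
#'
#' @param genome named \code{DNAStringSet} of chromosomes.
#' @param regions \code{GRanges}.
#' @param width extraction width in bp, centered on each region's center
#'   (clamped at chromosome ends).
#' @return \code{DNAStringSet} named by region.
#' @export
regionSequences <- function(genome, regions, width = 1000) {
    gseq <- as.character(genome)
    cen <- .regionCenter(regions)
    chr <- as.character(seqnames(regions))
    miss <- setdiff(unique(chr), names(gseq))
    if (length(miss))
        stop("genome lacks chromosome(s): ", paste(miss, collapse = ", "))
    s <- pmax(1L, cen - width %/% 2L)
    e <- pmin(nchar(gseq)[match(chr, names(gseq))], s + width - 1L)
    out <- substring(gseq[chr], s, e)
    bs <- Biostrings::DNAStringSet(out)
    names(bs) <- if (!is.null(names(regions))) names(regions)
                 else paste0("region_", seq_along(regions))
    bs
}

#' Motif enrichment in TF-bound differentially acetylated regions
#'
#' Intersects a differentially acetylated region set with a TF peak set
#' (regions with at least 1 bp of overlap are kept with their own
#' coordinates) and runs motif overrepresentation on the intersection
#' against a generated background, to find motifs co-localizing with the
#' TF in active chromatin.
#'
#' @param daRegions \code{GRanges} of differentially acetylated regions.
#' @param tfPeaks \code{GRanges} of TF ChIP peaks.
#' @param pwms list of \linkS4class{PositionWeightMatrix}.
#' @param genome \code{DNAStringSet} of chromosomes.
#' @param width sequence width extracted around each region center.
#' @param backgroundMode passed to \code{\link{generateBackground}}.
#' @param times background multiplier.
#' @param threshold scan threshold (fraction of max score).
#' @param seed seed for background generation.
#' @return \code{\link{enrichMotifs}} result, or an empty data.frame (with
#'   a warning) when the intersection is empty.
#' @export
colocalization <- function(daRegions, tfPeaks, pwms, genome, width = 1000,
                           backgroundMode = "shuffled", times = 5,
                           threshold = 0.8, seed = 1) {
    keep <- IRanges::overlapsAny(daRegions, tfPeaks, ignore.strand = TRUE)
    fgRegions <- daRegions[keep]
    if (!length(fgRegions)) {
        warning("no overlap between the region sets")
        return(data.frame())
    }
    fg <- regionSequences(genome, fgRegions, width = width)
    bg <- generateBackground(fg, genome = genome, mode = backgroundMode,
                             times = times, seed = seed)
    enrichMotifs(fg, bg, pwms, threshold = threshold)
}
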