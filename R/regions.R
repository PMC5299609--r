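## Region-level operations over time-course H3K27ac peak sets.

#' Replicate consensus peaks
#'
#' Keeps the regions supported by both replicates: every pair of peaks
#' overlapping by at least 1 bp contributes the span (union) of the two
#' peaks, and spans are merged into sorted, non-overlapping consensus
#' regions.
#'
#' @param rep1,rep2 \code{GRanges} peak sets of the two replicates.
#' @return Sorted, reduced \code{GRanges}.
#' @export
replicateConsensus <- function(rep1, rep2) {
    h <- GenomicRanges::findOverlaps(rep1, rep2, ignore.strand = TRUE)
    if (!length(h)) return(GRanges())
    q <- S4Vectors::queryHits(h); s <- S4Vectors::subjectHits(h)
    span <- GRanges(seqnames(rep1)[q],
                    IRanges(pmin(start(rep1)[q], start(rep2)[s]),
                            pmax(end(rep1)[q], end(rep2)[s])))
    sort(GenomicRanges::reduce(span))
}

#' Count tags overlapping each region, per sample
#'
#' A tag position falling inside two (overlapping) regions counts in both.
#' Tag chromosomes absent from the region set are ignored with a warning.
#'
#' @param regions \code{GRanges}; names (or \code{mcols()$id}) become row
#'   ids.
#' @param tagSets named list of per-sample tag position \code{GRanges}.
#' @param timepoint,replicate per-sample labels (parsed from names of
#'   \code{tagSets} as "<tp>_r<rep>" when omitted).
#' @return A \linkS4class{TimecourseCounts} of regions x samples.
#' @export
quantifyTags <- function(regions, tagSets, timepoint = NULL,
                         replicate = NULL) {
    ids <- names(regions)
    if (is.null(ids) && "id" %in% colnames(mcols(regions)))
        ids <- mcols(regions)$id
    if (is.null(ids)) ids <- paste0("region_", seq_along(regions))
    known <- GenomeInfoDb::seqlevels(regions)
    cnt <- vapply(tagSets, function(tags) {
        extra <- setdiff(GenomeInfoDb::seqlevels(tags), known)
        if (length(extra) &&
            sum(as.character(seqnames(tags)) %in% extra) > 0)
            warning("ignoring tags on chromosome(s) absent from regions: ",
                    paste(extra, collapse = ", "))
        suppressWarnings(
            GenomicRanges::countOverlaps(regions, tags,
                                         ignore.strand = TRUE))
    }, integer(length(regions)))
    cnt <- matrix(cnt, nrow = length(regions),
                  dimnames = list(ids, names(tagSets)))
    if (is.null(timepoint)) {
        timepoint <- sub("_r[0-9]+$", "", names(tagSets))
        replicate <- sub("^.*_r", "", names(tagSets))
    }
    TimecourseCounts(cnt, timepoint = timepoint, replicate = replicate)
}

#' Derive the differential-acetylation region catalog
#'
#' Applies the pipeline's subsetting rules to per-contrast differential
#' results over a union region set: per-time-point enriched regions (up in
#' one time point versus the mean of the others), preadipocyte-specific
#' regions (up at the first time point versus each mature time point),
#' mature-adipocyte-specific regions (up versus the first time point at
#' each mature time point, or on the pooled mature group), and consecutive
#' gains between adjacent time points. Regions qualifying for both the pre-
#' and the mature-specific set are excluded from both.
#'
#' @param results named list of \code{moderatedTest} data.frames. Needs
#'   "\code{<tp>.vs.rest}" for every time point and pairwise
#'   "\code{<a>.vs.<b>}" contrasts (plus "\code{mature.vs.<first>}" for the
#'   pooled mode).
#' @param regions union \code{GRanges}, names or \code{mcols()$id} matching
#'   the result ids.
#' @param timepoints time point labels in chronological order; the first is
#'   the preadipocyte state, all others count as mature except any listed
#'   in \code{earlyTimepoints}.
#' @param earlyTimepoints time points grouped with the preadipocyte state
#'   and excluded from the mature group (e.g. the 2 h sample).
#' @param lfc,alpha significance thresholds (defaults 2 and 0.01).
#' @param matureMode how a region qualifies as mature-specific: "any"
#'   (default) requires enrichment versus the first time point at at least
#'   one mature time point, "each" at every mature time point, "pooled"
#'   uses the single pooled-mature contrast.
#' @return A \linkS4class{DaCatalog}.
#' @export
deriveDaCatalog <- function(results, regions,
                            timepoints,
                            earlyTimepoints = intersect("h2", timepoints),
                            lfc = 2, alpha = 0.01,
                            matureMode = c("any", "each", "pooled")) {
    matureMode <- match.arg(matureMode)
    ids <- names(regions)
    if (is.null(ids) && "id" %in% colnames(mcols(regions)))
        ids <- mcols(regions)$id
    if (is.null(ids)) ids <- paste0("region_", seq_along(regions))
    names(regions) <- ids
    getRes <- function(nm) {
        if (is.null(results[[nm]])) stop("missing contrast: ", nm)
        results[[nm]]
    }
    up <- function(nm) significantFeatures(getRes(nm), lfc = lfc,
                                           alpha = alpha, direction = "up")
    subsetRegions <- function(idset) regions[intersect(ids, idset)]
    tpEnriched <- lapply(timepoints, function(tp)
        subsetRegions(up(paste0(tp, ".vs.rest"))))
    names(tpEnriched) <- timepoints
    pre <- timepoints[1]
    mature <- setdiff(timepoints, c(pre, earlyTimepoints))
    preIds <- Reduce(intersect, lapply(mature, function(tp)
        up(paste0(pre, ".vs.", tp))))
    matPer <- lapply(mature, function(tp) up(paste0(tp, ".vs.", pre)))
    matIds <- switch(matureMode,
                     any = Reduce(union, matPer),
                     each = Reduce(intersect, matPer),
                     pooled = up(paste0("mature.vs.", pre)))
    both <- intersect(preIds, matIds)
    preIds <- setdiff(preIds, both)
    matIds <- setdiff(matIds, both)
    gains <- lapply(seq_len(length(timepoints) - 1), function(i)
        subsetRegions(up(paste0(timepoints[i + 1], ".vs.", timepoints[i]))))
    names(gains) <- paste0(timepoints[-length(timepoints)], "_to_",
                           timepoints[-1])
    new("DaCatalog", unionRegions = regions,
        timepointEnriched = tpEnriched,
        preSpecific = subsetRegions(preIds),
        matureSpecific = subsetRegions(matIds),
        consecutiveGains = gains)
}

.regionCenter <- function(gr) {
    ## center of the 0-based half-open interval, returned 1-based
    floor((start(gr) - 1 + end(gr)) / 2) + 1L
}

#' Classify regions as promoter-proximal or distal
#'
#' Compares each region's center to the strand-aware promoter window
#' [TSS - upstream, TSS + downstream) of the nearest TSS (mirrored for
#' minus-strand genes) and reports the nearest gene with the signed,
#' strand-oriented distance (positive = downstream of the TSS).
#'
#' @param regions \code{GRanges}.
#' @param ann annotation data.frame as from \code{\link{readTss}}.
#' @param upstream,downstream promoter window in bp (defaults 1000 and
#'   100).
#' @return data.frame with columns id, gene, distance, class
#'   ("proximal"/"distal"; NA gene when the chromosome is unannotated).
#' @export
annotateRegions <- function(regions, ann, upstream = 1000,
                            downstream = 100) {
    if (!nrow(ann)) stop("empty annotation")
    ids <- names(regions)
    if (is.null(ids)) ids <- paste0("region_", seq_along(regions))
    cen <- .regionCenter(regions)
    chr <- as.character(seqnames(regions))
    gene <- rep(NA_character_, length(regions))
    dist <- rep(NA_integer_, length(regions))
    cls <- rep(NA_character_, length(regions))
    for (i in seq_along(regions)) {
        cand <- ann[ann$chrom == chr[i], , drop = FALSE]
        if (!nrow(cand)) next
        j <- which.min(abs(cand$tss - cen[i]))
        tss <- cand$tss[j]
        d <- if (cand$strand[j] == "+") cen[i] - tss else tss - cen[i]
        gene[i] <- cand$gene_id[j]
        dist[i] <- d
        cls[i] <- if (d >= -upstream && d < downstream) "proximal"
                  else "distal"
    }
    data.frame(id = ids, gene = gene, distance = dist, class = cls,
               stringsAsFactors = FALSE)
}

#' Binned signal profile around anchors
#'
#' Counts tag positions in fixed-width bins across a +/- \code{window}
#' region centered on each anchor (region centers, or TSS positions when a
#' strand is present: minus-strand anchors are mirrored). Column sums over a
#' profile row equal the total tag count in the window, so profiles are
#' conservative with respect to \code{\link{quantifyTags}} on the same
#' windows.
#'
#' @param anchors \code{GRanges}; width-1 ranges anchor at their position,
#'   wider ranges at their center. Minus-strand anchors are flipped.
#' @param tags tag position \code{GRanges} for one sample.
#' @param window half-width in bp (e.g. 5000 for a 10 kb window).
#' @param bin bin width in bp; must divide \code{window}.
#' @return anchors x (2 * window / bin) count matrix; column names give the
#'   bin start offsets.
#' @export
signalProfile <- function(anchors, tags, window = 5000, bin = 25) {
    if (window %% bin != 0) stop("window must be divisible by bin")
    nb <- 2L * window / bin
    cen <- ifelse(width(anchors) == 1L, start(anchors),
                  .regionCenter(anchors))
    minus <- as.logical(strand(anchors) == "-")
    win <- GRanges(seqnames(anchors),
                   IRanges(pmax(1L, cen - window), cen + window - 1L))
    prof <- matrix(0L, length(anchors), nb)
    h <- GenomicRanges::findOverlaps(win, tags, ignore.strand = TRUE)
    if (length(h)) {
        q <- S4Vectors::queryHits(h)
        pos <- start(tags)[S4Vectors::subjectHits(h)]
        off <- ifelse(minus[q], cen[q] + window - 1L - pos,
                      pos - (cen[q] - window))
        keep <- off >= 0 & off < 2L * window
        colIdx <- off[keep] %/% bin + 1L
        lin <- q[keep] + (colIdx - 1L) * length(anchors)
        prof <- matrix(tabulate(lin, nbins = length(anchors) * nb),
                       length(anchors), nb)
    }
    rownames(prof) <- if (!is.null(names(anchors))) names(anchors)
                      else paste0("anchor_", seq_along(anchors))
    colnames(prof) <- seq(-window, window - bin, by = bin)
    prof
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped (with a warning when all are zero, giving
#' p = 1). The p-value is exact (full sign-assignment enumeration) for up
#' to 25 informative pairs without ties, and uses the normal approximation
#' with continuity correction otherwise.
#'
#' @param a,b paired measurement vectors of equal length.
#' @param alternative "two.sided" (default), "greater" or "less".
#' @return list with \code{statistic} (V), \code{p.value} and \code{n}
#'   (informative pairs).
#' @export
pairedWilcoxon <- function(a, b, alternative = "two.sided") {
    if (length(a) != length(b)) stop("a and b must have equal length")
    d <- a - b
    d <- d[d != 0]
    if (!length(d)) {
        warning("all differences are zero; p = 1")
        return(list(statistic = NA_real_, p.value = 1, n = 0L))
    }
    exact <- length(d) <= 25 && !anyDuplicated(abs(d))
    wt <- suppressWarnings(
        stats::wilcox.test(d, mu = 0, alternative = alternative,
                           exact = exact, correct = TRUE))
    list(statistic = unname(wt$statistic), p.value = wt$p.value,
         n = length(d))
}
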