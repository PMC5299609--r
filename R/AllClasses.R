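#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom GenomicRanges GRanges seqnames start end width strand mcols mcols<- findOverlaps countOverlaps reduce
#' @importFrom IRanges IRanges
#' @importFrom BiocGenerics counts
NULL

## ---------------------------------------------------------------------------
## TimecourseCounts: genes-or-regions x samples integer counts with sample
## metadata (time point, replicate, batch, library size).
## ---------------------------------------------------------------------------

#' Time-course count matrix with sample metadata
#'
#' An extension of \linkS4class{SummarizedExperiment} holding a non-negative
#' integer count matrix (genes or chromatin regions in rows) together with
#' per-sample time point, replicate, batch and library-size annotation.
#' Library sizes default to column sums and may be overridden explicitly
#' (e.g. to carry pre-filtering totals through a filtering step).
#'
#' @export
setClass("TimecourseCounts", contains = "SummarizedExperiment")

setValidity("TimecourseCounts", function(object) {
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is missing")
    m <- SummarizedExperiment::assay(object, "counts")
    if (any(m < 0)) return("negative counts are not allowed")
    if (any(m != round(m))) return("counts must be integers")
    need <- c("timepoint", "replicate", "libSize")
    miss <- setdiff(need, colnames(colData(object)))
    if (length(miss))
        return(paste0("colData lacks column(s): ", paste(miss, collapse = ", ")))
    if (any(colData(object)$libSize < 0)) return("library sizes must be >= 0")
    TRUE
})

#' Construct a TimecourseCounts object
#'
#' @param counts non-negative integer matrix, features x samples. Row names
#'   identify genes or regions and must be unique.
#' @param timepoint per-sample time point labels (character or factor).
#' @param replicate per-sample replicate labels.
#' @param batch optional per-sample batch labels; defaults to a single batch.
#' @param libSize optional per-sample library sizes; defaults to column sums.
#' @return A \linkS4class{TimecourseCounts} object.
#' @examples
#' m <- matrix(rpois(12, 50), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' tc <- TimecourseCounts(m, timepoint = c("D0", "D0", "D4", "D4"),
#'                        replicate = c(1, 2, 1, 2))
#' libSizes(tc)
#' @export
TimecourseCounts <- function(counts, timepoint, replicate,
                             batch = NULL, libSize = NULL) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("f", seq_len(nrow(counts)))
    dup <- rownames(counts)[duplicated(rownames(counts))]
    if (length(dup))
        stop("duplicated row ids: ", paste(unique(dup), collapse = ", "))
    if (any(counts < 0)) stop("negative counts are not allowed")
    if (any(counts != round(counts))) stop("counts must be integers")
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("s", seq_len(ncol(counts)))
    if (length(timepoint) != ncol(counts) || length(replicate) != ncol(counts))
        stop("timepoint/replicate must have one entry per sample")
    if (is.null(batch)) batch <- rep("b1", ncol(counts))
    if (is.null(libSize)) libSize <- colSums(counts)
    cd <- DataFrame(timepoint = as.character(timepoint),
                    replicate = as.character(replicate),
                    batch = as.character(batch),
                    libSize = as.numeric(libSize),
                    row.names = colnames(counts))
    se <- SummarizedExperiment(assays = list(counts = counts), colData = cd)
    new("TimecourseCounts", se)
}

#' @describeIn TimecourseCounts raw count matrix
#' @param object a TimecourseCounts object
#' @export
setMethod("counts", "TimecourseCounts",
          function(object) SummarizedExperiment::assay(object, "counts"))

#' Sample annotation accessors
#'
#' @param object a \linkS4class{TimecourseCounts} object.
#' @return Character (or numeric, for \code{libSizes}) vector, one entry per
#'   sample.
#' @export
timepoints <- function(object) colData(object)$timepoint

#' @rdname timepoints
#' @export
replicates <- function(object) colData(object)$replicate

#' @rdname timepoints
#' @export
batches <- function(object) colData(object)$batch

#' @rdname timepoints
#' @export
libSizes <- function(object) {
    ls <- colData(object)$libSize
    names(ls) <- colnames(object)
    ls
}

setMethod("show", "TimecourseCounts", function(object) {
    cat("TimecourseCounts:", nrow(object), "features x", ncol(object),
        "samples\n")
    cat("  time points:", paste(unique(timepoints(object)), collapse = ", "),
        "\n")
    cat("  batches:", paste(unique(batches(object)), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## PositionWeightMatrix
## ---------------------------------------------------------------------------

#' Position weight matrix with background model
#'
#' Per-position nucleotide probabilities over A/C/G/T together with a
#' background nucleotide distribution, used for log-odds scanning.
#'
#' @slot name motif name.
#' @slot probs 4 x L probability matrix, rows A, C, G, T; columns sum to 1.
#' @slot background named length-4 nucleotide background summing to 1.
#' @export
setClass("PositionWeightMatrix",
         representation(name = "character", probs = "matrix",
                        background = "numeric"))

setValidity("PositionWeightMatrix", function(object) {
    p <- object@probs
    if (nrow(p) != 4 || !identical(rownames(p), c("A", "C", "G", "T")))
        return("probs must be a 4 x L matrix with rows A, C, G, T")
    if (ncol(p) < 1) return("motif must have at least one position")
    if (any(p < 0)) return("probabilities must be non-negative")
    if (any(abs(colSums(p) - 1) > 1e-9))
        return("each position's probabilities must sum to 1 (tol 1e-9)")
    b <- object@background
    if (length(b) != 4 || abs(sum(b) - 1) > 1e-9 || any(b <= 0))
        return("background must be 4 positive frequencies summing to 1")
    TRUE
})

#' Construct a PositionWeightMatrix
#'
#' @param name motif name.
#' @param probs 4 x L matrix of per-position probabilities (rows A, C, G, T).
#' @param background nucleotide background frequencies (A, C, G, T).
#' @export
PositionWeightMatrix <- function(name, probs,
                                 background = c(A = 0.25, C = 0.25,
                                                G = 0.25, T = 0.25)) {
    probs <- as.matrix(probs)
    rownames(probs) <- c("A", "C", "G", "T")
    background <- stats::setNames(as.numeric(background), c("A", "C", "G", "T"))
    new("PositionWeightMatrix", name = name, probs = probs,
        background = background)
}

#' @rdname PositionWeightMatrix
#' @param object,x a PositionWeightMatrix
#' @export
pwmName <- function(x) x@name

#' @rdname PositionWeightMatrix
#' @export
pwmLength <- function(x) ncol(x@probs)

#' Maximal achievable log-odds score (bits) of a PWM
#' @param x a \linkS4class{PositionWeightMatrix}.
#' @export
maxScore <- function(x) sum(apply(.logOddsMatrix(x), 2, max))

setMethod("show", "PositionWeightMatrix", function(object) {
    cat("PositionWeightMatrix '", object@name, "' (", ncol(object@probs),
        " bp)\n", sep = "")
    cat("  consensus:", paste(rownames(object@probs)[
        apply(object@probs, 2, which.max)], collapse = ""), "\n")
})

## ---------------------------------------------------------------------------
## FuzzyClustering
## ---------------------------------------------------------------------------

#' Fuzzy c-means clustering result
#'
#' @slot centroids c x T centroid matrix.
#' @slot membership genes x c membership matrix; rows sum to 1.
#' @slot m fuzzifier used for the fit.
#' @slot objective objective value J per iteration (non-increasing).
#' @slot dmin minimum pairwise centroid distance (cluster validity index).
#' @export
setClass("FuzzyClustering",
         representation(centroids = "matrix", membership = "matrix",
                        m = "numeric", objective = "numeric",
                        dmin = "numeric"))

setValidity("FuzzyClustering", function(object) {
    u <- object@membership
    if (any(u < -1e-12) || any(u > 1 + 1e-12))
        return("memberships must lie in [0, 1]")
    if (any(abs(rowSums(u) - 1) > 1e-9))
        return("membership rows must sum to 1 (tol 1e-9)")
    if (ncol(u) != nrow(object@centroids))
        return("membership columns must match centroid rows")
    if (object@m <= 1) return("fuzzifier m must exceed 1")
    TRUE
})

#' @rdname fcmFit
#' @param x a \linkS4class{FuzzyClustering} object.
#' @export
membership <- function(x) x@membership

#' @rdname fcmFit
#' @export
centroids <- function(x) x@centroids

#' @rdname fcmFit
#' @export
dmin <- function(x) x@dmin

#' Hard cluster assignment (argmax membership)
#' @param x a \linkS4class{FuzzyClustering} object.
#' @return Integer vector of cluster indices, named by gene.
#' @export
clusterAssignments <- function(x) {
    a <- max.col(x@membership, ties.method = "first")
    names(a) <- rownames(x@membership)
    a
}

setMethod("show", "FuzzyClustering", function(object) {
    cat("FuzzyClustering:", nrow(object@membership), "profiles,",
        nrow(object@centroids), "clusters (m =", object@m, ")\n")
    cat("  final objective:", signif(utils::tail(object@objective, 1), 6),
        " Dmin:", signif(object@dmin, 6), "\n")
})

## ---------------------------------------------------------------------------
## DaCatalog: differential-acetylation region catalog
## ---------------------------------------------------------------------------

#' Catalog of differentially acetylated region sets
#'
#' Holds the union region set plus the derived subsets: per-time-point
#' enriched regions, preadipocyte-specific and mature-adipocyte-specific
#' regions, and consecutive time-point gains. Preadipocyte- and
#' mature-specific sets are disjoint and every member region is drawn from
#' the union set.
#'
#' @export
setClass("DaCatalog",
         representation(unionRegions = "GRanges",
                        timepointEnriched = "list",
                        preSpecific = "GRanges",
                        matureSpecific = "GRanges",
                        consecutiveGains = "list"))

setValidity("DaCatalog", function(object) {
    inUnion <- function(gr) {
        if (length(gr) == 0) return(TRUE)
        hits <- GenomicRanges::findOverlaps(gr, object@unionRegions,
                                            type = "equal")
        length(unique(S4Vectors::queryHits(hits))) == length(gr)
    }
    all_sets <- c(list(object@preSpecific, object@matureSpecific),
                  object@timepointEnriched, object@consecutiveGains)
    if (!all(vapply(all_sets, inUnion, logical(1))))
        return("every catalog member must come from the union region set")
    if (length(object@preSpecific) && length(object@matureSpecific)) {
        ov <- GenomicRanges::findOverlaps(object@preSpecific,
                                          object@matureSpecific,
                                          type = "equal")
        if (length(ov))
            return("pre- and mature-specific sets must be disjoint")
    }
    TRUE
})

#' @rdname deriveDaCatalog
#' @param x a \linkS4class{DaCatalog}.
#' @export
unionRegions <- function(x) x@unionRegions

#' @rdname deriveDaCatalog
#' @export
timepointEnriched <- function(x) x@timepointEnriched

#' @rdname deriveDaCatalog
#' @export
preSpecific <- function(x) x@preSpecific

#' @rdname deriveDaCatalog
#' @export
matureSpecific <- function(x) x@matureSpecific

#' @rdname deriveDaCatalog
#' @export
consecutiveGains <- function(x) x@consecutiveGains

setMethod("show", "DaCatalog", function(object) {
    cat("DaCatalog over", length(object@unionRegions), "union regions\n")
    cat("  pre-specific:", length(object@preSpecific),
        " mature-specific:", length(object@matureSpecific), "\n")
    cat("  time-point enriched:",
        paste(vapply(object@timepointEnriched, length, integer(1)),
              collapse = "/"), "\n")
    cat("  consecutive gains:",
        paste(vapply(object@consecutiveGains, length, integer(1)),
              collapse = "/"), "\n")
})

## ---------------------------------------------------------------------------
## PerturbationNetwork
## ---------------------------------------------------------------------------

#' Curated gene regulatory network with perturbation overlay
#'
#' Nodes are genes tagged with a module (early, core, thermogenic); edges are
#' signed regulatory links (activation, inhibition, protein-protein). The
#' overlay attaches per-shRNA knockdown log2 fold changes and per-time-point
#' TF binding flags (with a promoter/intronic/intergenic location class) to
#' each node.
#'
#' @export
setClass("PerturbationNetwork",
         representation(nodes = "data.frame", edges = "data.frame",
                        overlay = "list"))

setValidity("PerturbationNetwork", function(object) {
    if (!all(c("gene", "module") %in% colnames(object@nodes)))
        return("nodes need columns 'gene' and 'module'")
    if (anyDuplicated(object@nodes$gene)) return("duplicated node genes")
    if (nrow(object@edges)) {
        if (!all(c("source", "target", "type") %in% colnames(object@edges)))
            return("edges need columns 'source', 'target', 'type'")
        ok_type <- object@edges$type %in%
            c("activation", "inhibition", "protein-protein")
        if (!all(ok_type))
            return("edge types must be activation/inhibition/protein-protein")
        ends <- c(object@edges$source, object@edges$target)
        if (!all(ends %in% object@nodes$gene))
            return("edge endpoints must be declared nodes")
    }
    if (length(object@overlay) &&
        !all(names(object@overlay) %in% object@nodes$gene))
        return("overlay entries must be keyed by node genes")
    TRUE
})

#' Construct a PerturbationNetwork
#'
#' @param nodes data.frame with columns \code{gene} and \code{module}.
#' @param edges data.frame with columns \code{source}, \code{target},
#'   \code{type} (activation/inhibition/protein-protein) and optional
#'   \code{confidence}.
#' @param overlay optional named list (per node gene) with elements
#'   \code{log2fc} (named per shRNA) and \code{binding} (data.frame with
#'   columns timepoint, bound, location).
#' @export
PerturbationNetwork <- function(nodes, edges = data.frame(), overlay = list()) {
    new("PerturbationNetwork", nodes = as.data.frame(nodes),
        edges = as.data.frame(edges), overlay = overlay)
}

#' @rdname PerturbationNetwork
#' @param x a PerturbationNetwork
#' @export
networkNodes <- function(x) x@nodes

#' @rdname PerturbationNetwork
#' @export
networkEdges <- function(x) x@edges

#' @rdname PerturbationNetwork
#' @export
networkOverlay <- function(x) x@overlay

setMethod("show", "PerturbationNetwork", function(object) {
    cat("PerturbationNetwork:", nrow(object@nodes), "nodes,",
        nrow(object@edges), "edges\n")
    if (length(object@overlay))
        cat("  overlay present for", length(object@overlay), "nodes\n")
})
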