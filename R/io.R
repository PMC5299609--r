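#' Read genomic intervals from a BED-like file
#'
#' Supports BED3 (chrom, start, end), BED4 (+ name) and a documented custom
#' "summit" dialect: BED4 plus a fifth column giving the summit offset in bp
#' from the region start (0-based, as in the file's half-open coordinates).
#' Input coordinates are 0-based half-open and are converted to the 1-based
#' closed convention of \link[GenomicRanges]{GRanges}; \code{writeBed}
#' inverts the conversion so files round-trip exactly.
#'
#' @param path path to a tab-separated BED-like file.
#' @param dialect one of "auto", "bed3", "bed4", "summit". "auto" infers the
#'   dialect from the column count.
#' @return A sorted \code{GRanges}; BED4 names in \code{mcols()$name}, summit
#'   dialect adds an absolute 1-based \code{mcols()$summit} position.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200", f)
#' readBed(f)
#' @export
readBed <- function(path, dialect = c("auto", "bed3", "bed4", "summit")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(GRanges())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    want <- switch(dialect, auto = nf[1], bed3 = 3L, bed4 = 4L, summit = 5L)
    bad <- which(nf != want)
    if (length(bad))
        stop("malformed BED line ", bad[1], ": expected ", want,
             " fields, found ", nf[bad[1]])
    m <- do.call(rbind, fields)
    start0 <- suppressWarnings(as.integer(m[, 2]))
    end0 <- suppressWarnings(as.integer(m[, 3]))
    bad <- which(is.na(start0) | is.na(end0))
    if (length(bad))
        stop("malformed BED line ", bad[1], ": non-integer coordinates")
    bad <- which(start0 >= end0)
    if (length(bad))
        stop("invalid interval at line ", bad[1], ": start >= end")
    gr <- GRanges(m[, 1], IRanges(start0 + 1L, end0))
    if (want >= 4L) mcols(gr)$name <- m[, 4]
    if (want >= 5L) {
        off <- suppressWarnings(as.integer(m[, 5]))
        bad <- which(is.na(off) | off < 0 | off >= end0 - start0)
        if (length(bad))
            stop("invalid summit offset at line ", bad[1])
        mcols(gr)$summit <- start0 + off + 1L
    }
    GenomeInfoDb::seqlevels(gr) <- sort(GenomeInfoDb::seqlevels(gr))
    sort(gr)
}

#' @rdname readBed
#' @param gr a \code{GRanges} to write.
#' @export
writeBed <- function(gr, path) {
    if (length(gr) == 0) {
        writeLines(character(0), path)
        return(invisible(path))
    }
    out <- paste(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                 sep = "\t")
    has_name <- "name" %in% colnames(mcols(gr))
    has_summit <- "summit" %in% colnames(mcols(gr))
    if (has_name || has_summit) {
        nm <- if (has_name) mcols(gr)$name else paste0("region_", seq_along(gr))
        out <- paste(out, nm, sep = "\t")
    }
    if (has_summit)
        out <- paste(out, mcols(gr)$summit - start(gr), sep = "\t")
    writeLines(out, path)
    invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Sequence letters are upper-cased; IUPAC ambiguity codes are allowed.
#'
#' @param path path to a FASTA file.
#' @return A \code{DNAStringSet}.
#' @export
readFastaSeqs <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    first <- readLines(path, n = 1)
    if (length(first) && !startsWith(first, ">"))
        stop("sequence line before header in ", path)
    x <- Biostrings::readDNAStringSet(path)
    Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' @rdname readFastaSeqs
#' @param seqs named \code{DNAStringSet} or character vector.
#' @export
writeFastaSeqs <- function(seqs, path) {
    if (!methods::is(seqs, "DNAStringSet"))
        seqs <- Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(seqs, path)
    invisible(path)
}

#' Read a TSV count table into a TimecourseCounts object
#'
#' The first column holds feature ids; remaining columns are samples whose
#' header names must all be present in the metadata table.
#'
#' @param path tab-separated count file with a header row.
#' @param metadata data.frame with rownames (or a \code{sample} column)
#'   matching the count columns and columns \code{timepoint},
#'   \code{replicate} and optionally \code{batch}.
#' @return A \linkS4class{TimecourseCounts}; library sizes are column sums.
#' @export
readCounts <- function(path, metadata) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(tab[[1]])
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
        stop("duplicated row ids: ", paste(dup, collapse = ", "))
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
        stop("counts must be non-negative integers")
    rownames(m) <- ids
    md <- as.data.frame(metadata)
    if (!is.null(md$sample)) rownames(md) <- md$sample
    miss <- setdiff(colnames(m), rownames(md))
    if (length(miss))
        stop("metadata missing for sample(s): ", paste(miss, collapse = ", "))
    md <- md[colnames(m), , drop = FALSE]
    TimecourseCounts(m, timepoint = md$timepoint, replicate = md$replicate,
                     batch = md$batch)
}

#' Write a count or numeric matrix as TSV
#' @param m matrix with row and column names.
#' @param path output path.
#' @param idColumn name for the leading id column.
#' @export
writeMatrixTsv <- function(m, path, idColumn = "id") {
    df <- data.frame(rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1] <- idColumn
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read position weight matrices from a motif text file
#'
#' The format is HOMER-like: a header line \code{>NAME} (extra tab-separated
#' fields after the name are ignored) followed by one line per motif
#' position with four whitespace-separated numbers for A, C, G, T. Rows may
#' be probabilities (summing to 1) or raw counts; counts are converted to
#' probabilities with a background-distributed pseudocount.
#'
#' @param path motif file.
#' @param format "auto" detects counts (any row sum clearly different from
#'   1); "probability" and "counts" force the interpretation.
#' @param pseudocount total pseudocount per position, distributed according
#'   to the background, applied when converting counts (default 0.8).
#' @param background nucleotide background frequencies (A, C, G, T).
#' @return A named list of \linkS4class{PositionWeightMatrix} objects.
#' @export
readPwms <- function(path, format = c("auto", "probability", "counts"),
                     pseudocount = 0.8,
                     background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
    format <- match.arg(format)
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines)]
    heads <- grep("^>", lines)
    if (!length(heads)) stop("no motif headers ('>') found in ", path)
    bounds <- c(heads, length(lines) + 1L)
    out <- list()
    for (i in seq_along(heads)) {
        name <- sub("\t.*$", "", sub("^>\\s*", "", lines[heads[i]]))
        body <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
        if (!length(body)) stop("motif '", name, "' has no positions")
        rows <- lapply(strsplit(body, "[ \t]+"), as.numeric)
        if (any(vapply(rows, length, integer(1)) != 4L) ||
            any(vapply(rows, anyNA, logical(1))))
            stop("motif '", name, "': each position needs 4 numeric values")
        m <- t(do.call(rbind, rows))        # 4 x L, rows A C G T
        sums <- colSums(m)
        if (any(sums <= 0))
            stop("motif '", name, "': position with non-positive total")
        isCounts <- switch(format,
                           counts = TRUE,
                           probability = FALSE,
                           auto = any(abs(sums - 1) > 0.01))
        if (isCounts) {
            m <- sweep(m + pseudocount * background, 2,
                       sums + pseudocount, "/")
        } else {
            m <- sweep(m, 2, sums, "/")     # renormalize tiny drift
        }
        out[[name]] <- PositionWeightMatrix(name, m, background)
    }
    out
}

#' Read a TSS annotation table
#'
#' Tab-separated with header columns \code{gene_id}, \code{chrom},
#' \code{strand} (+/-) and \code{tss} (1-based transcription start
#' position); optional \code{start}/\code{end} columns delimit the gene body
#' (used to classify distal regions as intronic vs intergenic).
#'
#' @param path annotation TSV.
#' @return data.frame, one row per gene.
#' @export
readTss <- function(path) {
    ann <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "strand", "tss")
    miss <- setdiff(need, colnames(ann))
    if (length(miss))
        stop("annotation lacks column(s): ", paste(miss, collapse = ", "))
    if (!all(ann$strand %in% c("+", "-")))
        stop("strand must be '+' or '-'")
    if (anyDuplicated(ann$gene_id))
        stop("one record per gene_id required")
    ann
}

## ---------------------------------------------------------------------------
## Region set algebra (closed over sorted GRanges)
## ---------------------------------------------------------------------------

#' Region set algebra
#'
#' Thin, strand-blind wrappers over the \pkg{GenomicRanges} range machinery
#' so that union, intersection and subtraction on peak sets always return
#' reduced, sorted intervals.
#'
#' @param a,b \code{GRanges} region sets.
#' @return A sorted, reduced \code{GRanges}.
#' @export
regionUnion <- function(a, b) {
    GenomicRanges::reduce(c(GenomicRanges::granges(a),
                            GenomicRanges::granges(b)), ignore.strand = TRUE)
}

#' @rdname regionUnion
#' @export
regionIntersect <- function(a, b) {
    GenomicRanges::intersect(GenomicRanges::granges(a),
                             GenomicRanges::granges(b), ignore.strand = TRUE)
}

#' @rdname regionUnion
#' @export
regionSubtract <- function(a, b) {
    GenomicRanges::setdiff(GenomicRanges::granges(a),
                           GenomicRanges::granges(b), ignore.strand = TRUE)
}
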