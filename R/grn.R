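## Curated brown adipogenic gene regulatory network and the perturbation
## overlay (knockdown log2 fold changes, TF binding flags per time point).

#' Load the bundled curated brown adipogenic network
#'
#' The topology (early, core and thermogenic modules with activation,
#' inhibition and protein-protein edges) is shipped as an editable JSON
#' fixture curated from the adipogenesis literature; each edge carries a
#' confidence note. It is data, not code.
#'
#' @param path JSON network file; defaults to the bundled fixture.
#' @return A \linkS4class{PerturbationNetwork}.
#' @export
readGrn <- function(path = system.file("extdata", "brown_grn.json",
                                       package = "adipoDiff")) {
    x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    nodes <- as.data.frame(x$nodes, stringsAsFactors = FALSE)
    edges <- if (!is.null(x$edges) && length(x$edges))
        as.data.frame(x$edges, stringsAsFactors = FALSE) else data.frame()
    overlay <- list()
    if (!is.null(x$overlay)) {
        raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)$overlay
        overlay <- lapply(raw, function(o) {
            out <- list()
            if (!is.null(o$log2fc))
                out$log2fc <- vapply(o$log2fc, function(v)
                    if (is.null(v)) NA_real_ else as.numeric(v), numeric(1))
            if (!is.null(o$binding) && length(o$binding))
                out$binding <- do.call(rbind, lapply(o$binding, function(b)
                    data.frame(timepoint = b$timepoint,
                               bound = isTRUE(b$bound),
                               location = if (is.null(b$location))
                                   NA_character_ else b$location,
                               stringsAsFactors = FALSE)))
            out
        })
        names(overlay) <- names(raw)
    }
    PerturbationNetwork(nodes, edges, overlay)
}

#' @rdname readGrn
#' @param network a \linkS4class{PerturbationNetwork}.
#' @param file output path.
#' @export
writeGrn <- function(network, file) {
    overlay <- lapply(networkOverlay(network), function(o) {
        out <- list()
        if (!is.null(o$log2fc)) out$log2fc <- as.list(o$log2fc)
        if (!is.null(o$binding))
            out$binding <- lapply(seq_len(nrow(o$binding)), function(i)
                list(timepoint = o$binding$timepoint[i],
                     bound = o$binding$bound[i],
                     location = o$binding$location[i]))
        out
    })
    jsonlite::write_json(list(nodes = networkNodes(network),
                              edges = networkEdges(network),
                              overlay = overlay),
                         file, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    invisible(file)
}

#' Overlay knockdown and binding evidence on the network
#'
#' Attaches to every node the available knockdown log2 fold changes (one
#' per shRNA; missing genes are flagged with NA) and, per time point, a
#' binding flag set when a peak's nearest annotated gene is the node, with
#' a promoter / intronic / intergenic location class: promoter when the
#' peak center falls in the strand-aware promoter window, intronic when it
#' falls inside the gene body (if the annotation carries
#' \code{start}/\code{end} columns), intergenic otherwise.
#'
#' @param network a \linkS4class{PerturbationNetwork}.
#' @param kdLog2fc named list: shRNA label -> named numeric vector of
#'   log2 fold changes per gene.
#' @param peaks named list: time point -> \code{GRanges} of TF peaks.
#' @param ann TSS annotation data.frame (see \code{\link{readTss}}).
#' @param upstream,downstream promoter window (defaults 1000 / 100 bp).
#' @return The network with a filled overlay.
#' @export
overlayNetwork <- function(network, kdLog2fc = list(), peaks = list(),
                           ann = NULL, upstream = 1000, downstream = 100) {
    nodes <- networkNodes(network)$gene
    peakAnn <- lapply(peaks, function(p) {
        if (is.null(ann) || !length(p)) return(NULL)
        a <- annotateRegions(p, ann, upstream, downstream)
        a$center <- .regionCenter(p)
        a$chrom <- as.character(seqnames(p))
        a
    })
    overlay <- lapply(nodes, function(g) {
        out <- list()
        if (length(kdLog2fc))
            out$log2fc <- vapply(kdLog2fc, function(v)
                if (g %in% names(v)) unname(v[g]) else NA_real_, numeric(1))
        if (length(peakAnn)) {
            rows <- lapply(names(peakAnn), function(tp) {
                a <- peakAnn[[tp]]
                hit <- !is.null(a) && g %in% a$gene
                loc <- NA_character_
                if (hit) {
                    sub <- a[a$gene == g, , drop = FALSE]
                    j <- which.min(abs(sub$distance))
                    loc <- if (sub$class[j] == "proximal") "promoter"
                           else .distalClass(sub[j, ], ann)
                }
                data.frame(timepoint = tp, bound = hit, location = loc,
                           stringsAsFactors = FALSE)
            })
            out$binding <- do.call(rbind, rows)
        }
        out
    })
    names(overlay) <- nodes
    PerturbationNetwork(networkNodes(network), networkEdges(network),
                        overlay)
}

## gene-body lookup for distal peaks; falls back to "intergenic" when the
## annotation has no gene extents
.distalClass <- function(row, ann) {
    if (!all(c("start", "end") %in% colnames(ann))) return("intergenic")
    g <- ann[ann$gene_id == row$gene, , drop = FALSE]
    if (nrow(g) == 1 && !is.na(g$start) &&
        row$center >= g$start && row$center <= g$end) "intronic"
    else "intergenic"
}

#' Export a network to GraphML
#'
#' Nodes carry module, per-shRNA log2 fold changes and binding flags as
#' data attributes; edges carry their type and confidence. Intended for
#' graph viewers; the JSON form (\code{\link{writeGrn}}) is the loss-free
#' round-trip format.
#'
#' @param network a \linkS4class{PerturbationNetwork}.
#' @param file output path.
#' @export
exportGraphml <- function(network, file) {
    doc <- xml2::xml_new_root("graphml",
        xmlns = "http://graphml.graphdrawing.org/xmlns")
    for (k in c("module", "log2fc", "binding"))
        xml2::xml_add_child(doc, "key", id = k, `for` = "node",
                            attr.name = k, attr.type = "string")
    for (k in c("type", "confidence"))
        xml2::xml_add_child(doc, "key", id = k, `for` = "edge",
                            attr.name = k, attr.type = "string")
    g <- xml2::xml_add_child(doc, "graph", id = "grn",
                             edgedefault = "directed")
    ov <- networkOverlay(network)
    nodes <- networkNodes(network)
    for (i in seq_len(nrow(nodes))) {
        nd <- xml2::xml_add_child(g, "node", id = nodes$gene[i])
        d <- xml2::xml_add_child(nd, "data", key = "module")
        xml2::xml_text(d) <- nodes$module[i]
        o <- ov[[nodes$gene[i]]]
        if (!is.null(o$log2fc)) {
            d <- xml2::xml_add_child(nd, "data", key = "log2fc")
            xml2::xml_text(d) <- paste(names(o$log2fc),
                                       signif(o$log2fc, 4),
                                       sep = "=", collapse = ";")
        }
        if (!is.null(o$binding)) {
            d <- xml2::xml_add_child(nd, "data", key = "binding")
            b <- o$binding[o$binding$bound, , drop = FALSE]
            xml2::xml_text(d) <- paste(b$timepoint, b$location,
                                       sep = ":", collapse = ";")
        }
    }
    edges <- networkEdges(network)
    for (i in seq_len(nrow(edges))) {
        ed <- xml2::xml_add_child(g, "edge", id = paste0("e", i),
                                  source = edges$source[i],
                                  target = edges$target[i])
        d <- xml2::xml_add_child(ed, "data", key = "type")
        xml2::xml_text(d) <- edges$type[i]
        if ("confidence" %in% colnames(edges)) {
            d <- xml2::xml_add_child(ed, "data", key = "confidence")
            xml2::xml_text(d) <- as.character(edges$confidence[i])
        }
    }
    xml2::write_xml(doc, file)
    invisible(file)
}
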