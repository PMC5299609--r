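## Config-driven orchestration of the synthetic end-to-end analysis, with a
## reproducibility manifest (file hashes, seeds, versions).

#' Built-in example PWM (NFI-family-like dyad)
#'
#' A near-deterministic palindromic TTGGC-N5-GCCAA dyad motif used by the
#' synthetic pipeline and the examples; the spacer positions are uniform.
#'
#' @param name motif name.
#' @param certainty probability mass on the consensus base (default 0.95).
#' @return A \linkS4class{PositionWeightMatrix}.
#' @export
makeExamplePwm <- function(name = "NFI_dyad", certainty = 0.95) {
    consensus <- c("T", "T", "G", "G", "C", "N", "N", "N", "N", "N",
                   "G", "C", "C", "A", "A")
    p <- vapply(consensus, function(b) {
        if (b == "N") return(rep(0.25, 4))
        v <- rep((1 - certainty) / 3, 4)
        v[match(b, c("A", "C", "G", "T"))] <- certainty
        v
    }, numeric(4))
    PositionWeightMatrix(name, p)
}

#' Deterministic decoy PWM collection
#' @param n number of decoys.
#' @param length motif length.
#' @param seed integer seed.
#' @return Named list of \linkS4class{PositionWeightMatrix} objects.
#' @export
makeDecoyPwms <- function(n = 5, length = 10, seed = 7) {
    set.seed(seed)
    out <- lapply(seq_len(n), function(i) {
        p <- matrix(stats::rgamma(4 * length, shape = 0.6), 4, length)
        p <- sweep(p, 2, colSums(p), "/")
        PositionWeightMatrix(sprintf("decoy_%02d", i), p)
    })
    names(out) <- vapply(out, pwmName, character(1))
    out
}

.defaultConfig <- function() list(
    seed = 1,
    timepoints = c("D0", "h2", "D1", "D2", "D4"),
    thresholds = list(
        lfc = 2, padj = 0.01, motifQ = 0.01,
        fuzzifier = 2.057216, clusters = 4, coreMembership = 0.5,
        promoterUpstream = 1000, promoterDownstream = 100,
        profileWindow = 5000, profileBin = 25,
        centralityWindow = 500, centralityBin = 5,
        cpmThreshold = 1, cpmMinSamples = 8,
        minReads = 200, rThreshold = 0.5),
    sim = list(
        genesPerTrend = 120, nullGenes = 400, replicates = 3,
        dispersion = 0.1, baselineMean = 100, amplitude = 3,
        regions = 100, regionFold = 8, regionMeanTags = 100,
        motifForeground = 100, motifBackground = 500, motifLength = 300,
        fgMotifRate = 0.6, bgMotifRate = 0.05, offsetSd = 50,
        panelSamples = 100, panelHighR = 0.85,
        kdMolecules = 60, duplicateRate = 0.3),
    stages = list(simulate = TRUE, de = TRUE, cluster = TRUE,
                  regions = TRUE, motifs = TRUE, prioritize = TRUE,
                  kd = TRUE, grn = TRUE))

.checkKeys <- function(cfg, ref, path = "") {
    extra <- setdiff(names(cfg), names(ref))
    if (length(extra))
        stop("unknown config key(s): ",
             paste0(path, extra, collapse = ", "))
    for (nm in names(cfg))
        if (is.list(ref[[nm]]))
            .checkKeys(cfg[[nm]], ref[[nm]], paste0(path, nm, "."))
}

.mergeConfig <- function(base, override) {
    for (nm in names(override)) {
        base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]]))
            .mergeConfig(base[[nm]], override[[nm]]) else override[[nm]]
    }
    base
}

#' Build and validate a pipeline configuration
#'
#' Returns the default configuration (all thresholds, simulation sizes and
#' stage toggles) with any overrides applied. Unknown keys are rejected;
#' threshold values are type-checked before any stage runs.
#'
#' @param ... named overrides, e.g. \code{seed = 7} or
#'   \code{thresholds = list(lfc = 1.5)}.
#' @param file optional YAML file of overrides (applied before \code{...}).
#' @return Validated configuration list.
#' @export
pipelineConfig <- function(..., file = NULL) {
    cfg <- .defaultConfig()
    if (!is.null(file))
        cfg <- .mergeConfig(cfg, yaml::read_yaml(file))
    dots <- list(...)
    if (length(dots)) cfg <- .mergeConfig(cfg, dots)
    .checkKeys(cfg, .defaultConfig())
    numKeys <- setdiff(names(cfg$thresholds), character(0))
    for (nm in numKeys)
        if (!is.numeric(cfg$thresholds[[nm]]) ||
            length(cfg$thresholds[[nm]]) != 1)
            stop("threshold '", nm, "' must be a single number")
    if (!is.numeric(cfg$seed) || length(cfg$seed) != 1)
        stop("seed must be a single integer")
    cfg
}

.writeJson <- function(x, path)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")

#' Run the full synthetic pipeline
#'
#' Executes the stages in dependency order on seeded synthetic data:
#' time-course simulation, differential expression, trend clustering,
#' region catalog, motif enrichment and centrality, candidate
#' prioritization, knockdown screen processing and the network overlay.
#' All outputs are plain text (TSV/BED/JSON/GraphML) under \code{outDir};
#' a manifest with md5 hashes of every artifact, the seed and the package
#' version is written last, and the resolved configuration is stored next
#' to the outputs. Two runs with the same configuration produce
#' byte-identical manifests.
#'
#' @param config a validated \code{\link{pipelineConfig}} list.
#' @param outDir output directory (created if needed).
#' @return The manifest list, invisibly.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir) {
    .checkKeys(config, .defaultConfig())
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    th <- config$thresholds; sm <- config$sim
    tps <- config$timepoints
    seed <- as.integer(config$seed)
    files <- character(0)
    emit <- function(name, writer) {
        path <- file.path(outDir, name)
        writer(path)
        files <<- c(files, name)
        path
    }
    state <- list()

    if (isTRUE(config$stages$simulate)) {
        trends <- data.frame(
            pattern = c("rising", "early-spike", "dip-at-mid",
                        "peak-at-mid", "flat"),
            amplitude = c(rep(sm$amplitude, 4), 0),
            n_genes = c(rep(sm$genesPerTrend, 4), sm$nullGenes))
        sim <- simulateTimecourseCounts(
            trends, timepoints = tps, replicates = sm$replicates,
            dispersion = sm$dispersion, baselineMean = sm$baselineMean,
            seed = seed)
        state$sim <- sim
        emit("counts.tsv", function(p) writeMatrixTsv(counts(sim$counts),
                                                      p, "gene"))
        emit("truth_genes.tsv", function(p)
            utils::write.table(sim$truth, p, sep = "\t", quote = FALSE,
                               row.names = FALSE))
    }

    if (isTRUE(config$stages$de)) {
        res <- deTimecourse(state$sim$counts)
        state$de <- res
        deGenes <- sort(unique(unlist(lapply(
            paste0(tps, ".vs.rest"),
            function(nm) significantFeatures(res[[nm]], lfc = th$lfc,
                                             alpha = th$padj)))))
        state$deGenes <- deGenes
        emit("de_results.tsv", function(p)
            utils::write.table(do.call(rbind, res), p, sep = "\t",
                               quote = FALSE, row.names = FALSE))
        emit("de_genes.txt", function(p) writeLines(deGenes, p))
    }

    if (isTRUE(config$stages$cluster)) {
        y <- logCpm(state$sim$counts,
                    normFactors = tmmFactors(state$sim$counts))
        prof <- standardizeProfiles(y[state$deGenes, , drop = FALSE],
                                    timepoints(state$sim$counts), tps)
        fit <- fcmFit(prof, centers = th$clusters, m = th$fuzzifier)
        state$fcm <- fit
        state$profiles <- prof
        emit("cluster_membership.tsv", function(p)
            writeMatrixTsv(membership(fit), p, "gene"))
        emit("cluster_centroids.tsv", function(p) {
            ce <- centroids(fit)
            dimnames(ce) <- list(paste0("cluster", seq_len(nrow(ce))), tps)
            writeMatrixTsv(ce, p, "cluster")
        })
    }

    if (isTRUE(config$stages$regions)) {
        rex <- simulateRegionExperiment(
            nRegions = sm$regions, timepoints = tps,
            foldChange = sm$regionFold, meanTags = sm$regionMeanTags,
            seed = seed + 101L)
        cons <- lapply(rex$peaks, function(reps)
            replicateConsensus(reps[[1]], reps[[2]]))
        union <- Reduce(regionUnion, cons)
        names(union) <- sprintf("u%04d", seq_along(union))
        rc <- quantifyTags(union, rex$tags)
        rres <- deTimecourse(rc)
        cat_ <- deriveDaCatalog(rres, union, tps, lfc = th$lfc,
                                alpha = th$padj)
        state$regions <- list(rex = rex, union = union, catalog = cat_,
                              results = rres)
        emit("regions_union.bed", function(p) writeBed(union, p))
        emit("regions_pre_specific.bed", function(p)
            writeBed(preSpecific(cat_), p))
        emit("regions_mature_specific.bed", function(p)
            writeBed(matureSpecific(cat_), p))
        emit("regions_summary.json", function(p) .writeJson(list(
            union = length(union),
            pre_specific = length(preSpecific(cat_)),
            mature_specific = length(matureSpecific(cat_)),
            timepoint_enriched = lapply(timepointEnriched(cat_), length),
            consecutive_gains = lapply(consecutiveGains(cat_), length)), p))
    }

    if (isTRUE(config$stages$motifs)) {
        pwm <- makeExamplePwm()
        ms <- simulateMotifSequences(
            pwm, nForeground = sm$motifForeground,
            nBackground = sm$motifBackground, length = sm$motifLength,
            fgRate = sm$fgMotifRate, bgRate = sm$bgMotifRate,
            offsetSd = sm$offsetSd, seed = seed + 202L)
        pwms <- c(stats::setNames(list(pwm), pwmName(pwm)), makeDecoyPwms())
        enr <- enrichMotifs(ms$fg, ms$bg, pwms, qCutoff = th$motifQ)
        ## summit-centrality: each foreground sequence is one region on its
        ## own toy chromosome, summit at the sequence center
        hits <- scanPwm(ms$fg, pwm)
        L <- pwmLength(pwm)
        peaks <- GRanges(names(ms$fg),
                         IRanges(1, sm$motifLength))
        mcols(peaks)$summit <- rep(sm$motifLength %/% 2L, length(peaks))
        hitPos <- GRanges(hits$seq,
                          IRanges(hits$offset + L %/% 2L, width = 1L))
        centr <- centralityProfile(peaks, hitPos,
                                   window = th$centralityWindow,
                                   bin = th$centralityBin)
        state$motifs <- list(enrichment = enr, centrality = centr,
                             pwm = pwm, sim = ms)
        emit("motif_enrichment.tsv", function(p)
            utils::write.table(enr, p, sep = "\t", quote = FALSE,
                               row.names = FALSE))
        emit("motif_centrality.tsv", function(p)
            utils::write.table(
                data.frame(offset = as.integer(names(centr)),
                           density = unname(centr)),
                p, sep = "\t", quote = FALSE, row.names = FALSE))
    }

    if (isTRUE(config$stages$prioritize)) {
        truth <- state$sim$truth
        assign_ <- clusterAssignments(state$fcm)
        risingCl <- .majorityCluster(assign_, truth, "rising")
        rising <- intersect(names(assign_),
                            truth$gene[truth$pattern == "rising"])
        flat <- intersect(truth$gene[truth$pattern == "flat"],
                          rownames(counts(state$sim$counts)))
        tfHigh <- utils::head(rising, 6)
        tfNull <- utils::head(flat, 6)
        tfCor <- c(stats::setNames(rep(sm$panelHighR, length(tfHigh)),
                                   tfHigh),
                   stats::setNames(rep(0, length(tfNull)), tfNull))
        panels <- lapply(c(mouse = 303L, human = 404L), function(off)
            simulatePanel(tfCor, nSamples = sm$panelSamples,
                          seed = seed + off))
        pc <- lapply(panels, function(p)
            panelCorrelations(p$panel, marker = "Ucp1"))
        u <- membership(state$fcm)
        tfAll <- c(tfHigh, tfNull)
        memb <- stats::setNames(rep(0, length(tfAll)), tfAll)
        cl <- stats::setNames(rep(0L, length(tfAll)), tfAll)
        inU <- tfAll[tfAll %in% rownames(u)]
        memb[inU] <- apply(u[inU, , drop = FALSE], 1, max)
        cl[inU] <- assign_[inU]
        clusterTable <- data.frame(tf = tfAll, cluster = unname(cl),
                                   membership = unname(memb))
        topQ <- state$motifs$enrichment$q[
            state$motifs$enrichment$pwm == pwmName(state$motifs$pwm)]
        motifTable <- data.frame(tf = tfHigh[1],
                                 regionClass = c("pre", "mature"),
                                 q = topQ)
        cand <- integrateCandidates(
            clusterTable, lapply(pc, `[[`, "genes"), motifTable,
            targetCluster = risingCl,
            membershipCutoff = th$coreMembership,
            rThreshold = th$rThreshold, qThreshold = th$motifQ)
        state$prioritize <- list(candidates = cand, panels = pc,
                                 tfHigh = tfHigh, tfNull = tfNull)
        emit("candidates.tsv", function(p)
            utils::write.table(cand, p, sep = "\t", quote = FALSE,
                               row.names = FALSE))
    }

    if (isTRUE(config$stages$kd)) {
        kdTargets <- c(kd_Nfia = "Nfia", kd_Hoxa4 = "Hoxa4",
                       kd_Zfp467 = "Zfp467")
        genes <- c("Ucp1", "Nfia", "Hoxa4", "Zfp467",
                   sprintf("gene%02d", 1:16))
        samples <- c(names(kdTargets), "ctrl1", "ctrl2")
        wl <- makeBarcodeWhitelist(length(samples))
        wl <- stats::setNames(samples, names(wl))
        base <- sm$kdMolecules
        set.seed(seed + 504L)
        perGene <- pmax(5L, round(stats::rlnorm(length(genes),
                                                log(base), 0.6)))
        truthC <- matrix(rep(perGene, length(samples)),
                         length(genes), length(samples),
                         dimnames = list(genes, samples))
        for (s in names(kdTargets))
            truthC[kdTargets[[s]], s] <- round(truthC[kdTargets[[s]], s] *
                                               0.2)
        truthC["Ucp1", "kd_Nfia"] <- round(truthC["Ucp1", "kd_Nfia"] * 0.3)
        fqs <- simulateBarcodedFastq(truthC, wl,
                                     duplicateRate = sm$duplicateRate,
                                     dir = outDir, seed = seed + 505L)
        rs <- readStructure(wl)
        dm <- demultiplex(fqs$fastq1, fqs$fastq2, rs)
        uc <- umiCount(dm$reads, fqs$transcriptome, samples = samples)
        uc <- sampleQcFilter(uc, minReads = th$minReads)
        rep_ <- kdReport(cpm(uc$table), kdMap = kdTargets,
                         controls = intersect(c("ctrl1", "ctrl2"),
                                              colnames(uc$table)))
        state$kd <- list(umi = uc, report = rep_, truth = truthC,
                         demux = dm)
        emit("kd_counts.tsv", function(p)
            writeMatrixTsv(uc$table, p, "gene"))
        emit("kd_report.tsv", function(p)
            utils::write.table(rep_$perSample, p, sep = "\t",
                               quote = FALSE, row.names = FALSE))
        emit("kd_qc.json", function(p) .writeJson(list(
            total_reads = dm$stats$total, assigned = dm$stats$assigned,
            unassigned = dm$unassigned,
            duplication_rate = uc$duplicationRate,
            dropped_samples = uc$dropped), p))
        unlink(c(fqs$fastq1, fqs$fastq2))
    }

    if (isTRUE(config$stages$grn)) {
        net <- readGrn()
        kdFc <- list()
        if (!is.null(state$kd)) {
            tab <- cpm(state$kd$umi$table)
            ctrls <- intersect(c("ctrl1", "ctrl2"), colnames(tab))
            for (s in setdiff(colnames(tab), ctrls))
                kdFc[[s]] <- log2((tab[, s] + 0.5) /
                                  (rowMeans(tab[, ctrls, drop = FALSE]) +
                                   0.5))
        }
        peaks <- list(); ann <- NULL
        if (!is.null(state$regions)) {
            rex <- state$regions$rex
            peaks <- list(D0 = rex$peaks$D0[[1]], D4 = rex$peaks$D4[[1]])
            nodes <- networkNodes(net)$gene
            k <- min(length(nodes), length(rex$truth))
            ann <- data.frame(gene_id = nodes[seq_len(k)],
                              chrom = as.character(
                                  seqnames(rex$truth)[seq_len(k)]),
                              strand = "+",
                              tss = .regionCenter(rex$truth)[seq_len(k)])
        }
        net <- overlayNetwork(net, kdLog2fc = kdFc, peaks = peaks,
                              ann = ann,
                              upstream = th$promoterUpstream,
                              downstream = th$promoterDownstream)
        state$grn <- net
        emit("grn_overlay.json", function(p) writeGrn(net, p))
        emit("grn.graphml", function(p) exportGraphml(net, p))
    }

    emit("config.yaml", function(p) yaml::write_yaml(config, p))
    hashes <- as.list(tools::md5sum(file.path(outDir, sort(files))))
    names(hashes) <- sort(files)
    manifest <- list(package = "adipoDiff",
                     version = as.character(utils::packageVersion(
                         "adipoDiff")),
                     seed = seed, files = hashes)
    .writeJson(manifest, file.path(outDir, "manifest.json"))
    invisible(manifest)
}

## cluster index holding the majority of genes with a given planted pattern
.majorityCluster <- function(assignments, truth, pattern) {
    g <- intersect(names(assignments), truth$gene[truth$pattern == pattern])
    if (!length(g)) return(1L)
    as.integer(names(which.max(table(assignments[g]))))
}
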