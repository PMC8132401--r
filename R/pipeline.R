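# End-to-end orchestration: simulate -> pair -> assign -> quantify ->
# classify, with a JSON run manifest. Identical config + seed gives
# identical stage outputs.

#' Default pipeline thresholds
#'
#' Every numeric rule threshold used downstream, overridable per run:
#' silencing floor (3 reads per replicate), bias ratio bounds (2 and
#' 0.5), off-SNP mismatch limit (1), specific-expression floor (3), DEH
#' cutoffs (FDR 0.01, |log2FC| 1.0), replicate-screen multiplier (k = 2),
#' and the pairing score threshold.
#'
#' @return a named list of thresholds.
#' @export
defaultThresholds <- function() {
    list(silenceMin = 3, biasHigh = 2, biasLow = 0.5,
         exclusionMean = 3, maxMismatch = 1L, specificMin = 3,
         dehFdr = 0.01, dehLfc = 1.0, screenK = 2,
         minScore = 60, nCandidates = 5L,
         vote = "strict", hesFirst = TRUE)
}

#' Assemble a pipeline run configuration
#'
#' Exactly one of `simulate` (a list of [simConfig()] arguments) or
#' `alignments` (paths to existing inputs: `bsb_fasta`, `tc_fasta`,
#' `snp_catalog`, `design`, and `sam`, a vector of per-sample SAM paths
#' named by sample id) must be given.
#'
#' @param simulate list of [simConfig()] arguments, or `NULL`.
#' @param alignments named list of input paths, or `NULL`.
#' @param orthologTable optional path to a precomputed ortholog table
#'   (`bsb_id  tc_id` TSV); when given, reciprocal-best-hit pairing is
#'   skipped.
#' @param thresholds overrides of [defaultThresholds()].
#' @param seed integer run seed; threads through every random draw.
#' @return a validated run-config list.
#' @export
runConfig <- function(simulate = NULL, alignments = NULL,
                      orthologTable = NULL, thresholds = list(),
                      seed = 1L) {
    if (is.null(simulate) == is.null(alignments))
        stop("exactly one of 'simulate' or 'alignments' must be given")
    th <- utils::modifyList(defaultThresholds(), thresholds)
    num <- th[vapply(th, is.numeric, TRUE)]
    if (any(unlist(num) <= 0))
        stop("thresholds must be positive")
    if (!is.null(alignments)) {
        need <- c("bsb_fasta", "tc_fasta", "snp_catalog", "design", "sam")
        if (!all(need %in% names(alignments)))
            stop("alignments block needs: ",
                 paste(need, collapse = ", "))
    }
    list(simulate = simulate, alignments = alignments,
         orthologTable = orthologTable, thresholds = th,
         seed = as.integer(seed))
}

#' Read a pipeline configuration from a YAML file
#'
#' @param file path to a YAML config with keys `simulate` or
#'   `alignments`, optional `ortholog_table`, `thresholds`, `seed`.
#' @return a validated run-config list (see [runConfig()]).
#' @export
readRunConfig <- function(file) {
    y <- yaml::read_yaml(file)
    runConfig(simulate = y$simulate, alignments = y$alignments,
              orthologTable = y$ortholog_table,
              thresholds = if (is.null(y$thresholds)) list()
                           else y$thresholds,
              seed = if (is.null(y$seed)) 1L else y$seed)
}

.stage <- function(manifest, name, params, n_in, n_out, t0) {
    manifest$stages[[name]] <- list(
        name = name, params = params, n_in = n_in, n_out = n_out,
        elapsed_s = round(as.numeric(Sys.time() - t0, units = "secs"), 3))
    message(sprintf("[%s] done in %.1fs (%s -> %s rows)", name,
                    manifest$stages[[name]]$elapsed_s, n_in, n_out))
    manifest
}

#' Run the whole homoeolog-expression pipeline
#'
#' Executes the stages in order, writes every stage output as TSV under
#' `outDir`, and records row counts, parameters and the seed in
#' `manifest.json`. In simulate mode the classifier's per-condition
#' calls are additionally compared with the designed truth
#' (`recovery.tsv`, plus a recovery rate in the manifest).
#'
#' @param config a run-config list from [runConfig()] /
#'   [readRunConfig()].
#' @param outDir output directory.
#' @return invisibly, a list: `counts` ([SubgenomeCounts-class]),
#'   `pairs`, `classification`, `dominance`, `deh`, `specific`,
#'   `partition`, `recovery` (simulate mode), `manifest`.
#' @export
runPipeline <- function(config, outDir) {
    config <- runConfig(config$simulate, config$alignments,
                        config$orthologTable, config$thresholds,
                        config$seed)
    th <- config$thresholds
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(seed = config$seed, thresholds = th,
                     stages = list())

    ## stage 1: inputs -----------------------------------------------------
    t0 <- Sys.time()
    truth <- NULL
    if (!is.null(config$simulate)) {
        simArgs <- config$simulate
        simArgs$seed <- config$seed
        if (!is.null(simArgs$categoryMix))
            simArgs$categoryMix <- unlist(simArgs$categoryMix)
        scfg <- do.call(simConfig, simArgs)
        study <- simulateStudy(scfg, file.path(outDir, "sim"))
        bsb <- study$sim$bsb; tc <- study$sim$tc
        snps <- study$sim$snps
        design <- study$design
        truth <- study$truth
        samFiles <- stats::setNames(design$sam, design$sample_id)
        n_in <- scfg@nPairs
    } else {
        al <- config$alignments
        bsb <- Biostrings::readDNAStringSet(al$bsb_fasta)
        tc <- Biostrings::readDNAStringSet(al$tc_fasta)
        snps <- readSnpCatalog(al$snp_catalog)
        design <- readDesign(al$design)
        samFiles <- unlist(al$sam)
        if (is.null(names(samFiles)))
            names(samFiles) <- design$sample_id
        n_in <- length(bsb)
    }
    manifest <- .stage(manifest, "inputs",
                       list(mode = if (is.null(config$simulate))
                                "alignments" else "simulate"),
                       n_in, nrow(design), t0)

    ## stage 2: ortholog pairing -------------------------------------------
    t0 <- Sys.time()
    pairs <- if (!is.null(config$orthologTable)) {
        readOrthologTable(config$orthologTable, bsb, tc)
    } else {
        reciprocalBestHits(bsb, tc,
                           scoring = scoringParams(minScore = th$minScore),
                           nCandidates = th$nCandidates)
    }
    utils::write.table(as.data.frame(pairs),
                       file.path(outDir, "pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- .stage(manifest, "pair",
                       list(method = if (is.null(config$orthologTable))
                                "reciprocal-best-hit" else "table",
                            minScore = th$minScore),
                       length(bsb), length(pairs), t0)

    ## stage 3: read assignment --------------------------------------------
    t0 <- Sys.time()
    refs <- c(bsb, tc)
    results <- lapply(design$sample_id, function(sid) {
        r <- assignSample(samFiles[[sid]], pairs, snps,
                          maxMismatch = th$maxMismatch, vote = th$vote,
                          refs = refs)
        if (nrow(r)) r$sample_id <- sid else r$sample_id <- character()
        r
    })
    results <- do.call(rbind, results)
    sc <- tallyCounts(results, design, pairs)
    writeCountsTsv(sc, file.path(outDir, "counts.tsv"))
    acct <- S4Vectors::metadata(sc)$accounting
    utils::write.table(acct, file.path(outDir, "accounting.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- .stage(manifest, "assign",
                       list(maxMismatch = th$maxMismatch, vote = th$vote),
                       nrow(results), sum(acct$assigned_bsb +
                                          acct$assigned_tc), t0)

    ## stage 4: quantification ---------------------------------------------
    t0 <- Sys.time()
    expr <- expressionMatrix(sc, k = th$screenK)
    ex <- SummarizedExperiment::assay(expr, "bsb_fpkm")
    exprLong <- data.frame(
        pair_id = rep(rownames(ex), 2L * ncol(ex)),
        sample_id = rep(rep(colnames(ex), each = nrow(ex)), 2L),
        subgenome = rep(c("BSB", "TC"), each = nrow(ex) * ncol(ex)),
        fpkm = .fmtNum(c(SummarizedExperiment::assay(expr, "bsb_fpkm"),
                         SummarizedExperiment::assay(expr, "tc_fpkm"))),
        flag = c(SummarizedExperiment::assay(expr, "bsb_flag"),
                 SummarizedExperiment::assay(expr, "tc_flag")),
        stringsAsFactors = FALSE)
    utils::write.table(exprLong, file.path(outDir, "expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    deh <- specific <- NULL
    grp <- SummarizedExperiment::colData(sc)$group
    glv <- unique(grp)
    if (length(glv) >= 2L) {
        norm <- libraryNormalize(sc)
        totn <- norm$bsb + norm$tc
        a <- totn[, grp == glv[1L], drop = FALSE]
        b <- totn[, grp == glv[2L], drop = FALSE]
        deh <- dehCall(a, b, fdr = th$dehFdr, lfcMin = th$dehLfc)
        dout <- deh
        for (cc in c("mean_a", "mean_b", "log2fc", "p", "p_adj"))
            dout[[cc]] <- .fmtNum(dout[[cc]])
        utils::write.table(dout, file.path(outDir, "deh.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        # group-specific expression on raw assigned counts
        rawTot <- bsbCounts(sc) + tcCounts(sc)
        ra <- rawTot[, grp == glv[1L], drop = FALSE]
        rb <- rawTot[, grp == glv[2L], drop = FALSE]
        specific <- data.frame(
            pair_id = rownames(rawTot),
            call = vapply(seq_len(nrow(rawTot)), function(i)
                detectSpecific(ra[i, ], rb[i, ],
                               minCount = th$specificMin),
                character(1L)),
            stringsAsFactors = FALSE)
        specific$call <- sub("-A$", paste0("-", glv[1L]), specific$call)
        specific$call <- sub("-B$", paste0("-", glv[2L]), specific$call)
        utils::write.table(specific, file.path(outDir, "specific.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest <- .stage(manifest, "quantify",
                       list(screenK = th$screenK, dehFdr = th$dehFdr,
                            dehLfc = th$dehLfc),
                       nrow(sc) * ncol(sc),
                       if (is.null(deh)) 0L else nrow(deh), t0)

    ## stage 5: classification ---------------------------------------------
    t0 <- Sys.time()
    cls <- classifyConditions(sc, silenceMin = th$silenceMin,
                              biasHigh = th$biasHigh,
                              biasLow = th$biasLow,
                              exclusionMean = th$exclusionMean,
                              hesFirst = th$hesFirst)
    clsOut <- cls
    clsOut$ratio <- .fmtNum(clsOut$ratio)
    utils::write.table(clsOut, file.path(outDir, "classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dom <- summarizeDominance(cls)
    writeDominanceSummary(dom,
                          file.path(outDir, "dominance_counts.tsv"),
                          file.path(outDir, "dominance_percent.tsv"))
    conds <- unique(cls$condition)
    partition <- NULL
    if (length(conds) >= 2L) {
        partition <- sharedSpecificPartition(
            cls[cls$condition == conds[1L], ],
            cls[cls$condition == conds[2L], ])
        utils::write.table(partition,
                           file.path(outDir, "partition.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    recovery <- NULL
    if (!is.null(truth)) {
        tr1 <- unique(truth[, c("pair_id", "group", "class_truth")])
        m <- merge(cls, tr1,
                   by.x = c("pair_id", "condition"),
                   by.y = c("pair_id", "group"))
        recovery <- m[, c("pair_id", "condition", "class_truth",
                          "category")]
        recovery$recovered <- recovery$category == recovery$class_truth
        utils::write.table(recovery, file.path(outDir, "recovery.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        manifest$recovery_rate <- mean(recovery$recovered)
    }
    manifest <- .stage(manifest, "classify",
                       list(silenceMin = th$silenceMin,
                            biasHigh = th$biasHigh,
                            biasLow = th$biasLow,
                            hesFirst = th$hesFirst),
                       nrow(cls), nrow(dom), t0)

    ## conservation check recorded in the manifest
    manifest$read_accounting <- list(
        total = sum(acct$total),
        assigned = sum(acct$assigned_bsb + acct$assigned_tc),
        ambiguous = sum(acct$ambiguous),
        uninformative = sum(acct$uninformative),
        discarded = sum(acct$discarded))
    jsonlite::write_json(manifest,
                         file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(counts = sc, pairs = pairs, classification = cls,
                   dominance = dom, deh = deh, specific = specific,
                   partition = partition, recovery = recovery,
                   manifest = manifest))
}
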