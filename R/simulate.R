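# Synthetic allodiploid study generator.
#
# Produces two parental gene sets that differ only by substitutions (so
# both copies share one coordinate system), the catalog of diagnostic
# sites, per-pair expression designs spanning silenced / biased /
# balanced / group-specific / differentially-expressed categories, and
# single-end hybrid reads with truth alignments. Every draw derives from
# the config seed, so identical configs give byte-identical outputs.

#' Generate a pair of parental transcriptomes and their SNP catalog
#'
#' The maternal (BSB) copy of each homoeolog pair is random DNA; the
#' paternal (TC) copy is the same sequence with substitutions drawn
#' independently per site at `snpRate`. Every substituted site becomes one
#' diagnostic SNP record with both alleles in each copy's (shared)
#' coordinate system.
#'
#' @param config a [SimConfig-class] object.
#' @return a list with elements `bsb` and `tc`
#'   ([Biostrings::DNAStringSet] objects named `<pair_id>_bsb` /
#'   `<pair_id>_tc`), `snps` (data.frame `pair_id`, `bsb_pos`, `tc_pos`,
#'   `bsb_allele`, `tc_allele`; 1-based), `pairs` (the ortholog truth:
#'   `pair_id`, `bsb_id`, `tc_id`, `length`) and `config`.
#' @examples
#' sim <- simulateParentalPair(simConfig(nPairs = 5, seed = 1))
#' head(sim$snps)
#' @export
simulateParentalPair <- function(config) {
    stopifnot(methods::is(config, "SimConfig"))
    methods::validObject(config)
    .withSeed(.stageSeed(config@seed, 11L), {
        n <- config@nPairs
        wid <- max(4L, nchar(as.character(n)))
        pid <- sprintf("pair%0*d", wid, seq_len(n))
        lenPool <- seq.int(config@lengthRange[1L], config@lengthRange[2L])
        lens <- lenPool[sample.int(length(lenPool), n, replace = TRUE)]
        total <- sum(lens)
        gene_of <- rep.int(seq_len(n), lens)
        pos_in <- sequence(lens)
        bsb_bases <- sample(.DNA_BASES, total, replace = TRUE)
        is_snp <- stats::runif(total) < config@snpRate
        tc_bases <- bsb_bases
        idx <- which(is_snp)
        if (length(idx)) {
            cur <- match(bsb_bases[idx], .DNA_BASES)
            shift <- sample.int(3L, length(idx), replace = TRUE)
            tc_bases[idx] <- .DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
        }
        f <- factor(gene_of, levels = seq_len(n))
        bsb <- Biostrings::DNAStringSet(
            vapply(split(bsb_bases, f), paste, "", collapse = ""))
        tc <- Biostrings::DNAStringSet(
            vapply(split(tc_bases, f), paste, "", collapse = ""))
        names(bsb) <- paste0(pid, "_bsb")
        names(tc) <- paste0(pid, "_tc")
        snps <- data.frame(
            pair_id = pid[gene_of[idx]],
            bsb_pos = pos_in[idx],
            tc_pos = pos_in[idx],
            bsb_allele = bsb_bases[idx],
            tc_allele = tc_bases[idx],
            stringsAsFactors = FALSE)
        pairs <- data.frame(
            pair_id = pid,
            bsb_id = names(bsb),
            tc_id = names(tc),
            length = lens,
            stringsAsFactors = FALSE)
        list(bsb = bsb, tc = tc, snps = snps, pairs = pairs,
             config = config)
    })
}

#' Design per-pair expression profiles (the truth table)
#'
#' Allocates each homoeolog pair to a designed category according to
#' `categoryMix` and draws the expected fragment count of each copy in
#' every (group, replicate) cell. Silenced copies get expectation exactly
#' 0 (never a Poisson draw), biased pairs use `biasRatio` (BSB-biased) or
#' its reciprocal (TC-biased), `normal` pairs draw a ratio inside
#' `normalBand`, `specific` pairs are unexpressed in one randomly chosen
#' group, and `DE` pairs carry a `deFold` fold change in group 2 relative
#' to group 1 (direction random per pair).
#'
#' @param config a [SimConfig-class] object.
#' @return a data.frame with one row per (pair, group, replicate):
#'   `pair_id`, `group`, `replicate`, `design_label` (the allocated mix
#'   category), `designed_ratio` (BSB/TC expectation ratio; `NA` when one
#'   side is silenced), `class_truth` (the homoeolog category the
#'   classifier is expected to report for that pair in that group),
#'   `bsb_expected`, `tc_expected`. The per-pair category tally is
#'   attached as `attr(, "categoryTally")`.
#' @export
designProfiles <- function(config) {
    stopifnot(methods::is(config, "SimConfig"))
    methods::validObject(config)
    .withSeed(.stageSeed(config@seed, 23L), {
        n <- config@nPairs
        wid <- max(4L, nchar(as.character(n)))
        pid <- sprintf("pair%0*d", wid, seq_len(n))
        mix <- config@categoryMix
        labels <- sample(names(mix), n, replace = TRUE, prob = mix)
        lambda <- config@depthMean * exp(stats::rnorm(n, 0, 0.25))
        ratio <- rep(NA_real_, n)
        bsb_e <- tc_e <- numeric(n)
        for (cat in unique(labels)) {
            i <- which(labels == cat)
            switch(cat,
                "BSB-HES" = { bsb_e[i] <- 0; tc_e[i] <- lambda[i]
                              ratio[i] <- NA_real_ },
                "TC-HES"  = { bsb_e[i] <- lambda[i]; tc_e[i] <- 0
                              ratio[i] <- NA_real_ },
                "BSB-HEB" = { ratio[i] <- config@biasRatio
                              tc_e[i] <- lambda[i]
                              bsb_e[i] <- lambda[i] * config@biasRatio },
                "TC-HEB"  = { ratio[i] <- 1 / config@biasRatio
                              bsb_e[i] <- lambda[i]
                              tc_e[i] <- lambda[i] * config@biasRatio },
                { # normal, specific, DE: balanced-ish baseline ratio
                  r <- exp(stats::runif(length(i),
                                        log(config@normalBand[1L]),
                                        log(config@normalBand[2L])))
                  ratio[i] <- r
                  tc_e[i] <- lambda[i]
                  bsb_e[i] <- lambda[i] * r })
        }
        zero_group <- rep(NA_integer_, n)
        zero_group[labels == "specific"] <-
            sample.int(config@nGroups, sum(labels == "specific"),
                       replace = TRUE)
        de_up <- rep(NA, n)
        de_up[labels == "DE"] <-
            sample(c(TRUE, FALSE), sum(labels == "DE"), replace = TRUE)

        grid <- expand.grid(replicate = seq_len(config@nReplicates),
                            group = seq_len(config@nGroups),
                            pair = seq_len(n))
        p <- grid$pair; g <- grid$group
        be <- bsb_e[p]; te <- tc_e[p]
        # group effects
        sp <- !is.na(zero_group[p]) & zero_group[p] == g
        be[sp] <- 0; te[sp] <- 0
        de2 <- !is.na(de_up[p]) & g == 2L
        fold <- ifelse(de_up[p][de2], config@deFold, 1 / config@deFold)
        be[de2] <- be[de2] * fold
        te[de2] <- te[de2] * fold

        cls <- labels[p]
        cls[labels[p] %in% c("DE", "specific")] <- "normal"
        cls[sp] <- "excluded"
        truth <- data.frame(
            pair_id = pid[p],
            group = paste0("G", g),
            replicate = grid$replicate,
            design_label = labels[p],
            designed_ratio = ratio[p],
            class_truth = cls,
            bsb_expected = be,
            tc_expected = te,
            stringsAsFactors = FALSE)
        truth <- truth[order(truth$pair_id, truth$group,
                             truth$replicate), , drop = FALSE]
        rownames(truth) <- NULL
        attr(truth, "categoryTally") <-
            table(factor(labels, levels = .DESIGN_CATEGORIES))
        truth
    })
}

# Mutate sequencing errors into reads. `rd`/`pos` are parallel vectors of
# read index and 1-based position; bases are replaced by a uniformly
# chosen different base. Multiple errors in one read are applied in
# rounds so duplicated read indices do not clobber each other.
.applyErrors <- function(seqs, rd, pos) {
    if (!length(rd)) return(seqs)
    round <- stats::ave(rd, rd, FUN = seq_along)
    for (k in seq_len(max(round))) {
        i <- round == k
        r <- rd[i]; pp <- pos[i]
        cur <- substr(seqs[r], pp, pp)
        ci <- match(cur, .DNA_BASES)
        shift <- sample.int(3L, length(r), replace = TRUE)
        alt <- .DNA_BASES[((ci - 1L + shift) %% 4L) + 1L]
        s <- seqs[r]
        substr(s, pp, pp) <- alt
        seqs[r] <- s
    }
    seqs
}

# One sample's reads from one parental copy set. Returns a data.frame of
# read records (qname filled in later).
.sampleCopyReads <- function(seqChars, lens, ids, pairIds, expected,
                             readLength, errorRate) {
    nfrag <- stats::rpois(length(expected), expected)
    keep <- which(nfrag > 0L)
    if (!length(keep))
        return(data.frame(rname = character(), pair_id = character(),
                          pos = integer(), seq = character(),
                          nm = integer(), stringsAsFactors = FALSE))
    gi <- rep.int(keep, nfrag[keep])
    maxStart <- lens[gi] - readLength + 1L
    start <- 1L + as.integer(floor(stats::runif(length(gi)) * maxStart))
    seqs <- substring(seqChars[gi], start, start + readLength - 1L)
    nm <- integer(length(gi))
    if (errorRate > 0) {
        flat <- which(stats::runif(length(gi) * readLength) < errorRate)
        if (length(flat)) {
            rd <- ((flat - 1L) %/% readLength) + 1L
            pos <- ((flat - 1L) %% readLength) + 1L
            seqs <- .applyErrors(seqs, rd, pos)
            nm <- tabulate(rd, nbins = length(gi))
        }
    }
    data.frame(rname = ids[gi], pair_id = pairIds[gi], pos = start,
               seq = seqs, nm = nm, stringsAsFactors = FALSE)
}

.samHeader <- function(ids, lens) {
    c("@HD\tVN:1.6\tSO:unknown",
      sprintf("@SQ\tSN:%s\tLN:%d", ids, lens))
}

#' Simulate hybrid reads with truth alignments
#'
#' For every (group, replicate) sample, fragment counts per homoeolog copy
#' are drawn Poisson around the designed expectation (copies designed
#' silent emit exactly zero reads), read starts are uniform on the copy,
#' and bases are flipped independently at `errorRate` (to a uniformly
#' chosen different base). Reads are written as Phred+33 FASTQ and as SAM
#' records aligned to their true source copy (tags: `NM` introduced-error
#' count, `XP` pair id, `XC` source subgenome).
#'
#' @param sim output of [simulateParentalPair()].
#' @param truth output of [designProfiles()] from the same config.
#' @param outDir directory for the per-sample FASTQ/SAM files.
#' @return the study design as a data.frame: `sample_id`, `group`,
#'   `replicate`, `tissue`, `fastq`, `sam`, `n_reads`.
#' @export
simulateReads <- function(sim, truth, outDir) {
    config <- sim$config
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    L <- config@readLength
    bsbChars <- as.character(sim$bsb)
    tcChars <- as.character(sim$tc)
    lens <- sim$pairs$length
    header <- .samHeader(c(sim$pairs$bsb_id, sim$pairs$tc_id),
                         c(lens, lens))
    qual <- strrep("I", L)
    groups <- sort(unique(truth$group))
    design <- expand.grid(replicate = seq_len(config@nReplicates),
                          group = groups, stringsAsFactors = FALSE)
    design <- design[order(design$group, design$replicate), ,
                     drop = FALSE]
    design$sample_id <- sprintf("%s_R%d", design$group, design$replicate)
    design$tissue <- "T1"
    design$fastq <- file.path(outDir,
                              paste0("reads_", design$sample_id, ".fastq"))
    design$sam <- file.path(outDir,
                            paste0("aln_", design$sample_id, ".sam"))
    design$n_reads <- 0L

    .withSeed(.stageSeed(config@seed, 37L), {
        for (s in seq_len(nrow(design))) {
            tr <- truth[truth$group == design$group[s] &
                        truth$replicate == design$replicate[s], ,
                        drop = FALSE]
            tr <- tr[match(sim$pairs$pair_id, tr$pair_id), , drop = FALSE]
            rb <- .sampleCopyReads(bsbChars, lens, sim$pairs$bsb_id,
                                   sim$pairs$pair_id, tr$bsb_expected,
                                   L, config@errorRate)
            rt <- .sampleCopyReads(tcChars, lens, sim$pairs$tc_id,
                                   sim$pairs$pair_id, tr$tc_expected,
                                   L, config@errorRate)
            rb$copy <- rep("BSB", nrow(rb))
            rt$copy <- rep("TC", nrow(rt))
            rr <- rbind(rb, rt)
            nr <- nrow(rr)
            qname <- sprintf("%s.%06d", design$sample_id[s], seq_len(nr))
            # FASTQ
            fq <- Biostrings::QualityScaledDNAStringSet(
                Biostrings::DNAStringSet(rr$seq),
                Biostrings::PhredQuality(rep(qual, nr)))
            names(fq) <- qname
            Biostrings::writeQualityScaledXStringSet(fq, design$fastq[s])
            # truth SAM
            body <- sprintf(
                "%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d\tXP:Z:%s\tXC:Z:%s",
                qname, rr$rname, rr$pos, L, rr$seq, qual, rr$nm,
                rr$pair_id, rr$copy)
            writeLines(c(header, body), design$sam[s])
            design$n_reads[s] <- nr
        }
    })
    rownames(design) <- NULL
    design[, c("sample_id", "group", "replicate", "tissue",
               "fastq", "sam", "n_reads")]
}

#' Run the generator end-to-end and write all study files
#'
#' Convenience wrapper: parental FASTAs, SNP catalog (TSV and per-parent
#' minimal VCFs), ortholog truth table, design table, per-pair truth
#' table, per-sample FASTQ/SAM, and the config as a YAML file.
#'
#' @param config a [SimConfig-class] object.
#' @param outDir output directory (created if needed).
#' @return a list: `sim` (see [simulateParentalPair()]), `truth`,
#'   `design`, and `files` (named paths of everything written).
#' @export
simulateStudy <- function(config, outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    sim <- simulateParentalPair(config)
    truth <- designProfiles(config)
    design <- simulateReads(sim, truth, outDir)
    files <- c(
        bsb_fasta = file.path(outDir, "bsb.fa"),
        tc_fasta = file.path(outDir, "tc.fa"),
        snp_catalog = file.path(outDir, "snp_catalog.tsv"),
        snp_vcf_bsb = file.path(outDir, "snp_bsb.vcf"),
        snp_vcf_tc = file.path(outDir, "snp_tc.vcf"),
        ortholog_truth = file.path(outDir, "ortholog_truth.tsv"),
        truth = file.path(outDir, "truth.tsv"),
        design = file.path(outDir, "design.tsv"),
        config = file.path(outDir, "config.yaml"))
    Biostrings::writeXStringSet(sim$bsb, files["bsb_fasta"])
    Biostrings::writeXStringSet(sim$tc, files["tc_fasta"])
    writeSnpCatalog(sim$snps, files["snp_catalog"])
    writeSnpVcf(sim$snps, sim$pairs, files["snp_vcf_bsb"], "BSB")
    writeSnpVcf(sim$snps, sim$pairs, files["snp_vcf_tc"], "TC")
    utils::write.table(sim$pairs[, c("bsb_id", "tc_id")],
                       files["ortholog_truth"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(truth, files["truth"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
        design[, c("sample_id", "group", "replicate", "tissue")],
        files["design"], sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(.configAsList(config), files["config"])
    list(sim = sim, truth = truth, design = design, files = files)
}

.configAsList <- function(config) {
    sl <- methods::slotNames("SimConfig")
    out <- lapply(sl, methods::slot, object = config)
    names(out) <- sl
    out$categoryMix <- as.list(config@categoryMix)
    out
}
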