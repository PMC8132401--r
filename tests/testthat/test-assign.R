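# Mismatch filtering and SNP-based subgenome assignment.

test_that("the off-SNP mismatch filter keeps and discards correctly", {
    tp <- toy_pair()
    perfect <- substr(tp$bsb, 1, 40)             # exact BSB read
    two_mm <- perfect
    substr(two_mm, 2, 2) <- if (substr(two_mm, 2, 2) == "A") "C" else "A"
    substr(two_mm, 5, 5) <- if (substr(two_mm, 5, 5) == "G") "T" else "G"
    # a BSB-aligned read carrying the TC alleles at the two covered
    # diagnostic sites (positions 10 and 30): its only differences from
    # the BSB copy are cataloged sites, and it matches the TC copy
    # perfectly -- it must be kept
    diag <- substr(tp$tc, 1, 40)
    sam <- write_sam(tempfile(fileext = ".sam"), tp$refs, data.frame(
        qname = c("perfect", "twomm", "diag"),
        rname = "g1_bsb", pos = 1L,
        seq = c(perfect, two_mm, diag),
        nm = c(0L, 2L, 2L), stringsAsFactors = FALSE))
    aln <- readSamAlignments(sam, tp$pairs)
    fl <- filterAlignments(aln, tp$snps, maxMismatch = 1L)
    expect_identical(
        fl$keep[match(c("perfect", "twomm", "diag"), fl$read_id)],
        c(TRUE, FALSE, TRUE))
    expect_identical(fl$mismatch_nonsnp[fl$read_id == "diag"], 0L)
    # cross-check: the kept diagnostic read matches the TC copy exactly
    expect_identical(substr(tp$tc, 1, 40),
                     fl$seq[fl$read_id == "diag"])
})

test_that("mismatches are recomputed from sequences when NM is absent", {
    tp <- toy_pair()
    r <- substr(tp$bsb, 1, 40)
    substr(r, 3, 3) <- if (substr(r, 3, 3) == "A") "C" else "A"
    sam <- write_sam(tempfile(fileext = ".sam"), tp$refs, data.frame(
        qname = "r1", rname = "g1_bsb", pos = 1L, seq = r,
        nm = NA_integer_, stringsAsFactors = FALSE))
    aln <- readSamAlignments(sam, tp$pairs)
    expect_true(is.na(aln$nm))
    expect_error(filterAlignments(aln, tp$snps), "refs")
    fl <- filterAlignments(aln, tp$snps, refs = tp$refs)
    expect_identical(fl$mismatch_nonsnp, 1L)
    expect_true(fl$keep)
})

test_that("verdicts follow the SNP alleles a read covers", {
    tp <- toy_pair()
    mk <- function(qname, seq, pos) data.frame(
        qname = qname, rname = "g1_bsb", pos = pos, seq = seq,
        nm = NA_integer_, stringsAsFactors = FALSE)
    # read over SNP 1 only (positions 1..20), pure BSB
    r_bsb <- substr(tp$bsb, 1, 20)
    # same window carrying the TC allele at site 10
    r_tc <- substr(tp$tc, 1, 20)
    # read covering no cataloged SNP (positions 31..49)
    r_none <- substr(tp$bsb, 31, 49)
    # read over SNPs 1 and 2 with one allele of each kind
    r_mix <- substr(tp$bsb, 1, 35)
    substr(r_mix, 30, 30) <- tp$snps$tc_allele[2]
    aln <- data.frame(
        read_id = c("b", "t", "none", "mix"),
        pair_id = "g1", rname = "g1_bsb", copy = "BSB",
        start = c(1L, 1L, 31L, 1L),
        end = c(20L, 20L, 49L, 35L),
        seq = c(r_bsb, r_tc, r_none, r_mix),
        nm = 0L, multi = FALSE, stringsAsFactors = FALSE)
    res <- assignReads(aln, tp$snps)
    expect_identical(setNames(res$verdict, res$read_id),
                     c(b = "BSB", t = "TC", none = "uninformative",
                       mix = "ambiguous"))
    # single-site verdicts agree with the direct two-copy comparison
    for (i in c(1, 2)) {
        o <- two_copy_oracle(aln$seq[i], aln$start[i], tp$bsb, tp$tc,
                             tp$snps$bsb_pos)
        expect_identical(res$verdict[i], o)
    }
    # majority voting resolves a 2-vs-1 split that strict calls ambiguous
    r_maj <- substr(tp$bsb, 1, 55)                   # covers all 3 SNPs
    substr(r_maj, 50, 50) <- tp$snps$tc_allele[3]
    aln2 <- data.frame(read_id = "maj", pair_id = "g1",
                       rname = "g1_bsb", copy = "BSB", start = 1L,
                       end = 55L, seq = r_maj, nm = 1L, multi = FALSE,
                       stringsAsFactors = FALSE)
    expect_identical(assignReads(aln2, tp$snps)$verdict, "ambiguous")
    expect_identical(assignReads(aln2, tp$snps, vote = "majority")$verdict,
                     "BSB")
})

test_that("a malformed catalog with out-of-gene positions errors", {
    tp <- toy_pair()
    bad <- tp$snps
    bad$bsb_pos[1] <- 999L
    aln <- data.frame(read_id = "r", pair_id = "g1", rname = "g1_bsb",
                      copy = "BSB", start = 1L, end = 20L,
                      seq = substr(tp$bsb, 1, 20), nm = 0L,
                      multi = FALSE, stringsAsFactors = FALSE)
    expect_error(assignReads(aln, bad, geneLengths = c(g1 = 60L)),
                 "malformed catalog")
})

test_that("multi-mapped reads are discarded with zeroed counters", {
    tp <- toy_pair()
    # second pair: an unrelated gene
    set.seed(123)
    g2 <- rand_dna(60)
    refs <- c(tp$refs, Biostrings::DNAStringSet(c(g2_bsb = g2,
                                                  g2_tc = g2)))
    pairs <- HomoeologPairs(bsb_id = c("g1_bsb", "g2_bsb"),
                            tc_id = c("g1_tc", "g2_tc"),
                            bsb_length = 60L, tc_length = 60L,
                            pair_id = c("g1", "g2"))
    sam <- write_sam(tempfile(fileext = ".sam"), refs, data.frame(
        qname = c("m", "m", "ok"),
        rname = c("g1_bsb", "g2_bsb", "g1_bsb"),
        pos = 1L,
        seq = c(substr(tp$bsb, 1, 20), substr(g2, 1, 20),
                substr(tp$bsb, 1, 20)),
        nm = 0L, stringsAsFactors = FALSE))
    res <- assignSample(sam, pairs, tp$snps)
    m_rows <- res[res$read_id == "m", ]
    expect_true(all(m_rows$verdict == "discarded"))
    expect_true(all(m_rows$n_snps_covered == 0L &
                    m_rows$n_bsb_alleles == 0L &
                    m_rows$n_tc_alleles == 0L))
    expect_identical(res$verdict[res$read_id == "ok"], "BSB")
})

test_that("verdict classes partition the input reads exactly", {
    cfg <- simConfig(nPairs = 15, depthMean = 12, errorRate = 0.01,
                     seed = 51)
    study <- simulateStudy(cfg, tempfile())
    pairs <- HomoeologPairs(bsb_id = study$sim$pairs$bsb_id,
                            tc_id = study$sim$pairs$tc_id,
                            bsb_length = study$sim$pairs$length,
                            tc_length = study$sim$pairs$length,
                            pair_id = study$sim$pairs$pair_id)
    res <- assignSample(study$design$sam[1], pairs, study$sim$snps)
    expect_identical(nrow(res), study$design$n_reads[1])
    expect_true(all(res$verdict %in%
        c("BSB", "TC", "ambiguous", "uninformative", "discarded")))
    expect_identical(anyDuplicated(res$read_id), 0L)
    expect_true(all(res$n_bsb_alleles + res$n_tc_alleles <=
                    res$n_snps_covered))
})

test_that("zero-error assignment recovers the truth alignments", {
    cfg <- simConfig(nPairs = 20, depthMean = 15, errorRate = 0,
                     seed = 61)
    study <- simulateStudy(cfg, tempfile())
    pairs <- HomoeologPairs(bsb_id = study$sim$pairs$bsb_id,
                            tc_id = study$sim$pairs$tc_id,
                            bsb_length = study$sim$pairs$length,
                            tc_length = study$sim$pairs$length,
                            pair_id = study$sim$pairs$pair_id)
    results <- do.call(rbind, lapply(seq_len(nrow(study$design)),
        function(s) {
            r <- assignSample(study$design$sam[s], pairs,
                              study$sim$snps)
            r$sample_id <- study$design$sample_id[s]
            r
        }))
    # no read is assigned to the wrong subgenome
    truth <- do.call(rbind, lapply(study$design$sam, read_truth_sam))
    names(truth)[names(truth) == "copy"] <- "true_copy"
    m <- merge(results, truth[, c("qname", "true_copy")],
               by.x = "read_id", by.y = "qname")
    assigned <- m[m$verdict %in% c("BSB", "TC"), ]
    expect_identical(assigned$verdict, assigned$true_copy)
    # per-copy tallies equal truth source counts minus uninformative
    sc <- tallyCounts(results, study$design, pairs)
    tr1 <- truth[truth$qname %in%
                 results$read_id[results$sample_id ==
                                 study$design$sample_id[1]], ]
    src_bsb <- table(factor(tr1$pair_id[tr1$true_copy == "BSB"],
                            levels = study$sim$pairs$pair_id))
    uninf <- m[m$verdict == "uninformative" & m$true_copy == "BSB" &
               m$sample_id == study$design$sample_id[1], ]
    uninf_bsb <- table(factor(uninf$pair_id,
                              levels = study$sim$pairs$pair_id))
    expect_identical(as.integer(bsbCounts(sc)[, 1]),
                     as.integer(src_bsb - uninf_bsb))
    # accounting conservation
    acct <- S4Vectors::metadata(sc)$accounting
    expect_identical(acct$assigned_bsb + acct$assigned_tc +
                     acct$ambiguous + acct$uninformative +
                     acct$discarded, acct$total)
})

test_that("empty assignment results give an all-zero matrix", {
    tp <- toy_pair()
    design <- data.frame(sample_id = "s1", group = "G1", replicate = 1L,
                         tissue = "T1", stringsAsFactors = FALSE)
    empty <- data.frame(read_id = character(), pair_id = character(),
                        copy = character(), verdict = character(),
                        n_snps_covered = integer(),
                        n_bsb_alleles = integer(),
                        n_tc_alleles = integer(),
                        sample_id = character(),
                        stringsAsFactors = FALSE)
    sc <- tallyCounts(empty, design, tp$pairs)
    expect_true(all(bsbCounts(sc) == 0L) && all(tcCounts(sc) == 0L))
    bad <- data.frame(read_id = "r", pair_id = "nope", copy = "BSB",
                      verdict = "BSB", n_snps_covered = 1L,
                      n_bsb_alleles = 1L, n_tc_alleles = 0L,
                      sample_id = "s1", stringsAsFactors = FALSE)
    expect_error(tallyCounts(bad, design, tp$pairs), "unknown pair_id")
})
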