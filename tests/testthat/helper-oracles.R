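# Fixture builders and independent oracles used across the suite.

rand_dna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Write a SAM file by hand. `refs` is a named character vector of
# reference sequences; `records` a data.frame with qname, rname, pos,
# seq, and optionally nm (NA/absent -> no NM tag).
write_sam <- function(path, refs, records) {
    refs <- setNames(as.character(refs), names(refs))
    hdr <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", names(refs), nchar(refs)))
    body <- vapply(seq_len(nrow(records)), function(i) {
        r <- records[i, ]
        line <- sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                        r$qname, r$rname, r$pos, nchar(r$seq), r$seq,
                        strrep("I", nchar(r$seq)))
        if (!is.null(records$nm) && !is.na(r$nm))
            line <- paste0(line, sprintf("\tNM:i:%d", r$nm))
        line
    }, character(1L))
    writeLines(c(hdr, body), path)
    path
}

# Parse the truth tags (source copy, pair, position) back out of a
# simulator SAM, independently of the package's SAM reader.
read_truth_sam <- function(path) {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "@")]
    f <- strsplit(ln, "\t", fixed = TRUE)
    data.frame(
        qname = vapply(f, `[`, "", 1L),
        rname = vapply(f, `[`, "", 3L),
        pos = as.integer(vapply(f, `[`, "", 4L)),
        seq = vapply(f, `[`, "", 10L),
        copy = sub("XC:Z:", "",
                   vapply(f, function(x) grep("^XC:Z:", x, value = TRUE),
                          "")),
        pair_id = sub("XP:Z:", "",
                      vapply(f, function(x) grep("^XP:Z:", x,
                                                 value = TRUE), "")),
        stringsAsFactors = FALSE)
}

# Brute-force Benjamini-Hochberg step-up, written from the definition.
brute_bh <- function(p) {
    n <- length(p)
    o <- order(p)
    adj_sorted <- p[o] * n / seq_len(n)
    # enforce monotonicity from the largest rank down
    for (i in (n - 1L):1L)
        adj_sorted[i] <- min(adj_sorted[i], adj_sorted[i + 1L])
    out <- numeric(n)
    out[o] <- pmin(adj_sorted, 1)
    out
}

# Brute-force two-copy comparison oracle for read assignment: count the
# read's differences against both parental copies at its alignment
# window (the copies share coordinates) and assign to the copy with
# strictly fewer differences; equal counts are ambiguous unless the read
# covers no cataloged SNP, in which case it carries no evidence at all.
two_copy_oracle <- function(seq, start, bsb_seq, tc_seq, snp_pos) {
    L <- nchar(seq)
    wb <- substr(bsb_seq, start, start + L - 1L)
    wt <- substr(tc_seq, start, start + L - 1L)
    db <- sum(charToRaw(seq) != charToRaw(wb))
    dt <- sum(charToRaw(seq) != charToRaw(wt))
    ncov <- sum(snp_pos >= start & snp_pos <= start + L - 1L)
    if (db < dt) "BSB"
    else if (dt < db) "TC"
    else if (ncov == 0L) "uninformative"
    else "ambiguous"
}

# Exhaustive all-pairs best-hit oracle: scores every (query, target)
# combination one alignment at a time and picks the maximum, breaking
# ties by the lexicographically smallest target id.
brute_best_hits <- function(query, target, scoring) {
    sub <- Biostrings::nucleotideSubstitutionMatrix(
        match = scoring$match, mismatch = scoring$mismatch)
    out <- lapply(seq_along(query), function(i) {
        sc <- vapply(seq_along(target), function(j)
            Biostrings::pairwiseAlignment(
                target[[j]], query[[i]], type = "local",
                substitutionMatrix = sub,
                gapOpening = scoring$gapOpening,
                gapExtension = scoring$gapExtension,
                scoreOnly = TRUE),
            numeric(1L))
        best <- max(sc)
        if (best < scoring$minScore) return(NULL)
        data.frame(query_id = names(query)[i],
                   target_id = sort(names(target)[sc == best])[1L],
                   score = best, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    if (is.null(out))
        data.frame(query_id = character(), target_id = character(),
                   score = numeric(), stringsAsFactors = FALSE)
    else out
}

# Two diverged 60 nt gene copies with three diagnostic sites, used by
# the read-assignment unit tests.
toy_pair <- function() {
    set.seed(99)
    bsb <- rand_dna(60)
    tc <- bsb
    snp_pos <- c(10L, 30L, 50L)
    flip <- function(b) setdiff(c("A", "C", "G", "T"), b)[1L]
    for (p in snp_pos)
        substr(tc, p, p) <- flip(substr(bsb, p, p))
    snps <- data.frame(
        pair_id = "g1",
        bsb_pos = snp_pos, tc_pos = snp_pos,
        bsb_allele = vapply(snp_pos, function(p) substr(bsb, p, p), ""),
        tc_allele = vapply(snp_pos, function(p) substr(tc, p, p), ""),
        stringsAsFactors = FALSE)
    pairs <- HomoeologPairs(bsb_id = "g1_bsb", tc_id = "g1_tc",
                            score = NA_real_, bsb_length = 60L,
                            tc_length = 60L, pair_id = "g1")
    list(bsb = bsb, tc = tc, snps = snps, pairs = pairs,
         refs = Biostrings::DNAStringSet(c(g1_bsb = bsb, g1_tc = tc)))
}
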