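# Normalization, screening and differential-expression bookkeeping.

#' Fragments per kilobase per million mapped (FPKM)
#'
#' `count / ((length/1000) * (total/1e6))`. Vectorized with the usual
#' recycling rules.
#'
#' @param count non-negative read count(s).
#' @param lengthNt transcript length(s) in nt (> 0).
#' @param totalReads library size(s): total mapped reads (> 0).
#' @return FPKM value(s); 0 exactly where `count` is 0.
#' @examples
#' fpkm(10, 2000, 1e6)  # 5
#' @export
fpkm <- function(count, lengthNt, totalReads) {
    if (any(lengthNt <= 0)) stop("gene length must be > 0")
    if (any(totalReads <= 0)) stop("library size must be > 0")
    if (any(count < 0)) stop("counts must be non-negative")
    count / ((lengthNt / 1000) * (totalReads / 1e6))
}

#' Flag outlier replicates with a mean +/- k.SD screen
#'
#' A replicate is flagged iff `|value - mean| > k * SD`, with the sample
#' SD (n-1 denominator). For n = 3 and k = 2 this is provably a no-op:
#' `max |x - mean| / SD <= (n-1)/sqrt(n) = 2/sqrt(3) < 2`, so the screen
#' can never flag anything at the default settings with triplicates.
#' This vacuity is documented rather than silently corrected; lower `k`
#' (or use more replicates) for an active screen.
#'
#' @param values numeric vector of per-replicate values for one gene.
#' @param k SD multiplier.
#' @return logical vector of flags (TRUE = outlier, excluded downstream).
#' @export
replicateScreen <- function(values, k = 2) {
    if (length(values) < 2L) {
        warning("replicate screen needs >= 2 replicates; nothing flagged")
        return(rep(FALSE, length(values)))
    }
    s <- stats::sd(values)
    if (is.na(s) || s == 0) return(rep(FALSE, length(values)))
    abs(values - mean(values)) > k * s
}

#' Library-size normalization of subgenome counts
#'
#' Divides each gene's count by its sample's total mapped reads, scaled
#' per million for readability (counts per million input reads). Between-
#' sample ratios are preserved whenever totals are equal.
#'
#' @param x a counts matrix (genes x samples) or a
#'   [SubgenomeCounts-class] object.
#' @param totals per-sample total mapped reads; taken from
#'   [sampleTotals()] for `SubgenomeCounts` input.
#' @return for a matrix, the normalized matrix; for `SubgenomeCounts`, a
#'   list with normalized `bsb` and `tc` matrices.
#' @export
libraryNormalize <- function(x, totals = NULL) {
    if (methods::is(x, "SubgenomeCounts")) {
        tt <- sampleTotals(x)
        return(list(bsb = libraryNormalize(bsbCounts(x), tt),
                    tc = libraryNormalize(tcCounts(x), tt)))
    }
    x <- as.matrix(x)
    if (is.null(totals)) stop("'totals' required for matrix input")
    if (any(totals <= 0)) stop("library totals must be > 0")
    sweep(x, 2L, totals / 1e6, "/")
}

#' FPKM expression matrices with replicate-screen flags
#'
#' Computes FPKM per subgenome from assigned counts, per-copy transcript
#' length, and the per-sample library size, and flags outlier replicates
#' within each condition group via [replicateScreen()].
#'
#' @param sc a [SubgenomeCounts-class] object with transcript lengths in
#'   `rowData`.
#' @param k SD multiplier for the screen.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assays
#'   `bsb_fpkm`, `tc_fpkm`, `bsb_flag`, `tc_flag`.
#' @export
expressionMatrix <- function(sc, k = 2) {
    rd <- SummarizedExperiment::rowData(sc)
    tt <- sampleTotals(sc)
    if (any(tt <= 0)) stop("library size must be > 0")
    # len recycles down columns; totals divide per column
    fp <- function(cnt, len)
        sweep(fpkm(cnt, len, 1e6), 2L, tt / 1e6, "/")
    bf <- fp(bsbCounts(sc), rd$bsb_length)
    tf <- fp(tcCounts(sc), rd$tc_length)
    dimnames(bf) <- dimnames(tf) <- dimnames(bsbCounts(sc))
    cond <- conditions(sc)
    flag <- function(m) {
        fl <- matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m))
        for (cc in unique(cond)) {
            j <- cond == cc
            fl[, j] <- t(apply(m[, j, drop = FALSE], 1L,
                               replicateScreen, k = k))
        }
        fl
    }
    SummarizedExperiment::SummarizedExperiment(
        assays = list(bsb_fpkm = bf, tc_fpkm = tf,
                      bsb_flag = suppressWarnings(flag(bf)),
                      tc_flag = suppressWarnings(flag(tf))),
        colData = SummarizedExperiment::colData(sc),
        rowData = rd)
}

#' Call differentially expressed homoeologous genes (DEH)
#'
#' A gene is a DEH iff its BH-adjusted p-value is below `fdr` AND
#' `|log2((meanB + pseudo) / (meanA + pseudo))| > lfcMin`. When p-values
#' are not supplied, a two-sided pooled-variance two-sample t-test on
#' `log2(value + 1)` is applied per gene. That test is a pluggable
#' stand-in -- it is NOT a negative-binomial count model -- and callers
#' with a preferred test can pass its p-values instead. Genes whose two
#' group means are exactly equal get p = 1 without testing.
#'
#' @param groupA,groupB matrices (genes x replicates) of screened,
#'   library-normalized expression values, same row order.
#' @param pValues optional per-gene raw p-values overriding the built-in
#'   test.
#' @param fdr BH-adjusted p-value threshold.
#' @param lfcMin minimum absolute log2 fold change (exclusive).
#' @param pseudo pseudo-count added to means before the ratio.
#' @return a data.frame `pair_id`, `mean_a`, `mean_b`, `log2fc`, `p`,
#'   `p_adj`, `direction` (`"up"`/`"down"` in group B, `"none"`), `deh`.
#' @export
dehCall <- function(groupA, groupB, pValues = NULL, fdr = 0.01,
                    lfcMin = 1.0, pseudo = 1) {
    groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
    stopifnot(nrow(groupA) == nrow(groupB))
    ma <- rowMeans(groupA); mb <- rowMeans(groupB)
    lfc <- log2((mb + pseudo) / (ma + pseudo))
    if (is.null(pValues)) {
        pValues <- vapply(seq_len(nrow(groupA)), function(i) {
            a <- log2(groupA[i, ] + 1); b <- log2(groupB[i, ] + 1)
            if (isTRUE(all.equal(mean(a), mean(b)))) return(1)
            tryCatch(stats::t.test(a, b, var.equal = TRUE)$p.value,
                     error = function(e)
                         if (isTRUE(all.equal(ma[i], mb[i]))) 1 else 0)
        }, numeric(1L))
    }
    p_adj <- stats::p.adjust(pValues, method = "BH")
    deh <- p_adj < fdr & abs(lfc) > lfcMin
    ids <- rownames(groupA)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(groupA)))
    data.frame(pair_id = ids, mean_a = ma, mean_b = mb, log2fc = lfc,
               p = pValues, p_adj = p_adj,
               direction = ifelse(!deh, "none",
                                  ifelse(lfc > 0, "up", "down")),
               deh = deh, row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarize a DEH table
#'
#' @param deh output of [dehCall()].
#' @return named integer vector `up`, `down`, `total` (total = up + down).
#' @export
dehSummary <- function(deh) {
    up <- sum(deh$direction == "up")
    down <- sum(deh$direction == "down")
    c(up = up, down = down, total = up + down)
}

#' Relative expression by the 2^-ddCt method
#'
#' `2^-((CtTargetSample - CtRefSample) - (CtTargetCal - CtRefCal))`.
#'
#' @param ctTargetSample,ctRefSample threshold cycles of the target and
#'   reference gene in the sample of interest.
#' @param ctTargetCal,ctRefCal the same in the calibrator sample.
#' @return relative expression (1 when both delta-Cts are equal).
#' @examples
#' ddct(24.1, 18.3, 25.0, 18.5)  # 2^0.7
#' @export
ddct <- function(ctTargetSample, ctRefSample, ctTargetCal, ctRefCal) {
    2^-((ctTargetSample - ctRefSample) - (ctTargetCal - ctRefCal))
}
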