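# Homoeolog-level classification: specific expression, silencing (HES),
# bias (HEB), and dominance summaries.
#
# Rule thresholds (all configurable): a copy counts as silenced when it
# has 0 assigned reads in every replicate while the other copy has >= 3
# in every replicate; pairs with one copy at 0 and the other averaging
# below 3 are excluded as too weakly expressed; the bias ratio (mean BSB
# / mean TC over replicates) is biased at >= 2 or <= 0.5, boundaries
# inclusive. HES is evaluated before the exclusion pre-filter by
# default: the two rules overlap exactly at (0,0,0) vs three reads per
# replicate, and HES-first keeps the silencing tally well defined there;
# `hesFirst = FALSE` applies the exclusion first instead.

#' Detect group-specific expression of a gene
#'
#' A gene is specifically expressed in group B iff its read count is 0 in
#' every replicate of group A and at least `minCount` in every replicate
#' of group B (symmetrically for A).
#'
#' @param groupA,groupB per-replicate read-count vectors, equal length.
#' @param minCount floor for the expressed group (default 3).
#' @return `"none"`, `"specific-to-A"` or `"specific-to-B"`.
#' @examples
#' detectSpecific(c(0, 0, 0), c(3, 5, 4))  # "specific-to-B"
#' @export
detectSpecific <- function(groupA, groupB, minCount = 3) {
    if (length(groupA) != length(groupB))
        stop("groups must have the same number of replicates")
    if (all(groupA == 0) && all(groupB >= minCount)) return("specific-to-B")
    if (all(groupB == 0) && all(groupA >= minCount)) return("specific-to-A")
    "none"
}

#' Classify one homoeolog pair in one condition
#'
#' @param bsb,tc per-replicate assigned read counts of the two copies.
#' @param silenceMin minimum per-replicate count of the expressed copy
#'   for a silencing call.
#' @param biasHigh,biasLow inclusive BSB/TC ratio bounds for BSB-HEB and
#'   TC-HEB.
#' @param exclusionMean mean-count floor below which a pair with one
#'   all-zero copy is excluded rather than classified.
#' @param hesFirst evaluate silencing before the exclusion pre-filter
#'   (see the note above).
#' @return one of `"BSB-HES"`, `"TC-HES"`, `"BSB-HEB"`, `"TC-HEB"`,
#'   `"normal"`, `"excluded"`.
#' @examples
#' classifyHomoeolog(c(0, 0, 0), c(5, 7, 6))     # BSB-HES
#' classifyHomoeolog(c(20, 22, 18), c(10, 11, 9)) # ratio 2 -> BSB-HEB
#' @export
classifyHomoeolog <- function(bsb, tc, silenceMin = 3, biasHigh = 2,
                              biasLow = 0.5, exclusionMean = 3,
                              hesFirst = TRUE) {
    if (length(bsb) != length(tc))
        stop("replicate vectors must have the same length")
    classifyPairs(matrix(bsb, nrow = 1L), matrix(tc, nrow = 1L),
                  silenceMin = silenceMin, biasHigh = biasHigh,
                  biasLow = biasLow, exclusionMean = exclusionMean,
                  hesFirst = hesFirst)$category
}

#' Classify all pairs of a condition (matrix form)
#'
#' Row-vectorized version of [classifyHomoeolog()].
#'
#' @param bsb,tc matrices (pairs x replicates) of assigned counts.
#' @inheritParams classifyHomoeolog
#' @return a data.frame `pair_id`, `category`, `ratio` (mean BSB / mean
#'   TC; `NA` for silenced/excluded pairs).
#' @export
classifyPairs <- function(bsb, tc, silenceMin = 3, biasHigh = 2,
                          biasLow = 0.5, exclusionMean = 3,
                          hesFirst = TRUE) {
    bsb <- as.matrix(bsb); tc <- as.matrix(tc)
    stopifnot(identical(dim(bsb), dim(tc)))
    zeroB <- rowSums(bsb != 0) == 0L
    zeroT <- rowSums(tc != 0) == 0L
    minB <- .rowMins(bsb); minT <- .rowMins(tc)
    meanB <- rowMeans(bsb); meanT <- rowMeans(tc)
    hesB <- zeroB & minT >= silenceMin
    hesT <- zeroT & minB >= silenceMin
    excl <- (zeroB & meanT < exclusionMean) |
            (zeroT & meanB < exclusionMean) |
            (zeroB & zeroT)
    ratio <- meanB / meanT
    biased_hi <- !is.na(ratio) & ratio >= biasHigh
    biased_lo <- !is.na(ratio) & ratio <= biasLow
    cat <- rep("normal", nrow(bsb))
    # last assignment wins, so order from lowest to highest precedence
    cat[biased_lo] <- "TC-HEB"
    cat[biased_hi] <- "BSB-HEB"
    if (hesFirst) {
        cat[excl] <- "excluded"
        cat[hesB] <- "BSB-HES"
        cat[hesT] <- "TC-HES"
    } else {
        cat[hesB] <- "BSB-HES"
        cat[hesT] <- "TC-HES"
        cat[excl] <- "excluded"
    }
    ratio[cat %in% c("BSB-HES", "TC-HES", "excluded")] <- NA_real_
    ids <- rownames(bsb)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(bsb)))
    data.frame(pair_id = ids, category = cat, ratio = ratio,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify every condition of a SubgenomeCounts object
#'
#' Splits samples by condition (group x tissue) and classifies each
#' homoeolog pair within each condition.
#'
#' @param sc a [SubgenomeCounts-class] object.
#' @inheritParams classifyHomoeolog
#' @return a data.frame `pair_id`, `condition`, `category`, `ratio`.
#' @export
classifyConditions <- function(sc, silenceMin = 3, biasHigh = 2,
                               biasLow = 0.5, exclusionMean = 3,
                               hesFirst = TRUE) {
    cond <- conditions(sc)
    out <- lapply(unique(cond), function(cc) {
        j <- cond == cc
        r <- classifyPairs(bsbCounts(sc)[, j, drop = FALSE],
                           tcCounts(sc)[, j, drop = FALSE],
                           silenceMin, biasHigh, biasLow,
                           exclusionMean, hesFirst)
        cbind(r[, "pair_id", drop = FALSE], condition = cc,
              r[, c("category", "ratio")])
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Dominance summary over classified homoeolog pairs
#'
#' Per condition: counts and percentages of the five reported categories
#' (`excluded` pairs are omitted from the total), the total, and the
#' dominance rollups (TC dominance = BSB-HES + TC-HEB; BSB dominance =
#' TC-HES + BSB-HEB). Percentages are 100 * count / total rounded to two
#' decimals.
#'
#' Input is either a classification data.frame (columns `condition`,
#' `category`) or a matrix/data.frame of pre-tabulated counts with
#' conditions as rows and the five category names as columns.
#'
#' @param x classification records or a count table.
#' @return a data.frame with columns `condition`, the five category
#'   counts, `total`, `tc_dominance`, `bsb_dominance`, and `pct_`
#'   twins of the five category columns.
#' @examples
#' counts <- matrix(c(4522, 2977, 243, 254, 2070), nrow = 1,
#'                  dimnames = list("C-Intestine",
#'                                  c("BSB-HES", "TC-HEB", "TC-HES",
#'                                    "BSB-HEB", "normal")))
#' summarizeDominance(counts)
#' @export
summarizeDominance <- function(x) {
    if (is.data.frame(x) && all(c("condition", "category") %in% names(x))) {
        x <- x[x$category != "excluded", , drop = FALSE]
        if (nrow(x) == 0L)
            return(.dominanceFromCounts(
                matrix(0L, 0L, 5L,
                       dimnames = list(NULL, .REPORT_CATEGORIES))))
        tab <- table(x$condition,
                     factor(x$category, levels = .REPORT_CATEGORIES))
        m <- matrix(as.integer(tab), nrow = nrow(tab),
                    dimnames = dimnames(tab))
        return(.dominanceFromCounts(m))
    }
    m <- as.matrix(x)
    if (!all(.REPORT_CATEGORIES %in% colnames(m)))
        stop("count input must have columns: ",
             paste(.REPORT_CATEGORIES, collapse = ", "))
    .dominanceFromCounts(m[, .REPORT_CATEGORIES, drop = FALSE])
}

.dominanceFromCounts <- function(m) {
    total <- rowSums(m)
    pct <- round(100 * m / ifelse(total == 0, NA, total), 2L)
    colnames(pct) <- paste0("pct_", colnames(m))
    out <- data.frame(
        condition = if (is.null(rownames(m)))
            as.character(seq_len(nrow(m))) else rownames(m),
        m, check.names = FALSE, stringsAsFactors = FALSE)
    out$total <- as.integer(total)
    out$tc_dominance <- as.integer(m[, "BSB-HES"] + m[, "TC-HEB"])
    out$bsb_dominance <- as.integer(m[, "TC-HES"] + m[, "BSB-HEB"])
    out <- cbind(out, as.data.frame(pct, check.names = FALSE))
    rownames(out) <- NULL
    out
}

#' Shared vs condition-specific dominance partition
#'
#' For each dominance direction (TC-dominant = BSB-HES or TC-HEB;
#' BSB-dominant = TC-HES or BSB-HEB), counts homoeolog pairs dominant in
#' both conditions (shared) versus in exactly one.
#'
#' @param recordsA,recordsB classification data.frames of two conditions
#'   (columns `pair_id`, `category`).
#' @return a data.frame `direction`, `shared`, `only_a`, `only_b`,
#'   `specific` (= only_a + only_b).
#' @export
sharedSpecificPartition <- function(recordsA, recordsB) {
    dirs <- list("TC-dominant" = c("BSB-HES", "TC-HEB"),
                 "BSB-dominant" = c("TC-HES", "BSB-HEB"))
    out <- lapply(names(dirs), function(d) {
        a <- recordsA$pair_id[recordsA$category %in% dirs[[d]]]
        b <- recordsB$pair_id[recordsB$category %in% dirs[[d]]]
        sh <- length(intersect(a, b))
        data.frame(direction = d, shared = sh,
                   only_a = length(setdiff(a, b)),
                   only_b = length(setdiff(b, a)),
                   specific = length(setdiff(a, b)) + length(setdiff(b, a)),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Write the dominance summary as Table-style TSVs
#'
#' Emits a count table with columns
#' `condition  BSB-HES  TC-HEB  TC-HES  BSB-HEB  normal  total` and a
#' percent-formatted twin (`<count> (<pct>%)` cells).
#'
#' @param summary output of [summarizeDominance()].
#' @param countsFile,percentFile output paths.
#' @export
writeDominanceSummary <- function(summary, countsFile, percentFile) {
    cols <- c("condition", .REPORT_CATEGORIES, "total")
    utils::write.table(summary[, cols], countsFile, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    pretty <- summary[, "condition", drop = FALSE]
    for (cc in .REPORT_CATEGORIES)
        pretty[[cc]] <- sprintf("%d (%.2f%%)", summary[[cc]],
                                summary[[paste0("pct_", cc)]])
    pretty$total <- summary$total
    utils::write.table(pretty, percentFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(countsFile)
}
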