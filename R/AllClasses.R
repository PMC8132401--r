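# S4 classes for the homoeolog-expression pipeline.

# Category labels -------------------------------------------------------------

# Designed categories the simulator can allocate to a homoeolog pair.
.DESIGN_CATEGORIES <- c("BSB-HES", "TC-HES", "BSB-HEB", "TC-HEB",
                        "normal", "specific", "DE")

# Categories the classifier can emit for one (pair, condition).
.CLASS_CATEGORIES <- c("BSB-HES", "TC-HEB", "TC-HES", "BSB-HEB",
                       "normal", "excluded")

# The five categories reported in dominance summaries ("excluded" is dropped).
.REPORT_CATEGORIES <- c("BSB-HES", "TC-HEB", "TC-HES", "BSB-HEB", "normal")

#' Simulation configuration
#'
#' Parameters of the synthetic allodiploid study: a set of homoeolog pairs
#' whose two parental copies (maternal BSB, paternal TC) differ only by
#' substitutions, sequenced as single-end hybrid reads across replicated
#' condition groups.
#'
#' @slot nPairs number of homoeolog pairs.
#' @slot lengthRange integer(2), min/max transcript length in nt.
#' @slot snpRate per-site substitution probability between the parental
#'   copies (the diagnostic-SNP density).
#' @slot readLength read length in nt.
#' @slot errorRate per-base sequencing error probability.
#' @slot nReplicates biological replicates per group.
#' @slot nGroups number of condition groups (e.g. two diets).
#' @slot depthMean mean expected fragments per expressed homoeolog copy,
#'   per replicate.
#' @slot categoryMix named proportions over the designed categories
#'   `BSB-HES`, `TC-HES`, `BSB-HEB`, `TC-HEB`, `normal`, `specific`
#'   (expressed in one group only) and `DE` (between-group fold change).
#' @slot biasRatio designed BSB:TC expression ratio for biased pairs
#'   (>= 2; TC-biased pairs use its reciprocal).
#' @slot normalBand designed ratio band for `normal` pairs; kept away from
#'   the 0.5/2 decision boundaries so recovery measures pipeline error,
#'   not boundary ambiguity.
#' @slot deFold designed between-group fold change for `DE` pairs (> 2).
#' @slot seed integer RNG seed; every downstream draw derives from it.
#' @export
setClass("SimConfig", representation(
    nPairs = "integer",
    lengthRange = "integer",
    snpRate = "numeric",
    readLength = "integer",
    errorRate = "numeric",
    nReplicates = "integer",
    nGroups = "integer",
    depthMean = "numeric",
    categoryMix = "numeric",
    biasRatio = "numeric",
    normalBand = "numeric",
    deFold = "numeric",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@nPairs < 1L) msg <- c(msg, "nPairs must be >= 1")
    if (length(object@lengthRange) != 2L ||
        any(object@lengthRange < 1L) ||
        object@lengthRange[1L] > object@lengthRange[2L])
        msg <- c(msg, "lengthRange must be an increasing pair of lengths")
    if (object@snpRate < 0 || object@snpRate >= 1)
        msg <- c(msg, "snpRate must lie in [0, 1)")
    if (object@errorRate < 0 || object@errorRate >= 1)
        msg <- c(msg, "errorRate must lie in [0, 1)")
    if (object@readLength > object@lengthRange[1L])
        msg <- c(msg, "readLength exceeds the shortest transcript")
    if (object@depthMean <= 0) msg <- c(msg, "depthMean must be > 0")
    if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
    if (object@nGroups < 1L) msg <- c(msg, "nGroups must be >= 1")
    mix <- object@categoryMix
    if (!setequal(names(mix), .DESIGN_CATEGORIES))
        msg <- c(msg, sprintf("categoryMix must be named over {%s}",
                              paste(.DESIGN_CATEGORIES, collapse = ", ")))
    else if (abs(sum(mix) - 1) > 1e-9 || any(mix < 0))
        msg <- c(msg, "categoryMix must be non-negative and sum to 1")
    if (setequal(names(mix), .DESIGN_CATEGORIES) &&
        (mix["specific"] > 0 || mix["DE"] > 0) && object@nGroups < 2L)
        msg <- c(msg, "specific/DE categories need at least two groups")
    if (object@biasRatio < 2) msg <- c(msg, "biasRatio must be >= 2")
    if (object@deFold <= 2) msg <- c(msg, "deFold must be > 2")
    if (length(object@normalBand) != 2L ||
        object@normalBand[1L] <= 0.5 || object@normalBand[2L] >= 2 ||
        object@normalBand[1L] > object@normalBand[2L])
        msg <- c(msg, "normalBand must lie strictly inside (0.5, 2)")
    if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' Defaults emulate the study design the package targets: 3 biological
#' replicates in each of 2 condition groups, a TC-skewed category mix, and
#' a 2% diagnostic-SNP density between the parental copies.
#'
#' @param nPairs number of homoeolog pairs.
#' @param lengthRange min/max transcript length (nt).
#' @param snpRate per-site substitution probability between parental copies.
#' @param readLength single-end read length (nt).
#' @param errorRate per-base sequencing error probability.
#' @param nReplicates biological replicates per group.
#' @param nGroups number of condition groups.
#' @param depthMean mean expected fragments per expressed copy per replicate.
#' @param categoryMix named proportions over the designed categories.
#' @param biasRatio designed ratio for biased pairs (>= 2).
#' @param normalBand designed ratio band for normal pairs.
#' @param deFold designed between-group fold change for DE pairs (> 2).
#' @param seed integer RNG seed.
#' @return a [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nPairs = 20, seed = 7)
#' cfg
#' @export
simConfig <- function(nPairs = 100L,
                      lengthRange = c(300L, 1500L),
                      snpRate = 0.02,
                      readLength = 75L,
                      errorRate = 0,
                      nReplicates = 3L,
                      nGroups = 2L,
                      depthMean = 30,
                      categoryMix = c("BSB-HES" = 0.15, "TC-HES" = 0.10,
                                      "BSB-HEB" = 0.10, "TC-HEB" = 0.15,
                                      "normal" = 0.30, "specific" = 0.10,
                                      "DE" = 0.10),
                      biasRatio = 4,
                      normalBand = c(0.8, 1.25),
                      deFold = 4,
                      seed = 1L) {
    new("SimConfig",
        nPairs = as.integer(nPairs),
        lengthRange = as.integer(lengthRange),
        snpRate = as.numeric(snpRate),
        readLength = as.integer(readLength),
        errorRate = as.numeric(errorRate),
        nReplicates = as.integer(nReplicates),
        nGroups = as.integer(nGroups),
        depthMean = as.numeric(depthMean),
        categoryMix = categoryMix[.DESIGN_CATEGORIES],
        biasRatio = as.numeric(biasRatio),
        normalBand = as.numeric(normalBand),
        deFold = as.numeric(deFold),
        seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nPairs, "homoeolog pairs,",
        sprintf("length %d-%d nt,", object@lengthRange[1L],
                object@lengthRange[2L]),
        sprintf("snpRate %.3g, errorRate %.3g\n", object@snpRate,
                object@errorRate))
    cat("  design:", object@nGroups, "groups x", object@nReplicates,
        "replicates, depthMean", object@depthMean,
        ", seed", object@seed, "\n")
    mix <- object@categoryMix
    cat("  mix:", paste(sprintf("%s=%.2f", names(mix), mix),
                        collapse = " "), "\n")
})

#' One-to-one homoeolog pairs
#'
#' A one-to-one mapping between a maternal (BSB) and a paternal (TC) gene
#' set, typically produced by [reciprocalBestHits()] or read from an
#' external ortholog table.
#'
#' @slot pairs data.frame with columns `pair_id`, `bsb_id`, `tc_id`,
#'   `score`, `bsb_length`, `tc_length`.
#' @export
setClass("HomoeologPairs", representation(pairs = "data.frame"))

setValidity("HomoeologPairs", function(object) {
    p <- object@pairs
    need <- c("pair_id", "bsb_id", "tc_id", "score",
              "bsb_length", "tc_length")
    if (!all(need %in% names(p)))
        return(sprintf("pairs must have columns: %s",
                       paste(need, collapse = ", ")))
    if (anyDuplicated(p$bsb_id) || anyDuplicated(p$tc_id) ||
        anyDuplicated(p$pair_id))
        return("pairing must be one-to-one (no repeated ids)")
    TRUE
})

#' Construct a HomoeologPairs object
#'
#' @param bsb_id,tc_id gene identifiers in the two parental sets.
#' @param score alignment score per pair (NA when externally supplied).
#' @param bsb_length,tc_length transcript lengths in nt.
#' @param pair_id identifier for the pair; defaults to `bsb_id`.
#' @return a [HomoeologPairs-class] object sorted by `bsb_id`.
#' @export
HomoeologPairs <- function(bsb_id, tc_id, score = NA_real_,
                           bsb_length = NA_integer_,
                           tc_length = NA_integer_,
                           pair_id = bsb_id) {
    df <- data.frame(pair_id = as.character(pair_id),
                     bsb_id = as.character(bsb_id),
                     tc_id = as.character(tc_id),
                     score = as.numeric(score),
                     bsb_length = as.integer(bsb_length),
                     tc_length = as.integer(tc_length),
                     stringsAsFactors = FALSE)
    df <- df[order(df$bsb_id), , drop = FALSE]
    rownames(df) <- NULL
    new("HomoeologPairs", pairs = df)
}

#' @describeIn HomoeologPairs number of pairs.
#' @param x a `HomoeologPairs` object.
#' @export
setMethod("length", "HomoeologPairs", function(x) nrow(x@pairs))

setMethod("show", "HomoeologPairs", function(object) {
    cat("HomoeologPairs with", nrow(object@pairs), "one-to-one pairs\n")
    if (nrow(object@pairs))
        print(utils::head(object@pairs, 5L))
})

#' @describeIn HomoeologPairs coerce to data.frame.
#' @param row.names,optional,... passed on for S3 consistency; unused.
#' @export
as.data.frame.HomoeologPairs <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
    x@pairs
}

#' Per-subgenome read counts
#'
#' A [SummarizedExperiment::SummarizedExperiment] with two integer assays,
#' `bsb` and `tc`, holding subgenome-assigned read counts per homoeolog
#' pair (rows) and sample (columns). `colData` carries the replicate
#' design (`group`, `replicate`, `tissue`) and `total_reads`, the number
#' of input alignments per sample used as the FPKM library size.
#' `rowData` carries the per-copy transcript lengths.
#'
#' @export
setClass("SubgenomeCounts", contains = "SummarizedExperiment")

setValidity("SubgenomeCounts", function(object) {
    msg <- character()
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("bsb", "tc") %in% an))
        msg <- c(msg, "assays 'bsb' and 'tc' are required")
    cd <- SummarizedExperiment::colData(object)
    need <- c("group", "replicate", "tissue", "total_reads")
    if (!all(need %in% names(cd)))
        msg <- c(msg, sprintf("colData must have columns: %s",
                              paste(need, collapse = ", ")))
    if (all(c("bsb", "tc") %in% an)) {
        b <- SummarizedExperiment::assay(object, "bsb")
        t <- SummarizedExperiment::assay(object, "tc")
        if (any(b < 0) || any(t < 0))
            msg <- c(msg, "counts must be non-negative")
        if ("total_reads" %in% names(cd) && ncol(object) > 0 &&
            any(colSums(b) + colSums(t) > cd$total_reads))
            msg <- c(msg, "total_reads must be >= assigned column sums")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a SubgenomeCounts object
#'
#' @param bsb,tc integer matrices (pairs x samples) of subgenome-assigned
#'   read counts, identically dimensioned and named.
#' @param design data.frame with one row per sample: `sample_id`, `group`,
#'   `replicate`, `tissue`.
#' @param totalReads numeric vector of per-sample total input alignments
#'   (library sizes). Defaults to the assigned column sums.
#' @param bsbLength,tcLength per-pair transcript lengths (nt).
#' @return a [SubgenomeCounts-class] object.
#' @export
SubgenomeCounts <- function(bsb, tc, design,
                            totalReads = NULL,
                            bsbLength = NA_integer_,
                            tcLength = NA_integer_) {
    bsb <- as.matrix(bsb); tc <- as.matrix(tc)
    stopifnot(identical(dim(bsb), dim(tc)))
    if (is.null(totalReads))
        totalReads <- colSums(bsb) + colSums(tc)
    ord <- match(colnames(bsb), design$sample_id)
    if (anyNA(ord))
        stop("every count column needs a design row (sample_id)")
    cd <- S4Vectors::DataFrame(
        group = design$group[ord],
        replicate = design$replicate[ord],
        tissue = design$tissue[ord],
        total_reads = as.numeric(totalReads),
        row.names = colnames(bsb))
    rd <- S4Vectors::DataFrame(
        bsb_length = as.integer(rep_len(bsbLength, nrow(bsb))),
        tc_length = as.integer(rep_len(tcLength, nrow(bsb))),
        row.names = rownames(bsb))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(bsb = bsb, tc = tc), colData = cd, rowData = rd)
    new("SubgenomeCounts", se)
}
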