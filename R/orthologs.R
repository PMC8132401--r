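# Reciprocal-best-hit ortholog pairing.
#
# Desk-scale gene sets are paired with built-in Smith-Waterman local
# alignment (Biostrings) instead of an external search tool. For larger
# sets an exhaustive all-vs-all alignment is wasteful, so candidate
# targets are pre-screened by shared k-mer content and only the top
# candidates are aligned; the screen is exact in the regime this package
# targets (orthologs at a few percent divergence share far more k-mers
# than unrelated genes) and can be disabled with `nCandidates = Inf`.

#' Alignment scoring parameters
#'
#' Nucleotide mode uses a match/mismatch matrix with affine gaps; protein
#' mode (AAStringSet inputs) uses BLOSUM62. `minScore` plays the role an
#' E-value cutoff plays in a database search: hits scoring below it are
#' dropped. The two are not equivalent -- a score threshold ignores
#' database size and composition -- but at these set sizes it is the
#' deterministic analogue.
#'
#' @param match,mismatch nucleotide match reward / mismatch penalty.
#' @param gapOpening,gapExtension affine gap costs (positive).
#' @param minScore minimum best-hit score to report.
#' @return a named list of scoring parameters.
#' @export
scoringParams <- function(match = 2, mismatch = -3,
                          gapOpening = 5, gapExtension = 2,
                          minScore = 60) {
    list(match = match, mismatch = mismatch, gapOpening = gapOpening,
         gapExtension = gapExtension, minScore = minScore)
}

.substMatrix <- function(set, scoring) {
    if (methods::is(set, "AAStringSet")) {
        e <- new.env()
        utils::data("BLOSUM62", package = "Biostrings", envir = e)
        e$BLOSUM62
    } else {
        Biostrings::nucleotideSubstitutionMatrix(
            match = scoring$match, mismatch = scoring$mismatch)
    }
}

# Rank candidate targets per query by shared 6-mer content (dot product
# of k-mer count vectors). Returns an index matrix (queries x candidates).
.kmerCandidates <- function(query, target, nCandidates) {
    k <- 6L
    q <- Biostrings::oligonucleotideFrequency(query, width = k)
    t <- Biostrings::oligonucleotideFrequency(target, width = k)
    sim <- q %*% t(t)
    t(apply(sim, 1L, function(row)
        order(row, decreasing = TRUE)[seq_len(nCandidates)]))
}

#' Best local-alignment hit of each query in a target set
#'
#' For each query sequence, the target with the maximal Smith-Waterman
#' local alignment score, provided that score reaches
#' `scoring$minScore`; queries with no hit above threshold are absent
#' from the result. Ties on the best score are broken by the
#' lexicographically smallest target id, so results are deterministic.
#'
#' @param query,target [Biostrings::DNAStringSet] (or `AAStringSet`)
#'   objects with unique names.
#' @param scoring see [scoringParams()].
#' @param nCandidates number of k-mer-screened candidate targets to align
#'   per query (DNA only); use `Inf` to align against every target.
#' @return a data.frame `query_id`, `target_id`, `score`.
#' @examples
#' s <- Biostrings::DNAStringSet(c(a = "ACGTACGTACGTACGTACGTACGTACGTACGT",
#'                                 b = "TTTTGGGGCCCCAAAATTTTGGGGCCCCAAAA"))
#' bestHits(s, s, scoring = scoringParams(minScore = 10))
#' @export
bestHits <- function(query, target, scoring = scoringParams(),
                     nCandidates = 5L) {
    if (length(query) == 0L || length(target) == 0L)
        return(data.frame(query_id = character(),
                          target_id = character(),
                          score = numeric(), stringsAsFactors = FALSE))
    if (is.null(names(query)) || is.null(names(target)))
        stop("query and target sets must be named")
    sub <- .substMatrix(target, scoring)
    screen <- methods::is(query, "DNAStringSet") &&
        is.finite(nCandidates) && nCandidates < length(target)
    cand <- if (screen) {
        .kmerCandidates(query, target, as.integer(nCandidates))
    } else {
        matrix(rep(seq_along(target), each = length(query)),
               nrow = length(query))
    }
    out_t <- character(length(query))
    out_s <- numeric(length(query))
    for (i in seq_along(query)) {
        idx <- cand[i, ]
        sc <- Biostrings::pairwiseAlignment(
            target[idx], query[[i]], type = "local",
            substitutionMatrix = sub,
            gapOpening = scoring$gapOpening,
            gapExtension = scoring$gapExtension,
            scoreOnly = TRUE)
        best <- max(sc)
        tied <- names(target)[idx[sc == best]]
        out_t[i] <- sort(tied)[1L]
        out_s[i] <- best
    }
    keep <- out_s >= scoring$minScore
    data.frame(query_id = names(query)[keep],
               target_id = out_t[keep],
               score = out_s[keep],
               stringsAsFactors = FALSE)
}

#' Reciprocal-best-hit homoeolog pairing
#'
#' A pair (b, t) is reported iff t is b's best hit in the TC set and b is
#' t's best hit in the BSB set. The mapping is one-to-one by
#' construction and invariant to the order of the input sets.
#'
#' @param bsb,tc named parental sequence sets.
#' @param scoring see [scoringParams()].
#' @param nCandidates see [bestHits()].
#' @return a [HomoeologPairs-class] object sorted by `bsb_id`; the score
#'   is the BSB-to-TC best-hit score.
#' @export
reciprocalBestHits <- function(bsb, tc, scoring = scoringParams(),
                               nCandidates = 5L) {
    fwd <- bestHits(bsb, tc, scoring, nCandidates)
    rev <- bestHits(tc, bsb, scoring, nCandidates)
    back <- rev$target_id[match(fwd$target_id, rev$query_id)]
    keep <- !is.na(back) & back == fwd$query_id
    hits <- fwd[keep, , drop = FALSE]
    HomoeologPairs(
        bsb_id = hits$query_id,
        tc_id = hits$target_id,
        score = hits$score,
        bsb_length = Biostrings::width(bsb)[match(hits$query_id,
                                                  names(bsb))],
        tc_length = Biostrings::width(tc)[match(hits$target_id,
                                                names(tc))],
        pair_id = .derivePairIds(hits$query_id, hits$target_id))
}
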