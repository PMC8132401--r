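# Readers/writers for the plain-text study formats. All TSVs are written
# without quoting or locale-dependent formatting.

#' Read and write diagnostic SNP catalogs
#'
#' The catalog is a TSV with header
#' `pair_id  bsb_pos  tc_pos  bsb_allele  tc_allele` (1-based positions in
#' each parental copy's coordinate system).
#'
#' @param file path to the catalog.
#' @return `readSnpCatalog`: a data.frame with the five catalog columns.
#' @export
readSnpCatalog <- function(file) {
    df <- utils::read.delim(file, stringsAsFactors = FALSE)
    need <- c("pair_id", "bsb_pos", "tc_pos", "bsb_allele", "tc_allele")
    if (!all(need %in% names(df)))
        stop("malformed SNP catalog: expected columns ",
             paste(need, collapse = ", "))
    bad <- df$bsb_allele == df$tc_allele
    if (any(bad))
        stop("malformed SNP catalog: identical alleles at ",
             sum(bad), " site(s)")
    df
}

#' @rdname readSnpCatalog
#' @param snps a SNP catalog data.frame.
#' @export
writeSnpCatalog <- function(snps, file) {
    utils::write.table(
        snps[, c("pair_id", "bsb_pos", "tc_pos",
                 "bsb_allele", "tc_allele")],
        file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' Write a minimal VCF v4.2 view of the SNP catalog
#'
#' Emits the catalog against one parental reference: `CHROM` is the gene
#' copy id, `REF` the allele of that parent and `ALT` the other parent's
#' allele.
#'
#' @param snps a SNP catalog data.frame.
#' @param pairs the ortholog table (`pair_id`, `bsb_id`, `tc_id`,
#'   `length`).
#' @param file output path.
#' @param subgenome `"BSB"` or `"TC"`: which parent is the reference.
#' @export
writeSnpVcf <- function(snps, pairs, file, subgenome = c("BSB", "TC")) {
    subgenome <- match.arg(subgenome)
    i <- match(snps$pair_id, pairs$pair_id)
    if (anyNA(i)) stop("SNP catalog references unknown pair ids")
    if (subgenome == "BSB") {
        chrom <- pairs$bsb_id[i]; pos <- snps$bsb_pos
        ref <- snps$bsb_allele; alt <- snps$tc_allele
    } else {
        chrom <- pairs$tc_id[i]; pos <- snps$tc_pos
        ref <- snps$tc_allele; alt <- snps$bsb_allele
    }
    ids <- if (subgenome == "BSB") pairs$bsb_id else pairs$tc_id
    hdr <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=%d>", ids, pairs$length),
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                    chrom, pos, ref, alt)
    writeLines(c(hdr, body), file)
    invisible(file)
}

#' Read a replicate/group design table
#'
#' TSV with header `sample_id  group  replicate  tissue`.
#'
#' @param file path to the table.
#' @return a data.frame.
#' @export
readDesign <- function(file) {
    df <- utils::read.delim(file, stringsAsFactors = FALSE)
    need <- c("sample_id", "group", "replicate", "tissue")
    if (!all(need %in% names(df)))
        stop("malformed design table: expected columns ",
             paste(need, collapse = ", "))
    df
}

#' Read an externally supplied ortholog table
#'
#' TSV with header `bsb_id  tc_id`; bypasses reciprocal-best-hit pairing.
#'
#' @param file path to the table.
#' @param bsb,tc optional [Biostrings::DNAStringSet] parental sets used to
#'   fill in transcript lengths.
#' @return a [HomoeologPairs-class] object.
#' @export
readOrthologTable <- function(file, bsb = NULL, tc = NULL) {
    df <- utils::read.delim(file, stringsAsFactors = FALSE)
    if (!all(c("bsb_id", "tc_id") %in% names(df)))
        stop("malformed ortholog table: expected columns bsb_id, tc_id")
    bl <- if (!is.null(bsb)) {
        Biostrings::width(bsb)[match(df$bsb_id, names(bsb))]
    } else NA_integer_
    tl <- if (!is.null(tc)) {
        Biostrings::width(tc)[match(df$tc_id, names(tc))]
    } else NA_integer_
    HomoeologPairs(df$bsb_id, df$tc_id, score = NA_real_,
                   bsb_length = bl, tc_length = tl,
                   pair_id = .derivePairIds(df$bsb_id, df$tc_id))
}

# Pair ids: when both gene ids share the simulator-style suffix
# convention (<id>_bsb / <id>_tc) use the common stem, else the BSB id.
.derivePairIds <- function(bsb_id, tc_id) {
    stem_b <- sub("_bsb$", "", bsb_id)
    stem_t <- sub("_tc$", "", tc_id)
    ifelse(stem_b == stem_t & stem_b != bsb_id, stem_b, bsb_id)
}

#' Write per-pair subgenome counts as TSV
#'
#' Long format with header `pair_id  sample_id  bsb_count  tc_count`.
#'
#' @param sc a [SubgenomeCounts-class] object.
#' @param file output path.
#' @export
writeCountsTsv <- function(sc, file) {
    b <- bsbCounts(sc); t <- tcCounts(sc)
    df <- data.frame(
        pair_id = rep(rownames(b), times = ncol(b)),
        sample_id = rep(colnames(b), each = nrow(b)),
        bsb_count = as.vector(b),
        tc_count = as.vector(t),
        stringsAsFactors = FALSE)
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

# Format a numeric column with 6 significant digits for TSV output.
.fmtNum <- function(x) ifelse(is.na(x), "NA", signif(x, 6))
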