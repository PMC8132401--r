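# Generics and accessors.

#' @rdname SubgenomeCounts-class
#' @param x a `SubgenomeCounts` object.
#' @export
setGeneric("bsbCounts", function(x) standardGeneric("bsbCounts"))

#' @rdname SubgenomeCounts-class
#' @export
setGeneric("tcCounts", function(x) standardGeneric("tcCounts"))

#' @rdname SubgenomeCounts-class
#' @export
setGeneric("sampleTotals", function(x) standardGeneric("sampleTotals"))

#' @rdname SubgenomeCounts-class
#' @export
setGeneric("conditions", function(x) standardGeneric("conditions"))

#' @describeIn SubgenomeCounts-class maternal-subgenome count matrix.
#' @export
setMethod("bsbCounts", "SubgenomeCounts", function(x)
    SummarizedExperiment::assay(x, "bsb"))

#' @describeIn SubgenomeCounts-class paternal-subgenome count matrix.
#' @export
setMethod("tcCounts", "SubgenomeCounts", function(x)
    SummarizedExperiment::assay(x, "tc"))

#' @describeIn SubgenomeCounts-class per-sample library sizes.
#' @export
setMethod("sampleTotals", "SubgenomeCounts", function(x)
    stats::setNames(SummarizedExperiment::colData(x)$total_reads,
                    colnames(x)))

#' @describeIn SubgenomeCounts-class per-sample condition labels
#'   (group crossed with tissue when more than one tissue is present).
#' @export
setMethod("conditions", "SubgenomeCounts", function(x) {
    cd <- SummarizedExperiment::colData(x)
    if (length(unique(cd$tissue)) > 1L)
        paste(cd$group, cd$tissue, sep = "-")
    else as.character(cd$group)
})

#' @rdname HomoeologPairs-class
#' @param object a `HomoeologPairs` object.
#' @export
setGeneric("bsbIds", function(object) standardGeneric("bsbIds"))

#' @rdname HomoeologPairs-class
#' @export
setGeneric("tcIds", function(object) standardGeneric("tcIds"))

#' @describeIn HomoeologPairs-class BSB-side gene ids.
#' @export
setMethod("bsbIds", "HomoeologPairs", function(object) object@pairs$bsb_id)

#' @describeIn HomoeologPairs-class TC-side gene ids.
#' @export
setMethod("tcIds", "HomoeologPairs", function(object) object@pairs$tc_id)
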