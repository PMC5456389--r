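#' @rdname FoldChangeMatrix
#' @param x a FoldChangeMatrix
#' @export
setGeneric("probeIds", function(x) standardGeneric("probeIds"))

#' @rdname FoldChangeMatrix
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname FoldChangeMatrix
#' @export
setGeneric("lnFC", function(x) standardGeneric("lnFC"))

#' @rdname RegulationCounts-class
#' @param x a RegulationCounts
#' @export
setGeneric("regCounts", function(x) standardGeneric("regCounts"))

#' @rdname RegulationCounts-class
#' @export
setGeneric("upCounts", function(x) standardGeneric("upCounts"))

#' @rdname RegulationCounts-class
#' @export
setGeneric("downCounts", function(x) standardGeneric("downCounts"))

#' @rdname RegulationCounts-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname RegulationCounts-class
#' @export
setGeneric("countLevel", function(x) standardGeneric("countLevel"))

#' @rdname GenePartition-class
#' @param x a GenePartition
#' @export
setGeneric("highSet", function(x) standardGeneric("highSet"))

#' @rdname GenePartition-class
#' @export
setGeneric("lowSet", function(x) standardGeneric("lowSet"))

#' @rdname GenePartition-class
#' @export
setGeneric("denDirection", function(x) standardGeneric("denDirection"))

#' @rdname GenePartition-class
#' @export
setGeneric("geneRanking", function(x) standardGeneric("geneRanking"))

#' @describeIn FoldChangeMatrix probe identifiers (row names)
setMethod("probeIds", "FoldChangeMatrix", function(x) rownames(x))

#' @describeIn FoldChangeMatrix sample identifiers (column names)
setMethod("sampleIds", "FoldChangeMatrix", function(x) colnames(x))

#' @describeIn FoldChangeMatrix the lnFC assay matrix
setMethod("lnFC", "FoldChangeMatrix", function(x) assay(x, "lnFC"))

setMethod("show", "FoldChangeMatrix", function(object) {
    v <- lnFC(object)
    cat("FoldChangeMatrix:", nrow(v), "probes x", ncol(v), "samples\n")
    cat("  missing cells:", sum(is.na(v)),
        sprintf("(%.2f%%)\n", 100 * mean(is.na(v))))
})

#' @describeIn RegulationCounts-class the per-unit count table
setMethod("regCounts", "RegulationCounts", function(x) x@counts)

#' @describeIn RegulationCounts-class named vector of up-DENs
setMethod("upCounts", "RegulationCounts", function(x)
    setNames(x@counts$up_count, x@counts$unit_id))

#' @describeIn RegulationCounts-class named vector of down-DENs
setMethod("downCounts", "RegulationCounts", function(x)
    setNames(x@counts$down_count, x@counts$unit_id))

#' @describeIn RegulationCounts-class number of samples counted over
setMethod("nSamples", "RegulationCounts", function(x) x@nSamples)

#' @describeIn RegulationCounts-class `"probe"` or `"gene"`
setMethod("countLevel", "RegulationCounts", function(x) x@level)

setMethod("show", "RegulationCounts", function(object) {
    k <- object@counts
    cat("RegulationCounts (", object@level, " level): ", nrow(k),
        " units over ", object@nSamples, " samples\n", sep = "")
    cat("  up-DEN range: [", min(k$up_count), ", ", max(k$up_count),
        "]; down-DEN range: [", min(k$down_count), ", ",
        max(k$down_count), "]\n", sep = "")
})

#' @describeIn GenePartition-class gene ids of the high (frequently
#'   regulated) set
setMethod("highSet", "GenePartition", function(x) x@highSet)

#' @describeIn GenePartition-class gene ids of the low set
setMethod("lowSet", "GenePartition", function(x) x@lowSet)

#' @describeIn GenePartition-class regulation direction
setMethod("denDirection", "GenePartition", function(x) x@direction)

#' @describeIn GenePartition-class full ranking (count desc, id asc)
setMethod("geneRanking", "GenePartition", function(x) x@ranking)

setMethod("show", "GenePartition", function(object) {
    lab <- if (object@direction == "up") c("up_h", "up_l")
           else c("down_h", "down_l")
    cat("GenePartition (", object@direction, "): ",
        length(object@highSet), " ", lab[1], " / ",
        length(object@lowSet), " ", lab[2],
        " (fraction ", object@fraction, ")\n", sep = "")
})
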