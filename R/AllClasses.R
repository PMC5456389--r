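#' FoldChangeMatrix: probe-by-sample natural-log fold changes
#'
#' Thin [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' assay `"lnFC"`: rows are probesets, columns are treated samples, each cell
#' the natural-log fold change of the probe in that sample relative to its
#' matched control. Cells may be `NA` (no measurement); every non-missing
#' value must be finite. Row and column names are the probe and sample
#' identifiers and must be unique.
#'
#' @slot . inherits all slots from `SummarizedExperiment`.
#' @seealso [FoldChangeMatrix()], [readFoldChangeMatrix()]
#' @exportClass FoldChangeMatrix
setClass("FoldChangeMatrix", contains = "SummarizedExperiment")

setValidity("FoldChangeMatrix", function(object) {
    msgs <- character()
    if (!"lnFC" %in% names(assays(object)))
        msgs <- c(msgs, "assay 'lnFC' is required")
    pid <- rownames(object)
    sid <- colnames(object)
    if (is.null(pid) || is.null(sid))
        msgs <- c(msgs, "probe (row) and sample (column) names are required")
    if (!is.null(pid) && anyDuplicated(pid))
        msgs <- c(msgs, paste0("duplicated probe id: ",
                               pid[duplicated(pid)][1L]))
    if (!is.null(sid) && anyDuplicated(sid))
        msgs <- c(msgs, paste0("duplicated sample id: ",
                               sid[duplicated(sid)][1L]))
    if ("lnFC" %in% names(assays(object))) {
        v <- assay(object, "lnFC")
        if (!is.numeric(v))
            msgs <- c(msgs, "lnFC values must be numeric")
        else if (any(is.infinite(v)))
            msgs <- c(msgs, "lnFC values must be finite or NA")
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a FoldChangeMatrix
#'
#' @param values numeric matrix of natural-log fold changes (probes in rows,
#'   samples in columns); `NA` marks missing cells.
#' @param probeIds,sampleIds optional character vectors overriding
#'   `rownames(values)` / `colnames(values)`.
#' @return A [FoldChangeMatrix-class] object.
#' @examples
#' m <- matrix(c(0.7, -0.8, 0.1, NA, 1.2, -0.1), nrow = 3,
#'             dimnames = list(paste0("p", 1:3), c("s1", "s2")))
#' FoldChangeMatrix(m)
#' @export
FoldChangeMatrix <- function(values, probeIds = rownames(values),
                             sampleIds = colnames(values)) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (is.null(probeIds) || is.null(sampleIds))
        stop("probe and sample identifiers are required")
    dimnames(values) <- list(as.character(probeIds), as.character(sampleIds))
    se <- SummarizedExperiment(assays = list(lnFC = values))
    new("FoldChangeMatrix", se)
}

#' RegulationCounts: per-unit differential expression numbers
#'
#' Holds, for each probe or gene, the number of samples in which it was
#' significantly up-regulated (`up_count`) and down-regulated (`down_count`)
#' -- the DENs -- together with the number of probes aggregated per unit
#' (`n_probes`, 1 at probe level) and the common sample count.
#'
#' @slot counts data.frame with columns `unit_id`, `up_count`, `down_count`,
#'   `n_probes`.
#' @slot level `"probe"` or `"gene"`.
#' @slot nSamples number of treated samples the counts were taken over.
#' @seealso [countRegulation()], [aggregateToGenes()]
#' @exportClass RegulationCounts
setClass("RegulationCounts",
         representation(counts = "data.frame", level = "character",
                        nSamples = "integer"))

setValidity("RegulationCounts", function(object) {
    msgs <- character()
    cn <- c("unit_id", "up_count", "down_count", "n_probes")
    if (!all(cn %in% names(object@counts)))
        msgs <- c(msgs, paste("counts needs columns:",
                              paste(cn, collapse = ", ")))
    else {
        k <- object@counts
        if (anyDuplicated(k$unit_id))
            msgs <- c(msgs, paste0("duplicated unit id: ",
                                   k$unit_id[duplicated(k$unit_id)][1L]))
        bad <- k$up_count < 0 | k$down_count < 0 |
            k$up_count != round(k$up_count) | k$down_count != round(k$down_count)
        if (any(bad))
            msgs <- c(msgs, "counts must be non-negative integers")
        if (any(k$up_count + k$down_count > object@nSamples * k$n_probes))
            msgs <- c(msgs, "up_count + down_count exceeds samples x probes")
    }
    if (!object@level %in% c("probe", "gene"))
        msgs <- c(msgs, "level must be 'probe' or 'gene'")
    if (length(object@nSamples) != 1L || object@nSamples < 1L)
        msgs <- c(msgs, "nSamples must be a single positive integer")
    if (length(msgs)) msgs else TRUE
})

#' GenePartition: frequently vs rarely regulated gene sets
#'
#' The assignment of every scored gene to the high set (top `fraction` by the
#' directional DEN; `up_h` or `down_h`) or the low set (the remainder;
#' `up_l`/`down_l`), plus the full deterministic ranking that produced it
#' (count descending, ties by gene id in C-locale ascending order).
#'
#' @slot direction `"up"` or `"down"`.
#' @slot highSet,lowSet character vectors of gene ids.
#' @slot fraction fraction of genes in the high set (default 0.15).
#' @slot ranking all gene ids in ranking order.
#' @seealso [partitionGenes()]
#' @exportClass GenePartition
setClass("GenePartition",
         representation(direction = "character", highSet = "character",
                        lowSet = "character", fraction = "numeric",
                        ranking = "character"))

setValidity("GenePartition", function(object) {
    msgs <- character()
    if (!object@direction %in% c("up", "down"))
        msgs <- c(msgs, "direction must be 'up' or 'down'")
    if (length(object@fraction) != 1L || object@fraction <= 0 ||
        object@fraction >= 1)
        msgs <- c(msgs, "fraction must lie in (0, 1)")
    n <- length(object@highSet) + length(object@lowSet)
    if (length(intersect(object@highSet, object@lowSet)))
        msgs <- c(msgs, "high and low sets must be disjoint")
    if (length(object@highSet) != floor(object@fraction * n))
        msgs <- c(msgs, "|high set| must equal floor(fraction * N)")
    if (!setequal(object@ranking, c(object@highSet, object@lowSet)))
        msgs <- c(msgs, "ranking must cover exactly the partitioned genes")
    if (length(msgs)) msgs else TRUE
})
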