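# Small in-code builders shared across test files.

makeFcm <- function(values, probes = NULL, samples = NULL) {
    if (is.null(probes)) probes <- sprintf("p%02d", seq_len(nrow(values)))
    if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
    dimnames(values) <- list(probes, samples)
    FoldChangeMatrix(values)
}

# Gene-level RegulationCounts straight from count vectors.
makeGeneCounts <- function(ids, up, down, nSamples = 1000L) {
    methods::new("RegulationCounts",
                 counts = data.frame(unit_id = as.character(ids),
                                     up_count = as.integer(up),
                                     down_count = as.integer(down),
                                     n_probes = 1L,
                                     stringsAsFactors = FALSE),
                 level = "gene", nSamples = as.integer(nSamples))
}

makeLoci <- function(gene_id, chrom, start, end) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                                 gene_id = gene_id)
    names(gr) <- gene_id
    gr
}

makeVariants <- function(chrom, pos, rs = NULL, labels = NULL) {
    n <- length(pos)
    if (is.null(rs)) rs <- sprintf("rs%d", seq_len(n))
    if (is.null(labels)) labels <- rep(list(character()), n)
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    S4Vectors::mcols(gr)$rs_id <- rs
    S4Vectors::mcols(gr)$clin_sig <- IRanges::CharacterList(labels)
    gr
}

writeTempLines <- function(lines, ext = ".tsv") {
    f <- tempfile(fileext = ext)
    writeLines(lines, f)
    f
}
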