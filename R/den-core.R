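#' Significance thresholds on the lnFC scale
#'
#' The defaults, `0.69` and `-0.69`, are `ln 2` rounded to two decimals: a
#' sample counts as significantly up-regulated for a probe when its lnFC is
#' strictly greater than `upCut` (two-fold induction) and down-regulated when
#' strictly below `downCut` (half-fold). Boundary values are not events.
#'
#' @param upCut positive number, lnFC scale.
#' @param downCut negative number, lnFC scale.
#' @return validated list with elements `upCut`, `downCut`.
#' @examples
#' denThresholds()          # 0.69 / -0.69, i.e. fold change > 2 or < 0.5
#' @export
denThresholds <- function(upCut = 0.69, downCut = -0.69) {
    stopifnot(is.numeric(upCut), is.numeric(downCut),
              length(upCut) == 1L, length(downCut) == 1L)
    if (!(downCut < 0 && 0 < upCut))
        stop("thresholds must satisfy downCut < 0 < upCut")
    list(upCut = upCut, downCut = downCut)
}

#' Count up-/down-regulation events per probe
#'
#' For every probe, the up-DEN is the number of samples with lnFC strictly
#' above `thresholds$upCut`, the down-DEN the number strictly below
#' `thresholds$downCut`. Missing cells count in neither direction.
#'
#' @param x a [FoldChangeMatrix-class].
#' @param thresholds see [denThresholds()].
#' @return A [RegulationCounts-class] at probe level.
#' @export
countRegulation <- function(x, thresholds = denThresholds()) {
    stopifnot(is(x, "FoldChangeMatrix"))
    v <- lnFC(x)
    up <- as.integer(rowSums(v > thresholds$upCut, na.rm = TRUE))
    dn <- as.integer(rowSums(v < thresholds$downCut, na.rm = TRUE))
    new("RegulationCounts",
        counts = data.frame(unit_id = rownames(v), up_count = up,
                            down_count = dn, n_probes = 1L,
                            stringsAsFactors = FALSE),
        level = "probe", nSamples = ncol(v))
}

#' Aggregate probe-level DENs to genes
#'
#' Probes without a map entry are dropped (their number is reported via a
#' message and the `"n_unmapped"` attribute). Up- and down-counts are
#' combined per gene independently under `policy`: `max` (default; a gene is
#' regulated as often as its most responsive probe), `sum`, or `mean`
#' (rounded half-up to an integer).
#'
#' @param probeCounts probe-level [RegulationCounts-class].
#' @param map data.frame from [readProbeGeneMap()].
#' @param policy `"max"`, `"sum"` or `"mean"`.
#' @return A gene-level [RegulationCounts-class].
#' @export
aggregateToGenes <- function(probeCounts, map, policy = c("max", "sum", "mean")) {
    policy <- match.arg(policy)
    stopifnot(is(probeCounts, "RegulationCounts"))
    if (countLevel(probeCounts) != "probe")
        stop("probeCounts must be probe-level")
    k <- regCounts(probeCounts)
    idx <- match(k$unit_id, map$probe_id)
    unmapped <- sum(is.na(idx))
    if (unmapped == nrow(k))
        stop("no probe in the counts has a map entry")
    if (unmapped > 0L)
        message(unmapped, " unmapped probe(s) dropped")
    k <- k[!is.na(idx), , drop = FALSE]
    gene <- map$gene_id[idx[!is.na(idx)]]
    comb <- switch(policy,
        max = function(x) max(x),
        sum = function(x) sum(x),
        mean = function(x) .roundHalfUp(mean(x)))
    genes <- sort(unique(gene), method = "radix")
    gi <- match(gene, genes)
    up <- vapply(split(k$up_count, gi), comb, 0)
    dn <- vapply(split(k$down_count, gi), comb, 0)
    np <- as.integer(tabulate(gi, nbins = length(genes)))
    out <- new("RegulationCounts",
               counts = data.frame(unit_id = genes,
                                   up_count = as.integer(up),
                                   down_count = as.integer(dn),
                                   n_probes = np, stringsAsFactors = FALSE),
               level = "gene", nSamples = nSamples(probeCounts))
    attr(out, "n_unmapped") <- unmapped
    out
}

# Shared deterministic ranking: directional count descending, ties broken by
# gene id ascending in the C locale.
.denRanking <- function(geneCounts, direction = c("up", "down")) {
    direction <- match.arg(direction)
    k <- regCounts(geneCounts)
    cnt <- if (direction == "up") k$up_count else k$down_count
    ord <- .radixOrder(-cnt, k$unit_id)
    list(ids = k$unit_id[ord], counts = cnt[ord])
}

#' Partition genes into frequently and rarely regulated sets
#'
#' Genes are ranked by the directional DEN (descending, ties broken by gene
#' id in C-locale ascending order); the first `floor(fraction * N)` genes
#' form the high set (`up_h` or `down_h`), the remainder the low set.
#'
#' @param geneCounts gene-level [RegulationCounts-class].
#' @param direction `"up"` or `"down"`.
#' @param fraction high-set fraction, in (0, 1); default 0.15 as deduced
#'   from the observed DEN distributions.
#' @return A [GenePartition-class].
#' @export
partitionGenes <- function(geneCounts, direction = c("up", "down"),
                           fraction = 0.15) {
    direction <- match.arg(direction)
    if (!is.numeric(fraction) || length(fraction) != 1L ||
        fraction <= 0 || fraction >= 1)
        stop("fraction must lie in (0, 1)")
    r <- .denRanking(geneCounts, direction)
    n <- length(r$ids)
    if (n < 10L) stop("need at least 10 genes to partition")
    k <- floor(fraction * n)
    new("GenePartition", direction = direction,
        highSet = r$ids[seq_len(k)],
        lowSet = r$ids[seq.int(k + 1L, n)],
        fraction = fraction, ranking = r$ids)
}

#' Top-N and last-N genes of the DEN ranking
#'
#' The `T1000`/`L1000` construction: under the same deterministic ranking as
#' [partitionGenes()], the first `n` genes form the top set and the final
#' `n` genes the last set. Requires `2n <= N` so the sets are disjoint.
#'
#' @inheritParams partitionGenes
#' @param n set size (default 1000).
#' @return list with character vectors `top` and `last`.
#' @export
topLastN <- function(geneCounts, direction = c("up", "down"), n = 1000L) {
    direction <- match.arg(direction)
    r <- .denRanking(geneCounts, direction)
    N <- length(r$ids)
    if (2L * n > N)
        stop("2n = ", 2L * n, " exceeds the number of genes (", N, ")")
    list(top = r$ids[seq_len(n)], last = r$ids[seq.int(N - n + 1L, N)])
}

#' Overlap summary of two gene sets
#'
#' @param a,b character vectors of gene ids.
#' @return list with `n_a`, `n_b`, `n_intersect`, `jaccard`.
#' @examples
#' partitionOverlap(c("g1", "g2", "g3"), c("g3", "g4"))  # jaccard 0.25
#' @export
partitionOverlap <- function(a, b) {
    a <- unique(as.character(a)); b <- unique(as.character(b))
    ni <- length(intersect(a, b))
    nu <- length(union(a, b))
    list(n_a = length(a), n_b = length(b), n_intersect = ni,
         jaccard = if (nu == 0L) NA_real_ else ni / nu)
}

#' Summarize a directional DEN distribution
#'
#' Histogram over integer counts, the share of the total DEN held by the top
#' `fraction` of genes, and moment skewness. A heavy-tailed (power-law-like)
#' DEN distribution shows up as a large top-15% share and strong positive
#' skewness.
#'
#' @inheritParams partitionGenes
#' @return list with `histogram` (table over counts), `top_share`,
#'   `skewness`, `n_genes`, `total_den`, and `all_zero` flag.
#' @export
denDistributionSummary <- function(geneCounts, direction = c("up", "down"),
                                   fraction = 0.15) {
    direction <- match.arg(direction)
    r <- .denRanking(geneCounts, direction)
    if (!length(r$ids)) stop("no counts to summarize")
    k <- floor(fraction * length(r$ids))
    total <- sum(r$counts)
    share <- if (total == 0) 0 else sum(r$counts[seq_len(k)]) / total
    list(histogram = table(r$counts),
         top_share = share,
         skewness = .skewness(r$counts),
         n_genes = length(r$ids),
         total_den = total,
         all_zero = total == 0)
}
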