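#' Developmental stage order
#'
#' The seven stages, earliest first: embryoid body, blastocyst, fetus,
#' neonate, infant, juvenile, adult. Ordinal codes 1..7.
#'
#' @return character vector of length 7.
#' @export
devStages <- function() DEV_STAGES

# Decode triangular pair index t in 1..choose(n,2) to (i, j), i < j,
# enumeration order (1,2),(1,3),...,(1,n),(2,3),...
.pairDecode <- function(t, n) {
    offs <- c(0, cumsum(seq.int(n - 1L, 1L)))   # block starts per i
    i <- findInterval(t - 0.5, offs)
    j <- as.integer(t - offs[i] + i)
    cbind(as.integer(i), j)
}

#' Pairwise chromosomal distances within a gene set
#'
#' For every unordered pair of distinct genes on the same chromosome the
#' distance is the absolute difference of gene midpoints
#' (`(start + end) / 2`). If the total number of pairs exceeds `maxPairs` a
#' uniform random subsample of `maxPairs` pairs is drawn with `seed`.
#' Genes without a locus are skipped; their number is in the `"n_skipped"`
#' attribute.
#'
#' @param loci named `GRanges` from [readGeneLoci()].
#' @param genes character vector of gene ids (default: all loci).
#' @param maxPairs subsample cap (default 2e6).
#' @param seed integer seed used only when subsampling.
#' @return numeric vector of distances (bp); empty with attribute
#'   `"flag" = "no_pairs"` when no chromosome carries two genes.
#' @export
chromPairDistances <- function(loci, genes = names(loci), maxPairs = 2e6,
                               seed = 1L) {
    genes <- unique(as.character(genes))
    hit <- genes %in% names(loci)
    if (sum(!hit))
        message(sum(!hit), " gene(s) without locus skipped")
    gr <- loci[genes[hit]]
    mids <- (start(gr) + end(gr)) / 2
    bychr <- split(mids, as.character(seqnames(gr)))
    bychr <- bychr[order(names(bychr), method = "radix")]
    npair <- vapply(bychr, function(m) choose(length(m), 2), 0)
    total <- sum(npair)
    if (total == 0) {
        out <- numeric()
        attr(out, "flag") <- "no_pairs"
        attr(out, "n_skipped") <- sum(!hit)
        return(out)
    }
    if (total > maxPairs) {
        set.seed(seed)
        take <- sort(sample(total, maxPairs))
        offs <- cumsum(c(0, npair))
        out <- numeric(maxPairs)
        pos <- 1L
        for (ci in seq_along(bychr)) {
            sel <- take[take > offs[ci] & take <= offs[ci + 1L]] - offs[ci]
            if (!length(sel)) next
            ij <- .pairDecode(sel, length(bychr[[ci]]))
            d <- abs(bychr[[ci]][ij[, 1L]] - bychr[[ci]][ij[, 2L]])
            out[seq.int(pos, pos + length(d) - 1L)] <- d
            pos <- pos + length(d)
        }
    } else {
        out <- unlist(lapply(bychr, function(m) {
            if (length(m) < 2L) return(numeric())
            as.vector(stats::dist(m))
        }), use.names = FALSE)
    }
    attr(out, "n_skipped") <- sum(!hit)
    out
}

#' Distances over a gene-disjoint random matching
#'
#' Alternative to the all-pairs enumeration of [chromPairDistances()]: genes
#' on each chromosome are randomly paired (seeded; each gene used at most
#' once, one leftover gene per odd chromosome dropped) and one distance is
#' emitted per pair. Because the pairs share no genes, the distances are
#' independent draws, which keeps downstream rank-sum comparisons calibrated;
#' this is the default distance sampling of [runFullAnalysis()].
#'
#' @inheritParams chromPairDistances
#' @param seed integer seed for the matching.
#' @return numeric vector of distances (bp).
#' @export
matchedPairDistances <- function(loci, genes = names(loci), seed = 1L) {
    genes <- unique(as.character(genes))
    gr <- loci[genes[genes %in% names(loci)]]
    mids <- (start(gr) + end(gr)) / 2
    bychr <- split(mids, as.character(seqnames(gr)))
    bychr <- bychr[order(names(bychr), method = "radix")]
    set.seed(seed)
    out <- unlist(lapply(bychr, function(m) {
        n <- length(m)
        if (n < 2L) return(numeric())
        perm <- sample(n)
        k <- n %/% 2L
        abs(m[perm[seq_len(k)]] - m[perm[seq.int(k + 1L, 2L * k)]])
    }), use.names = FALSE)
    out
}

#' Per-chromosome table of gene-level DENs
#'
#' Pairs each gene's up- and down-DEN with its chromosome, for the paired
#' per-chromosome up-versus-down comparison. Genes without a locus are
#' excluded; their number is in the `"n_excluded"` attribute.
#'
#' @param geneCounts gene-level [RegulationCounts-class].
#' @param loci named `GRanges`.
#' @return data.frame with columns `gene_id`, `chrom`, `up_count`,
#'   `down_count`.
#' @export
chromosomeDenTable <- function(geneCounts, loci) {
    k <- regCounts(geneCounts)
    idx <- match(k$unit_id, names(loci))
    excl <- sum(is.na(idx))
    if (excl) message(excl, " gene(s) without locus excluded")
    keep <- !is.na(idx)
    out <- data.frame(gene_id = k$unit_id[keep],
                      chrom = as.character(seqnames(loci))[idx[keep]],
                      up_count = k$up_count[keep],
                      down_count = k$down_count[keep],
                      stringsAsFactors = FALSE)
    attr(out, "n_excluded") <- excl
    out
}

#' Tissue expression specificity (TES)
#'
#' TES is the largest expression value across tissues divided by the sum
#' over all tissues: `1/T` for a uniform profile over `T` tissues, `1` when
#' a single tissue carries all expression. Undefined (`NA`) when a gene's
#' profile sums to zero.
#'
#' @param x numeric matrix (genes in rows, tissues in columns) or a single
#'   profile as a numeric vector. Values must be non-negative; at least two
#'   tissues are required.
#' @return named numeric vector of TES scores in `[1/T, 1]`, `NA` where
#'   undefined.
#' @examples
#' tissueSpecificity(rbind(g1 = c(10, 10, 10, 10), g2 = c(5, 0, 0, 0)))
#' @export
tissueSpecificity <- function(x) {
    if (is.null(dim(x))) x <- matrix(x, nrow = 1L,
                                     dimnames = list("", names(x)))
    if (ncol(x) < 2L) stop("TES needs at least two tissues")
    if (any(x < 0, na.rm = TRUE)) stop("expression values must be >= 0")
    tot <- rowSums(x, na.rm = TRUE)
    tes <- apply(x, 1L, max, na.rm = TRUE) / tot
    tes[tot == 0] <- NA_real_
    setNames(as.numeric(tes), rownames(x))
}

#' Earliest expression stage as an ordinal
#'
#' Maps stage labels to their ordinal position in the fixed developmental
#' order (see [devStages()]): embryoid body = 1 ... adult = 7. Matching is
#' case-insensitive and tolerant of underscores. Genes with an unknown label
#' are excluded with a warning.
#'
#' @param stages character vector of stage labels, named by gene id.
#' @return named integer vector of ordinals in 1..7 (unknown labels
#'   removed).
#' @export
earliestStage <- function(stages) {
    lab <- gsub("_", " ", .normLabel(as.character(stages)))
    ord <- match(lab, DEV_STAGES)
    if (anyNA(ord)) {
        bad <- unique(lab[is.na(ord)])
        warning("unknown stage label(s) excluded: ",
                paste(head(bad, 5L), collapse = ", "))
    }
    out <- setNames(ord, names(stages))
    out[!is.na(out)]
}

#' Disease-SNP status of variant records
#'
#' A variant is a disease-related SNP (dSNP) iff it has a dbSNP identifier,
#' carries at least one clinical-significance label, and none of its labels
#' is in the exclusion set: protective, benign, likely benign, uncertain
#' significance, conflicting data from submitters, other, not provided.
#'
#' @param variants `GRanges` from [readVariants()].
#' @return logical vector along `variants`.
#' @export
isDiseaseSnp <- function(variants) {
    cs <- mcols(variants)$clin_sig
    hasId <- !is.na(mcols(variants)$rs_id)
    nlab <- lengths(cs)
    flat <- unlist(cs, use.names = FALSE)
    owner <- rep.int(seq_along(cs), nlab)
    excluded <- logical(length(cs))
    excluded[unique(owner[flat %in% DSNP_EXCLUDED_LABELS])] <- TRUE
    hasId & nlab > 0L & !excluded
}

#' Per-gene SNP and disease-SNP summary
#'
#' Counts the variants falling inside each gene's genomic span (positions
#' are single base pairs; a variant just past the span is not counted) and
#' those that additionally pass `dsnpFilter`. SNP density is the count
#' divided by the span length in bp.
#'
#' @param loci named `GRanges`.
#' @param variants `GRanges` from [readVariants()].
#' @param dsnpFilter function mapping the variants to a logical vector;
#'   default [isDiseaseSnp()].
#' @return data.frame with columns `gene_id`, `snp_count`, `dsnp_count`,
#'   `gene_length`, `snp_density`.
#' @export
variantSummary <- function(loci, variants, dsnpFilter = isDiseaseSnp) {
    snp <- countOverlaps(loci, variants)
    dsnp <- countOverlaps(loci, variants[dsnpFilter(variants)])
    data.frame(gene_id = names(loci),
               snp_count = as.integer(snp),
               dsnp_count = as.integer(dsnp),
               gene_length = width(loci),
               snp_density = as.integer(snp) / width(loci),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Interaction-network degrees after edge filtering
#'
#' Removes genetic interactions and ubiquitination edges (covalent
#' ubiquitin-substrate links), collapses the remaining multigraph to a
#' simple undirected graph without self-loops, and reports each gene's
#' number of distinct partners. Genes whose every edge was filtered away
#' keep degree 0.
#'
#' @param edges data.frame from [readInteractions()].
#' @param dropGenetic,dropUbiquitination logical filter switches.
#' @return data.frame with columns `gene_id`, `degree`, sorted by gene id.
#' @export
ppiDegrees <- function(edges, dropGenetic = TRUE, dropUbiquitination = TRUE) {
    verts <- sort(unique(c(edges$gene_a, edges$gene_b)), method = "radix")
    keep <- rep(TRUE, nrow(edges))
    if (dropGenetic) keep <- keep & edges$system_class != "genetic"
    if (dropUbiquitination) {
        m <- edges$modification
        keep <- keep & (is.na(m) | tolower(m) != "ubiquitination")
    }
    e <- edges[keep & edges$gene_a != edges$gene_b, c("gene_a", "gene_b")]
    g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                       vertices = verts)
    g <- igraph::simplify(g)
    deg <- igraph::degree(g)
    data.frame(gene_id = verts, degree = as.integer(deg[verts]),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Subcellular classes from GO annotations
#'
#' Assigns each gene the subset of the four compartments -- extracellular
#' region (GO:0005576), membrane (GO:0016020), cytoplasm (GO:0005737),
#' nucleus (GO:0005634) -- whose term annotates it directly. Annotations
#' whose qualifier contains `NOT` are ignored; no ontology-graph propagation
#' is performed.
#'
#' @param gaf data.frame from [readGaf()].
#' @return data.frame with columns `gene_id`, `class` (one row per
#'   gene-class assignment; genes with no qualifying annotation are absent).
#' @export
subcellularClasses <- function(gaf) {
    keep <- !grepl("NOT", gaf$qualifier, fixed = TRUE) &
        gaf$go_id %in% names(SUBCELL_GO_TERMS)
    df <- gaf[keep, , drop = FALSE]
    out <- unique(data.frame(gene_id = df$gene_id,
                             class = unname(SUBCELL_GO_TERMS[df$go_id]),
                             stringsAsFactors = FALSE))
    out[.radixOrder(out$gene_id, out$class), , drop = FALSE]
}
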