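#' Assemble the per-gene feature bundle
#'
#' Light validation and naming for the feature tables consumed by
#' [runFullAnalysis()]. All elements are optional; comparisons whose inputs
#' are missing are skipped with a logged reason.
#'
#' @param loci named `GRanges` of gene loci.
#' @param tes named numeric vector of tissue expression specificity scores
#'   (see [tissueSpecificity()]).
#' @param ees named integer vector of earliest-stage ordinals (see
#'   [earliestStage()]).
#' @param homolog named numeric vector of homologous gene numbers.
#' @param phyletic named character vector of phyletic-age categories.
#' @param phyleticLevels optional character vector giving the age categories
#'   in evolutionary order (oldest first).
#' @param variants data.frame from [variantSummary()].
#' @param degree named integer vector of PPI degrees (see [ppiDegrees()]).
#' @param classes data.frame from [subcellularClasses()].
#' @return list of class `denFeatures`.
#' @export
denFeatures <- function(loci = NULL, tes = NULL, ees = NULL, homolog = NULL,
                        phyletic = NULL, phyleticLevels = NULL,
                        variants = NULL, degree = NULL, classes = NULL) {
    named <- function(x, what) {
        if (!is.null(x) && is.null(names(x)))
            stop(what, " must be named by gene id")
        x
    }
    structure(list(loci = loci, tes = named(tes, "tes"),
                   ees = named(ees, "ees"), homolog = named(homolog, "homolog"),
                   phyletic = named(phyletic, "phyletic"),
                   phyleticLevels = phyleticLevels,
                   variants = variants, degree = named(degree, "degree"),
                   classes = classes),
              class = "denFeatures")
}

# Comparisons the full analysis can run.
ALL_COMPARISONS <- c("distance", "tes", "tes_spearman", "ees", "homolog",
                     "phyletic", "snp_density", "dsnp", "dsnp_chrom",
                     "degree", "degree_spearman", "subcellular",
                     "chrom_updown")

# Split a named feature vector by partition membership; NULL when either
# group would have < 2 usable genes.
.groupSplit <- function(feat, hi, lo) {
    a <- feat[names(feat) %in% hi]
    b <- feat[names(feat) %in% lo]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L) return(NULL)
    list(high = a, low = b)
}

#' Run every configured high-vs-low comparison
#'
#' For each regulation direction the genes are partitioned with
#' [partitionGenes()] and compared over the available feature axes:
#' chromosomal distances (rank-sum; by default over a gene-disjoint random
#' matching, see [matchedPairDistances()]), TES (rank-sum, plus Spearman
#' against the DEN), earliest expression stage (chi-squared on the
#' stage-by-group table), homolog number (rank-sum), phyletic age
#' (chi-squared), SNP density (Kolmogorov-Smirnov), disease-SNP fraction
#' (Fisher overall; per-chromosome chi-squared), interaction degree
#' (rank-sum plus Spearman), subcellular classes (chi-squared over the
#' top-N/last-N sets), and the per-chromosome paired up-versus-down
#' signed-rank comparison. Comparisons whose inputs are missing, degenerate
#' or too small are skipped with a logged reason, never a hard failure.
#'
#' @param geneCounts gene-level [RegulationCounts-class].
#' @param features a [denFeatures()] bundle.
#' @param directions regulation directions to analyze.
#' @param fraction high-set fraction for [partitionGenes()].
#' @param nTopLast set size for the subcellular top/last comparison; skipped
#'   (with a log entry) when `2 * nTopLast` exceeds the gene count.
#' @param distancePairing `"matched"` (default, keeps distances independent)
#'   or `"all"` (all same-chromosome pairs, subsampled at `maxPairs`).
#' @param maxPairs cap for `distancePairing = "all"`.
#' @param seed integer; seeds the distance pairing/subsampling.
#' @param enabled character vector of comparisons to run.
#' @return data.frame of ComparisonResult rows with columns `den_direction`
#'   and BH-adjusted `p_bh` added; skipped comparisons are recorded in the
#'   `"skipped"` attribute.
#' @export
runFullAnalysis <- function(geneCounts, features,
                            directions = c("up", "down"), fraction = 0.15,
                            nTopLast = 1000L,
                            distancePairing = c("matched", "all"),
                            maxPairs = 2e6, seed = 1L,
                            enabled = ALL_COMPARISONS) {
    distancePairing <- match.arg(distancePairing)
    stopifnot(inherits(features, "denFeatures"))
    enabled <- match.arg(enabled, ALL_COMPARISONS, several.ok = TRUE)
    rows <- list()
    skipped <- list()
    skip <- function(feature, dirn, reason)
        skipped[[length(skipped) + 1L]] <<-
            data.frame(feature = feature, den_direction = dirn,
                       reason = reason, stringsAsFactors = FALSE)
    add <- function(row, dirn) {
        row$den_direction <- dirn
        rows[[length(rows) + 1L]] <<- row
    }
    try_cmp <- function(feature, dirn, expr) {
        res <- tryCatch(expr, error = function(e) conditionMessage(e))
        if (is.character(res)) skip(feature, dirn, res) else add(res, dirn)
    }
    seeds <- .childSeeds(seed, 2L * length(directions))
    si <- 0L

    for (dirn in directions) {
        part <- partitionGenes(geneCounts, dirn, fraction)
        hi <- highSet(part); lo <- lowSet(part)
        labs <- paste0(dirn, c("_h", "_l"))
        cnt <- if (dirn == "up") upCounts(geneCounts)
               else downCounts(geneCounts)

        if ("distance" %in% enabled) {
            si <- si + 1L
            s1 <- seeds[si]; si <- si + 1L; s2 <- seeds[si]
            try_cmp("chrom_distance", dirn, {
                if (is.null(features$loci)) stop("no loci available")
                dh <- if (distancePairing == "matched")
                    matchedPairDistances(features$loci, hi, seed = s1)
                else suppressMessages(
                    chromPairDistances(features$loci, hi, maxPairs, s1))
                dl <- if (distancePairing == "matched")
                    matchedPairDistances(features$loci, lo, seed = s2)
                else suppressMessages(
                    chromPairDistances(features$loci, lo, maxPairs, s2))
                if (length(dh) < 2L || length(dl) < 2L)
                    stop("fewer than 2 same-chromosome pairs in a group")
                rankSumTest(dh, dl, "chrom_distance", labs[1], labs[2])
            })
        }
        if ("tes" %in% enabled)
            try_cmp("tes", dirn, {
                g <- .groupSplit(features$tes, hi, lo)
                if (is.null(g)) stop("fewer than 2 genes with TES in a group")
                rankSumTest(g$high, g$low, "tes", labs[1], labs[2])
            })
        if ("tes_spearman" %in% enabled)
            try_cmp("tes_vs_den", dirn, {
                common <- intersect(names(cnt), names(features$tes))
                common <- common[!is.na(features$tes[common])]
                if (length(common) < 3L) stop("fewer than 3 genes with TES")
                spearmanCorr(cnt[common], features$tes[common], "tes_vs_den",
                             paste0(dirn, "_den"), "tes")
            })
        if ("ees" %in% enabled)
            try_cmp("ees", dirn, {
                g <- .groupSplit(features$ees, hi, lo)
                if (is.null(g)) stop("fewer than 2 genes with EES in a group")
                lev <- sort(unique(c(g$high, g$low)))
                tab <- cbind(high = table(factor(g$high, levels = lev)),
                             low = table(factor(g$low, levels = lev)))
                chiSquaredTable(tab, "ees",
                                .dirFromDelta(mean(g$high) - mean(g$low)),
                                labs[1], labs[2])
            })
        if ("homolog" %in% enabled)
            try_cmp("homolog_count", dirn, {
                g <- .groupSplit(features$homolog, hi, lo)
                if (is.null(g))
                    stop("fewer than 2 genes with homolog counts in a group")
                rankSumTest(g$high, g$low, "homolog_count", labs[1], labs[2])
            })
        if ("phyletic" %in% enabled)
            try_cmp("phyletic_age", dirn, {
                ph <- features$phyletic
                if (is.null(ph)) stop("no phyletic ages available")
                lev <- if (!is.null(features$phyleticLevels))
                    features$phyleticLevels else sort(unique(ph),
                                                      method = "radix")
                ords <- setNames(match(ph, lev), names(ph))
                g <- .groupSplit(ords, hi, lo)
                if (is.null(g))
                    stop("fewer than 2 genes with phyletic age in a group")
                lev2 <- sort(unique(c(g$high, g$low)))
                tab <- cbind(high = table(factor(g$high, levels = lev2)),
                             low = table(factor(g$low, levels = lev2)))
                chiSquaredTable(tab, "phyletic_age",
                                .dirFromDelta(mean(g$high) - mean(g$low)),
                                labs[1], labs[2])
            })
        if ("snp_density" %in% enabled)
            try_cmp("snp_density", dirn, {
                vs <- features$variants
                if (is.null(vs)) stop("no variant summary available")
                dens <- setNames(vs$snp_density, vs$gene_id)
                g <- .groupSplit(dens, hi, lo)
                if (is.null(g))
                    stop("fewer than 2 genes with SNP density in a group")
                ksTwoSample(g$high, g$low, "snp_density", labs[1], labs[2])
            })
        if ("dsnp" %in% enabled)
            try_cmp("dsnp_fraction", dirn, {
                vs <- features$variants
                if (is.null(vs)) stop("no variant summary available")
                inHi <- vs$gene_id %in% hi
                inLo <- vs$gene_id %in% lo
                tab <- rbind(
                    dsnp = c(sum(vs$dsnp_count[inHi]),
                             sum(vs$dsnp_count[inLo])),
                    other = c(sum(vs$snp_count[inHi] - vs$dsnp_count[inHi]),
                              sum(vs$snp_count[inLo] - vs$dsnp_count[inLo])))
                colnames(tab) <- labs
                fisher2x2(tab, "dsnp_fraction", labs[1], labs[2])
            })
        if ("dsnp_chrom" %in% enabled && !is.null(features$variants) &&
            !is.null(features$loci)) {
            vs <- features$variants
            chrom <- setNames(as.character(seqnames(features$loci)),
                              names(features$loci))
            vs_chrom <- chrom[vs$gene_id]
            for (ch in sort(unique(vs_chrom[!is.na(vs_chrom)]),
                            method = "radix")) {
                sel <- !is.na(vs_chrom) & vs_chrom == ch
                feature <- paste0("dsnp_fraction_", ch)
                try_cmp(feature, dirn, {
                    v <- vs[sel, , drop = FALSE]
                    inHi <- v$gene_id %in% hi
                    inLo <- v$gene_id %in% lo
                    tab <- rbind(
                        dsnp = c(sum(v$dsnp_count[inHi]),
                                 sum(v$dsnp_count[inLo])),
                        other = c(sum(v$snp_count[inHi] -
                                          v$dsnp_count[inHi]),
                                  sum(v$snp_count[inLo] -
                                          v$dsnp_count[inLo])))
                    colnames(tab) <- labs
                    chiSquaredTable(tab, feature, groupHigh = labs[1],
                                    groupLow = labs[2])
                })
            }
        }
        if ("degree" %in% enabled)
            try_cmp("ppi_degree", dirn, {
                g <- .groupSplit(features$degree, hi, lo)
                if (is.null(g))
                    stop("fewer than 2 genes with degree in a group")
                rankSumTest(g$high, g$low, "ppi_degree", labs[1], labs[2])
            })
        if ("degree_spearman" %in% enabled)
            try_cmp("degree_vs_den", dirn, {
                common <- intersect(names(cnt), names(features$degree))
                if (length(common) < 3L) stop("fewer than 3 genes with degree")
                spearmanCorr(cnt[common], features$degree[common],
                             "degree_vs_den", paste0(dirn, "_den"), "degree")
            })
        if ("subcellular" %in% enabled)
            try_cmp("subcellular", dirn, {
                cls <- features$classes
                if (is.null(cls)) stop("no subcellular classes available")
                tl <- topLastN(geneCounts, dirn, nTopLast)
                setlab <- paste0(c("T", "L"), nTopLast,
                                 toupper(substr(dirn, 1, 1)))
                inT <- cls[cls$gene_id %in% tl$top, , drop = FALSE]
                inL <- cls[cls$gene_id %in% tl$last, , drop = FALSE]
                if (nrow(inT) < 2L || nrow(inL) < 2L)
                    stop("fewer than 2 classified genes in a set")
                lev <- sort(unique(c(inT$class, inL$class)), method = "radix")
                tab <- cbind(top = table(factor(inT$class, levels = lev)),
                             last = table(factor(inL$class, levels = lev)))
                colnames(tab) <- setlab
                chiSquaredTable(tab, "subcellular", groupHigh = setlab[1],
                                groupLow = setlab[2])
            })
    }

    # per-chromosome paired up-vs-down comparison (direction-free)
    if ("chrom_updown" %in% enabled && is.null(features$loci))
        skip("chrom_updown", "both", "no loci available")
    if ("chrom_updown" %in% enabled && !is.null(features$loci)) {
        cdt <- suppressMessages(chromosomeDenTable(geneCounts,
                                                   features$loci))
        for (ch in sort(unique(cdt$chrom), method = "radix")) {
            sel <- cdt$chrom == ch
            feature <- paste0("chrom_updown_", ch)
            try_cmp(feature, "both", {
                if (sum(sel) < 2L) stop("fewer than 2 genes on chromosome")
                signedRankPaired(cdt$up_count[sel], cdt$down_count[sel],
                                 feature, "up", "down")
            })
        }
    }

    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- .comparisonRow("none", "chi_squared", NA, 1, "none",
                              0, 0)[0, ]
    out <- adjustComparisons(out)
    rownames(out) <- NULL
    attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
                            else data.frame(feature = character(),
                                            den_direction = character(),
                                            reason = character())
    out
}
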