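# Every test returns a one-row data.frame -- a ComparisonResult -- with a
# common column set, so results from the whole analysis stack row-bind into
# one tidy table.
.comparisonRow <- function(feature, test, statistic, p, direction,
                           nHigh, nLow, summaryHigh = NA_real_,
                           summaryLow = NA_real_, groupHigh = "high",
                           groupLow = "low", flag = NA_character_) {
    p <- min(max(p, 0), 1)
    if (p == 0) {                       # report a positive floor, never 0
        p <- .Machine$double.xmin
        flag <- if (is.na(flag)) "p_floor" else paste(flag, "p_floor", sep = ";")
    }
    data.frame(feature = feature, test = test,
               group_high = groupHigh, group_low = groupLow,
               n_high = as.integer(nHigh), n_low = as.integer(nLow),
               statistic = as.numeric(statistic), p_value = p,
               direction = direction,
               summary_high = as.numeric(summaryHigh),
               summary_low = as.numeric(summaryLow),
               flag = flag, stringsAsFactors = FALSE)
}

.dirFromDelta <- function(delta) {
    if (is.na(delta) || delta == 0) "none"
    else if (delta > 0) "high_greater" else "low_greater"
}

#' Two-sided Mann-Whitney rank-sum comparison
#'
#' Exact enumeration p-value when the pooled sample size is at most 12 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections. Effect direction is taken from the medians.
#'
#' @param a,b numeric samples (`a` = high group, `b` = low group).
#' @param feature label for the result row.
#' @param groupHigh,groupLow group labels for the result row.
#' @return one-row ComparisonResult data.frame.
#' @examples
#' rankSumTest(c(1, 2, 3), c(4, 5, 6))$p_value  # exact: 0.1
#' @export
rankSumTest <- function(a, b, feature = "feature",
                        groupHigh = "high", groupLow = "low") {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (!length(a) || !length(b)) stop("empty sample in rank-sum test")
    ties <- anyDuplicated(c(a, b)) > 0L
    exact <- (length(a) + length(b)) <= 12L && !ties
    wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
    delta <- median(a) - median(b)
    .comparisonRow(feature, "wilcoxon_ranksum", wt$statistic, wt$p.value,
                   .dirFromDelta(delta), length(a), length(b),
                   median(a), median(b), groupHigh, groupLow,
                   flag = if (exact) "exact" else NA_character_)
}

#' Two-sided Wilcoxon signed-rank comparison of paired samples
#'
#' Differences of zero are dropped. Exact sign-enumeration p-value when at
#' most 12 nonzero pairs without tied magnitudes; otherwise the normal
#' approximation with corrections. If every difference is zero the result is
#' `p = 1` with direction `none`.
#'
#' @param x,y numeric samples paired by index (`x` = first member).
#' @inheritParams rankSumTest
#' @return one-row ComparisonResult data.frame.
#' @export
signedRankPaired <- function(x, y, feature = "feature",
                             groupHigh = "x", groupLow = "y") {
    if (length(x) != length(y)) stop("paired samples differ in length")
    keep <- !(is.na(x) | is.na(y))
    x <- x[keep]; y <- y[keep]
    if (length(x) < 2L) stop("need at least 2 pairs")
    d <- x - y
    nz <- d[d != 0]
    if (!length(nz))
        return(.comparisonRow(feature, "wilcoxon_signedrank", 0, 1, "none",
                              length(x), length(y), median(x), median(y),
                              groupHigh, groupLow, flag = "all_zero"))
    exact <- length(nz) <= 12L && !anyDuplicated(abs(nz))
    wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = exact,
                                       correct = TRUE))
    .comparisonRow(feature, "wilcoxon_signedrank", wt$statistic, wt$p.value,
                   .dirFromDelta(median(d)), length(x), length(y),
                   median(x), median(y), groupHigh, groupLow,
                   flag = if (exact) "exact" else NA_character_)
}

#' Pearson chi-squared test on an r x c count table
#'
#' No continuity correction; df = (r-1)(c-1). A zero row or column margin is
#' a hard error naming the margin; tables with any expected count below 5
#' are flagged `low_expected`.
#'
#' @param tab numeric matrix of counts.
#' @param direction optional effect direction to carry into the result
#'   (chi-squared itself is direction-free).
#' @inheritParams rankSumTest
#' @return one-row ComparisonResult data.frame with attribute
#'   `"table"` holding `tab`.
#' @export
chiSquaredTable <- function(tab, feature = "feature", direction = "none",
                            groupHigh = "high", groupLow = "low") {
    tab <- as.matrix(tab)
    if (any(tab < 0)) stop("counts must be non-negative")
    rm <- rowSums(tab); cm <- colSums(tab)
    if (any(rm == 0))
        stop("zero row margin in contingency table: row ",
             which(rm == 0)[1L])
    if (any(cm == 0))
        stop("zero column margin in contingency table: column ",
             which(cm == 0)[1L])
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    flag <- if (any(ct$expected < 5)) "low_expected" else NA_character_
    out <- .comparisonRow(feature, "chi_squared", ct$statistic, ct$p.value,
                          direction, sum(tab[, 1L]),
                          sum(tab[, -1L, drop = FALSE]),
                          groupHigh = groupHigh, groupLow = groupLow,
                          flag = flag)
    attr(out, "table") <- tab
    attr(out, "df") <- unname(ct$parameter)
    out
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided; `D` is the maximum absolute difference of the two empirical
#' CDFs, with the asymptotic p-value. Direction from the medians.
#'
#' @inheritParams rankSumTest
#' @return one-row ComparisonResult data.frame.
#' @export
ksTwoSample <- function(a, b, feature = "feature",
                        groupHigh = "high", groupLow = "low") {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (!length(a) || !length(b)) stop("empty sample in KS test")
    kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
    .comparisonRow(feature, "ks_two_sample", kt$statistic, kt$p.value,
                   .dirFromDelta(median(a) - median(b)),
                   length(a), length(b), median(a), median(b),
                   groupHigh, groupLow)
}

#' Fisher exact test on a 2 x 2 table
#'
#' Two-sided exact p-value (sum of hypergeometric probabilities no larger
#' than the observed table's). The reported statistic is the sample odds
#' ratio, with 0.5 added to every cell for display only when some cell is
#' zero. A degenerate margin yields `p = 1`.
#'
#' @param tab 2 x 2 numeric matrix: rows = outcome (e.g. dSNP / other SNP),
#'   columns = group (high, low).
#' @inheritParams rankSumTest
#' @return one-row ComparisonResult data.frame.
#' @export
fisher2x2 <- function(tab, feature = "feature",
                      groupHigh = "high", groupLow = "low") {
    tab <- as.matrix(tab)
    storage.mode(tab) <- "double"      # cell products can exceed 2^31
    stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0))
    degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
    p <- if (degenerate) 1 else fisher.test(tab)$p.value
    disp <- if (any(tab == 0)) tab + 0.5 else tab
    orat <- (disp[1, 1] * disp[2, 2]) / (disp[1, 2] * disp[2, 1])
    fracHigh <- if (sum(tab[, 1L]) > 0) tab[1, 1] / sum(tab[, 1L]) else NA
    fracLow <- if (sum(tab[, 2L]) > 0) tab[1, 2] / sum(tab[, 2L]) else NA
    delta <- if (is.na(fracHigh) || is.na(fracLow)) NA else fracHigh - fracLow
    out <- .comparisonRow(feature, "fisher_exact", orat, p,
                          .dirFromDelta(delta), sum(tab[, 1L]),
                          sum(tab[, 2L]), fracHigh, fracLow,
                          groupHigh, groupLow,
                          flag = if (degenerate) "degenerate_margin"
                                 else NA_character_)
    attr(out, "table") <- tab
    out
}

#' Spearman rank correlation
#'
#' `rho` is the Pearson correlation of average-ranked values (ties get
#' average ranks); the p-value comes from the t approximation with `n - 2`
#' degrees of freedom. Zero variance in either ranked vector gives an
#' undefined, flagged result.
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs).
#' @inheritParams rankSumTest
#' @return one-row ComparisonResult data.frame; `direction` is
#'   `high_greater` for positive rho, `low_greater` for negative.
#' @export
spearmanCorr <- function(x, y, feature = "feature",
                         groupHigh = "x", groupLow = "y") {
    keep <- !(is.na(x) | is.na(y))
    x <- x[keep]; y <- y[keep]
    n <- length(x)
    if (n < 3L) stop("need at least 3 complete pairs")
    if (sd(x) == 0 || sd(y) == 0)
        return(.comparisonRow(feature, "spearman", NA, 1, "none", n, n,
                              groupHigh = groupHigh, groupLow = groupLow,
                              flag = "zero_variance"))
    rho <- cor(x, y, method = "spearman")
    if (abs(rho) >= 1) {
        p <- 0
    } else {
        tstat <- rho * sqrt((n - 2) / (1 - rho^2))
        p <- 2 * pt(-abs(tstat), df = n - 2)
    }
    .comparisonRow(feature, "spearman", rho, p, .dirFromDelta(rho),
                   n, n, groupHigh = groupHigh, groupLow = groupLow)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Convenience wrapper adding a `p_bh` column across a suite of comparison
#' rows. Headline inference uses the raw p-values (as in the source
#' analyses); the BH column is emitted for transparency.
#'
#' @param results data.frame of ComparisonResult rows.
#' @return `results` with a `p_bh` column.
#' @export
adjustComparisons <- function(results) {
    results$p_bh <- p.adjust(results$p_value, method = "BH")
    results
}
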