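# Independent brute-force oracles. These deliberately share no code with
# the package: double loops, full enumerations and direct formulas only.

# DEN counting by an explicit double loop over all cells.
bruteCountRegulation <- function(values, upCut, downCut) {
    n <- nrow(values)
    up <- integer(n); dn <- integer(n)
    for (i in seq_len(n)) {
        for (j in seq_len(ncol(values))) {
            v <- values[i, j]
            if (is.na(v)) next
            if (v > upCut) up[i] <- up[i] + 1L
            if (v < downCut) dn[i] <- dn[i] + 1L
        }
    }
    list(up = up, down = dn)
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled values to group A (requires no ties for exactness).
enumRankSumP <- function(a, b) {
    pool <- c(a, b)
    m <- length(a); n <- length(b)
    idx <- utils::combn(m + n, m)
    uStat <- function(sel) {
        r <- rank(pool)
        sum(r[sel]) - m * (m + 1) / 2
    }
    uobs <- uStat(seq_len(m))
    c0 <- m * n / 2
    us <- apply(idx, 2L, uStat)
    mean(abs(us - c0) >= abs(uobs - c0) - 1e-12)
}

# Exact two-sided signed-rank p by enumerating all 2^k sign patterns of the
# nonzero differences.
enumSignedRankP <- function(x, y) {
    d <- x - y
    d <- d[d != 0]
    k <- length(d)
    r <- rank(abs(d))
    vobs <- sum(r[d > 0])
    c0 <- sum(r) / 2
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), k)))
    vs <- as.vector(signs %*% r)
    mean(abs(vs - c0) >= abs(vobs - c0) - 1e-12)
}

# Two-sided Fisher exact p by enumerating every table with the observed
# margins and summing hypergeometric probabilities <= the observed one.
enumFisherP <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    lo <- max(0, k - n); hi <- min(k, m)
    probs <- stats::dhyper(lo:hi, m, n, k)
    pobs <- stats::dhyper(tab[1, 1], m, n, k)
    sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Pearson chi-squared statistic by the direct formula.
chiStatOracle <- function(tab) {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - E)^2 / E)
}

# Two-sample KS statistic by an explicit ECDF sweep.
ksDOracle <- function(a, b) {
    xs <- sort(unique(c(a, b)))
    Fa <- vapply(xs, function(x) mean(a <= x), 0)
    Fb <- vapply(xs, function(x) mean(b <= x), 0)
    max(abs(Fa - Fb))
}

# Spearman rho: explicit average ranks, then the Pearson formula by hand.
spearmanOracle <- function(x, y) {
    avgRank <- function(v) {
        s <- sort(v)
        vapply(v, function(z) mean(which(s == z)), 0)
    }
    rx <- avgRank(x); ry <- avgRank(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
        sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
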