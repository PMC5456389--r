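test_that("threshold construction validates signs", {
    th <- denThresholds()
    expect_equal(th$upCut, 0.69)
    expect_equal(th$downCut, -0.69)
    expect_error(denThresholds(-0.1, -0.5), "downCut < 0 < upCut")
    expect_error(denThresholds(0.5, 0.1), "downCut < 0 < upCut")
})

test_that("regulation events need strict threshold crossings", {
    m <- makeFcm(matrix(c(0.70, -0.80, 0.50), nrow = 1))
    k <- regCounts(countRegulation(m))
    expect_identical(k$up_count, 1L)
    expect_identical(k$down_count, 1L)
    # boundary values are not events; missing cells count in neither
    m2 <- makeFcm(matrix(c(0.69, -0.69, NA, 0.6901), nrow = 1))
    k2 <- regCounts(countRegulation(m2))
    expect_identical(k2$up_count, 1L)
    expect_identical(k2$down_count, 0L)
})

test_that("counting matches the brute-force double loop on random matrices", {
    set.seed(101)
    for (i in 1:12) {
        nr <- sample(5:20, 1); nc <- sample(10:50, 1)
        v <- matrix(rnorm(nr * nc, sd = 0.8), nr, nc)
        v[sample(length(v), round(0.05 * length(v)))] <- NA
        th <- denThresholds(runif(1, 0.3, 1), -runif(1, 0.3, 1))
        got <- regCounts(countRegulation(makeFcm(v), th))
        want <- bruteCountRegulation(v, th$upCut, th$downCut)
        expect_identical(got$up_count, want$up)
        expect_identical(got$down_count, want$down)
    }
})

test_that("raising thresholds never increases event counts", {
    set.seed(7)
    v <- matrix(rnorm(400), 20, 20)
    m <- makeFcm(v)
    base <- regCounts(countRegulation(m, denThresholds(0.5, -0.5)))
    tighter <- regCounts(countRegulation(m, denThresholds(0.8, -0.9)))
    expect_true(all(tighter$up_count <= base$up_count))
    expect_true(all(tighter$down_count <= base$down_count))
})

test_that("probe-to-gene aggregation honours the policy", {
    v <- rbind(p1 = c(rep(1, 3), rep(0, 7)),    # up-DEN 3
               p2 = c(rep(1, 7), rep(0, 3)),    # up-DEN 7
               px = c(rep(1, 2), rep(0, 8)))    # unmapped
    m <- makeFcm(v, probes = rownames(v))
    pc <- countRegulation(m)
    map <- data.frame(probe_id = c("p1", "p2"), gene_id = "G")
    expect_message(agg <- aggregateToGenes(pc, map, "max"), "1 unmapped")
    expect_identical(regCounts(agg)$up_count, 7L)
    agg2 <- suppressMessages(aggregateToGenes(pc, map, "sum"))
    expect_identical(regCounts(agg2)$up_count, 10L)
    agg3 <- suppressMessages(aggregateToGenes(pc, map, "mean"))
    expect_identical(regCounts(agg3)$up_count, 5L)
    # mean rounds half up: probes with up-DEN 1 and 2 -> 2
    map2 <- data.frame(probe_id = c("p1", "px"), gene_id = "H")
    v2 <- rbind(p1 = c(1, 1, 1, rep(0, 7)), px = c(1, 1, rep(0, 8)))
    pch <- countRegulation(makeFcm(v2, probes = rownames(v2)))
    agg4 <- suppressMessages(aggregateToGenes(pch, map2, "mean"))
    expect_identical(regCounts(agg4)$up_count, 3L)  # mean(3,2)=2.5 -> 3
    # no probe mapped at all is a hard error
    expect_error(suppressMessages(aggregateToGenes(
        pc, data.frame(probe_id = "nope", gene_id = "G"))), "no probe")
})

test_that("partition sizes follow floor(fraction * N) with deterministic ties", {
    gc <- makeGeneCounts(sprintf("g%03d", 1:100), up = 100:1, down = 1:100)
    p <- partitionGenes(gc, "up", 0.15)
    expect_length(highSet(p), 15L)
    expect_setequal(highSet(p), sprintf("g%03d", 1:15))
    # N = 10, fraction 0.15 -> k = floor(1.5) = 1
    gc10 <- makeGeneCounts(sprintf("g%02d", 1:10), up = 10:1, down = 1:10)
    expect_length(highSet(partitionGenes(gc10, "up", 0.15)), 1L)
    # all tied: the k lexicographically smallest ids win
    gct <- makeGeneCounts(sample(sprintf("g%03d", 1:40)), up = rep(5, 40),
                          down = rep(5, 40))
    pt <- partitionGenes(gct, "up", 0.15)
    expect_identical(sort(highSet(pt)), sprintf("g%03d", 1:6))
    expect_error(partitionGenes(gc, "up", 1.5), "fraction")
})

test_that("high and low sets always partition all scored genes", {
    set.seed(5)
    for (N in c(10, 57, 200)) {
        for (fr in c(0.1, 0.15, 0.5)) {
            gc <- makeGeneCounts(sprintf("g%04d", seq_len(N)),
                                 up = rpois(N, 3), down = rpois(N, 3))
            p <- partitionGenes(gc, sample(c("up", "down"), 1), fr)
            expect_length(c(highSet(p), lowSet(p)), N)
            expect_length(intersect(highSet(p), lowSet(p)), 0L)
            expect_length(highSet(p), floor(fr * N))
        }
    }
})

test_that("gene counts are invariant to row and column shuffles", {
    set.seed(33)
    v <- matrix(rnorm(30 * 12), 30, 12)
    m1 <- makeFcm(v)
    perm <- sample(30); permc <- sample(12)
    m2 <- FoldChangeMatrix(lnFC(m1)[perm, permc])
    map <- data.frame(probe_id = probeIds(m1),
                      gene_id = rep(sprintf("G%02d", 1:10), each = 3))
    g1 <- regCounts(suppressMessages(
        aggregateToGenes(countRegulation(m1), map)))
    g2 <- regCounts(suppressMessages(
        aggregateToGenes(countRegulation(m2), map)))
    expect_identical(g1, g2)
})

test_that("top/last-N sets are disjoint, ordered and deterministic", {
    gc <- makeGeneCounts(sprintf("g%02d", 1:10), up = c(9, 9, 7, 6, 5, 5,
                                                        3, 2, 1, 0),
                         down = rep(0, 10))
    tl <- topLastN(gc, "up", 3L)
    expect_identical(tl$top, c("g01", "g02", "g03"))
    expect_identical(tl$last, c("g08", "g09", "g10"))
    expect_length(intersect(tl$top, tl$last), 0L)
    # n = N/2 partitions all genes
    tl5 <- topLastN(gc, "up", 5L)
    expect_setequal(c(tl5$top, tl5$last), sprintf("g%02d", 1:10))
    # determinism under ties
    gct <- makeGeneCounts(sample(sprintf("g%02d", 1:10)), up = rep(4, 10),
                          down = rep(0, 10))
    expect_identical(topLastN(gct, "up", 3L), topLastN(gct, "up", 3L))
    expect_error(topLastN(gc, "up", 6L), "exceeds")
})

test_that("set overlap summaries are exact set arithmetic", {
    ov <- partitionOverlap(c("1", "2", "3"), c("3", "4"))
    expect_identical(ov$n_intersect, 1L)
    expect_equal(ov$jaccard, 0.25)
    expect_equal(partitionOverlap(letters[1:4], letters[1:4])$jaccard, 1)
    expect_equal(partitionOverlap(letters[1:3], letters[5:7])$jaccard, 0)
})

test_that("DEN distribution summaries report top-fraction share", {
    gc <- makeGeneCounts(sprintf("g%02d", 1:20),
                         up = c(10, rep(0, 19)), down = rep(0, 20))
    s <- denDistributionSummary(gc, "up")          # k = 3
    expect_equal(s$top_share, 1)
    # uniform counts: share = floor(0.15 N) / N
    gcu <- makeGeneCounts(sprintf("g%02d", 1:20), up = rep(4, 20),
                          down = rep(0, 20))
    expect_equal(denDistributionSummary(gcu, "up")$top_share, 3 / 20)
    # all zero: flagged, share defined as 0
    gz <- makeGeneCounts(sprintf("g%02d", 1:20), up = rep(0, 20),
                         down = rep(0, 20))
    sz <- denDistributionSummary(gz, "up")
    expect_true(sz$all_zero)
    expect_equal(sz$top_share, 0)
})
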