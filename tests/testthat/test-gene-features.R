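test_that("pair distances use midpoints and stay within chromosomes", {
    loci <- makeLoci(c("A", "B", "C"), c("chr1", "chr1", "chr2"),
                     start = c(50, 450, 10), end = c(150, 550, 20))
    d <- chromPairDistances(loci)
    expect_equal(as.numeric(d), 400)   # midpoints 100 and 500
    dAC <- suppressMessages(chromPairDistances(loci, c("A", "C")))
    expect_length(dAC, 0L)
    expect_identical(attr(dAC, "flag"), "no_pairs")
})

test_that("all-pairs distances match the brute-force oracle", {
    set.seed(11)
    st <- sort(sample(1e6, 5))
    loci <- makeLoci(paste0("G", 1:5), "chr3", st, st + 1000)
    d <- sort(chromPairDistances(loci))
    mids <- (st + st + 1000) / 2
    oracle <- c()
    for (i in 1:4) for (j in (i + 1):5)
        oracle <- c(oracle, abs(mids[i] - mids[j]))
    expect_equal(d, sort(oracle))
    expect_length(d, choose(5, 2))
})

test_that("distance counts sum choose(n_c, 2) over chromosomes and subsample deterministically", {
    set.seed(21)
    n <- 40
    chrom <- sample(paste0("chr", 1:4), n, replace = TRUE)
    st <- sample(1e7, n)
    loci <- makeLoci(sprintf("g%02d", 1:n), chrom, st, st + 500)
    d <- chromPairDistances(loci)
    expect_length(d, sum(choose(table(chrom), 2)))
    sub1 <- chromPairDistances(loci, maxPairs = 25, seed = 99)
    sub2 <- chromPairDistances(loci, maxPairs = 25, seed = 99)
    expect_identical(sub1, sub2)
    expect_length(sub1, 25L)
    expect_true(all(sub1 %in% d))
})

test_that("matched pairing is gene-disjoint and seed-stable", {
    set.seed(3)
    n <- 30
    chrom <- rep(c("chr1", "chr2"), each = 15)
    st <- sample(1e7, n)
    loci <- makeLoci(sprintf("g%02d", 1:n), chrom, st, st + 100)
    d1 <- matchedPairDistances(loci, seed = 5)
    d2 <- matchedPairDistances(loci, seed = 5)
    expect_identical(d1, d2)
    expect_length(d1, 7L + 7L)   # floor(15/2) per chromosome
})

test_that("per-chromosome DEN tables keep gene pairing and conservation", {
    gc <- makeGeneCounts(c("A", "B", "C", "D"), up = c(5, 4, 6, 2),
                         down = c(1, 0, 2, 9))
    loci <- makeLoci(c("A", "B", "C"), "chrY", c(1, 100, 200),
                     c(50, 150, 250))
    tab <- suppressMessages(chromosomeDenTable(gc, loci))
    expect_identical(nrow(tab), 3L)
    expect_identical(attr(tab, "n_excluded"), 1L)
    expect_setequal(tab$up_count, c(5, 4, 6))
    expect_equal(sum(tab$up_count) + 2, sum(regCounts(gc)$up_count))
})

test_that("TES closed forms hold, including the 79-tissue uniform profile", {
    m <- rbind(g1 = c(10, 10, 10, 10), g2 = c(5, 0, 0, 0))
    tes <- tissueSpecificity(m)
    expect_equal(unname(tes["g1"]), 0.25)
    expect_equal(unname(tes["g2"]), 1.0)
    u79 <- tissueSpecificity(matrix(rep(3.7, 79), nrow = 1))
    expect_equal(unname(u79), 1 / 79)
    expect_equal(unname(u79), 0.012658, tolerance = 1e-4)
    expect_true(is.na(tissueSpecificity(rbind(z = rep(0, 5)))["z"]))
    expect_error(tissueSpecificity(matrix(1, 1, 1)), "two tissues")
    expect_error(tissueSpecificity(rbind(c(-1, 2))), ">= 0")
})

test_that("TES hits its bounds exactly when and only when profiles degenerate", {
    set.seed(8)
    for (i in 1:20) {
        Tt <- sample(3:10, 1)
        x <- runif(Tt, 0.1, 5)
        tes <- unname(tissueSpecificity(matrix(x, nrow = 1)))
        expect_gt(tes, 1 / Tt - 1e-12)
        expect_lt(tes, 1 + 1e-12)
        expect_identical(tes == 1, sum(x > 0) == 1L)
        expect_identical(abs(tes - 1 / Tt) < 1e-12,
                         isTRUE(all.equal(max(x), min(x))))
    }
})

test_that("stage labels map to the fixed developmental order", {
    s <- earliestStage(c(a = "fetus", b = "adult", c = "Embryoid_body"))
    expect_identical(unname(s), c(3L, 7L, 1L))
    expect_warning(s2 <- earliestStage(c(a = "fetus", b = "larva")),
                   "larva")
    expect_identical(names(s2), "a")
    expect_identical(devStages()[2], "blastocyst")
})

test_that("variant summaries count half-open span membership", {
    # BED-style span [100, 200) of length 100 -> internal 101..200
    loci <- makeLoci("G", "chr1", 101, 200)
    v <- makeVariants("chr1", c(101, 150, 200, 201, 100))
    vs <- variantSummary(loci, v, dsnpFilter = function(x) rep(FALSE,
                                                               length(x)))
    expect_identical(vs$snp_count, 3L)   # 201 and 100 fall outside
    expect_identical(vs$gene_length, 100L)
    expect_equal(vs$snp_density, 0.03)
    # 5 SNPs in a 1000 bp span -> density 0.005
    loci2 <- makeLoci("H", "chr2", 1, 1000)
    v2 <- makeVariants("chr2", c(10, 20, 30, 40, 50))
    expect_equal(variantSummary(loci2, v2)$snp_density, 0.005)
})

test_that("variant counts match brute-force interval membership", {
    set.seed(17)
    st <- sample(1e5, 10)
    loci <- makeLoci(sprintf("g%02d", 1:10),
                     sample(c("chr1", "chr2"), 10, replace = TRUE),
                     st, st + sample(500:5000, 10))
    pos <- sample(1.1e5, 200, replace = TRUE)
    vchr <- sample(c("chr1", "chr2"), 200, replace = TRUE)
    v <- makeVariants(vchr, pos)
    vs <- variantSummary(loci, v)
    for (i in 1:10) {
        want <- sum(vchr == as.character(GenomicRanges::seqnames(loci))[i] &
                        pos >= GenomicRanges::start(loci)[i] &
                        pos <= GenomicRanges::end(loci)[i])
        expect_identical(vs$snp_count[i], want)
    }
    # one added variant strictly inside bumps count and density exactly
    v3 <- c(v, makeVariants(as.character(
        GenomicRanges::seqnames(loci))[1],
        GenomicRanges::start(loci)[1] + 5L))
    vs3 <- variantSummary(loci, v3)
    expect_identical(vs3$snp_count[1], vs$snp_count[1] + 1L)
    expect_equal(vs3$snp_density[1] - vs$snp_density[1],
                 1 / vs$gene_length[1])
})

test_that("disease-SNP status follows the id and exclusion-label rules", {
    v <- makeVariants("chr1", 1:6,
                      rs = c("rs1", "rs2", NA, "rs4", "rs5", "rs6"),
                      labels = list("pathogenic",
                                    "likely_benign",
                                    "pathogenic",
                                    character(),
                                    c("pathogenic", "benign"),
                                    c("pathogenic", "risk_factor")))
    expect_identical(isDiseaseSnp(v),
                     c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))
})

test_that("degrees follow the filtered simple graph", {
    tri <- data.frame(gene_a = c("A", "B", "A"), gene_b = c("B", "C", "C"),
                      system_class = "physical",
                      modification = NA_character_)
    d <- ppiDegrees(tri)
    expect_identical(d$degree, c(2L, 2L, 2L))
    # genetic + physical duplicate: one simple edge survives
    dup <- data.frame(gene_a = c("A", "A"), gene_b = c("B", "B"),
                      system_class = c("genetic", "physical"),
                      modification = NA_character_)
    expect_identical(ppiDegrees(dup)$degree, c(1L, 1L))
    # ubiquitination edges are dropped; isolated genes keep degree 0
    ub <- data.frame(gene_a = "A", gene_b = "B",
                     system_class = "physical",
                     modification = "Ubiquitination")
    expect_identical(ppiDegrees(ub)$degree, c(0L, 0L))
})

test_that("degrees equal brute-force adjacency sets on random edge lists", {
    set.seed(29)
    genes <- sprintf("n%02d", 1:20)
    e <- data.frame(gene_a = sample(genes, 100, replace = TRUE),
                    gene_b = sample(genes, 100, replace = TRUE),
                    system_class = sample(c("physical", "genetic"), 100,
                                          replace = TRUE,
                                          prob = c(0.8, 0.2)),
                    modification = NA_character_)
    d <- ppiDegrees(e)
    adj <- new.env()
    for (i in seq_len(nrow(e))) {
        if (e$system_class[i] == "genetic") next
        a <- e$gene_a[i]; b <- e$gene_b[i]
        if (a == b) next
        assign(a, union(get0(a, adj, ifnotfound = character()), b), adj)
        assign(b, union(get0(b, adj, ifnotfound = character()), a), adj)
    }
    for (i in seq_len(nrow(d))) {
        want <- length(get0(d$gene_id[i], adj, ifnotfound = character()))
        expect_identical(d$degree[i], want)
    }
    nEdges <- sum(vapply(ls(adj), function(g) length(get(g, adj)), 0L)) / 2
    expect_equal(sum(d$degree), 2 * nEdges)
})

test_that("subcellular classes map the four GO terms and honour NOT", {
    gaf <- data.frame(gene_id = c("A", "B", "B", "C", "D"),
                      qualifier = c("", "", "", "NOT", ""),
                      go_id = c("GO:0005634", "GO:0005634", "GO:0005737",
                                "GO:0005634", "GO:0099999"),
                      aspect = "C")
    cl <- subcellularClasses(gaf)
    expect_identical(cl$class[cl$gene_id == "A"], "nucleus")
    expect_setequal(cl$class[cl$gene_id == "B"], c("cytoplasm", "nucleus"))
    expect_false("C" %in% cl$gene_id)   # NOT-qualified only
    expect_false("D" %in% cl$gene_id)   # unrelated term
})
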