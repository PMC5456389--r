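test_that("generation is fully seeded: same seed, identical outputs", {
    cfg <- fixtureConfig("tiny", seed = 5)
    d1 <- generateDataset(cfg)
    d2 <- generateDataset(cfg)
    expect_identical(lnFC(d1$matrix), lnFC(d2$matrix))
    expect_identical(d1$truth, d2$truth)
    expect_identical(d1$edges, d2$edges)
    expect_identical(d1$annotations, d2$annotations)
    expect_identical(GenomicRanges::start(d1$loci),
                     GenomicRanges::start(d2$loci))
    d3 <- generateDataset(fixtureConfig("tiny", seed = 6))
    expect_false(identical(lnFC(d1$matrix), lnFC(d3$matrix)))
})

test_that("config validation rejects unknown effects and missing seed", {
    expect_error(syntheticConfig(nGenes = 100, seed = 1,
                                 effectSizes = c(bogus = 1)), "bogus")
    expect_error(syntheticConfig(nGenes = 100), "seed")
})

test_that("realized DEN tracks the planted propensities", {
    ds <- generateDataset(syntheticConfig(nGenes = 800, nSamples = 100,
                                          seed = 31))
    gcts <- suppressMessages(aggregateToGenes(countRegulation(ds$matrix),
                                              ds$map))
    k <- regCounts(gcts)
    tr <- ds$truth[match(k$unit_id, ds$truth$gene_id), ]
    m <- nSamples(gcts)
    # total realized DEN within 3 SE of its Poisson-binomial expectation
    for (cnt in list(cbind(k$up_count, tr$p_up),
                     cbind(k$down_count, tr$p_down))) {
        expected <- m * sum(cnt[, 2])
        se <- sqrt(m * sum(cnt[, 2] * (1 - cnt[, 2])))
        expect_lt(abs(sum(cnt[, 1]) - expected), 3 * se)
    }
})

test_that("a pareto(1.5) law concentrates DEN in the top 15% of genes", {
    for (seed in c(2, 12)) {
        ds <- generateDataset(syntheticConfig(nGenes = 1000,
                                              nSamples = 100, seed = seed))
        gcts <- suppressMessages(
            aggregateToGenes(countRegulation(ds$matrix), ds$map))
        for (dirn in c("up", "down")) {
            s <- denDistributionSummary(gcts, dirn)
            expect_gte(s$top_share, 0.5)
            expect_gt(s$skewness, 1)    # strongly right-skewed
            # share agrees with a direct recomputation from the counts
            cnt <- sort(if (dirn == "up") upCounts(gcts)
                        else downCounts(gcts), decreasing = TRUE)
            expect_equal(s$top_share, sum(cnt[1:150]) / sum(cnt))
        }
    }
})

test_that("null data shows no propensity-feature correlation", {
    ds <- generateDataset(syntheticConfig(nGenes = 1000, nSamples = 100,
                                          seed = 71))
    gcts <- suppressMessages(aggregateToGenes(countRegulation(ds$matrix),
                                              ds$map))
    up <- upCounts(gcts)
    feats <- featuresFromDataset(ds)
    bound <- 3 / sqrt(1000)
    for (f in list(feats$tes, feats$homolog, feats$degree)) {
        common <- intersect(names(up), names(f))
        common <- common[!is.na(f[common])]
        expect_lt(abs(cor(up[common], f[common], method = "spearman")),
                  bound)
    }
})

test_that("planted TES effects surface as DEN-TES correlation", {
    hits <- 0L
    for (seed in 101:110) {
        ds <- generateDataset(syntheticConfig(
            nGenes = 2000, nSamples = 100,
            effectSizes = c(tes_up = 1), seed = seed))
        gcts <- suppressMessages(
            aggregateToGenes(countRegulation(ds$matrix), ds$map))
        up <- upCounts(gcts)
        tes <- tissueSpecificity(ds$tissue)
        hits <- hits + (cor(up, tes[names(up)],
                            method = "spearman") > 0)
    }
    expect_gte(hits, 9L)
})

test_that("planted EES shifts move high-DEN genes to later stages", {
    ds <- generateDataset(syntheticConfig(
        nGenes = 2000, nSamples = 100,
        effectSizes = c(ees_up = 1, ees_down = -1), seed = 301))
    gcts <- suppressMessages(aggregateToGenes(countRegulation(ds$matrix),
                                              ds$map))
    res <- runFullAnalysis(gcts, featuresFromDataset(ds), seed = 302,
                           enabled = "ees")
    up <- res[res$feature == "ees" & res$den_direction == "up", ]
    dn <- res[res$feature == "ees" & res$den_direction == "down", ]
    expect_lt(up$p_value, 0.05)
    expect_identical(up$direction, "high_greater")    # later stages
    expect_lt(dn$p_value, 0.05)
    expect_identical(dn$direction, "low_greater")     # earlier stages
})

test_that("fixture files re-read cleanly and match the in-memory dataset", {
    dir <- file.path(tempdir(), "tinyfix")
    fx <- makeFixture("tiny", dir, seed = 9)
    ds <- fx$dataset
    expect_no_warning({
        m <- readFoldChangeMatrix(fx$paths[["matrix"]])
        map <- readProbeGeneMap(fx$paths[["map"]])
        loci <- readGeneLoci(fx$paths[["loci"]], "bed")
        tis <- readTissueMatrix(fx$paths[["tissue"]])
        v <- readVariants(fx$paths[["variants"]], "vcf")
        e <- readInteractions(fx$paths[["interactions"]])
        ann <- readAnnotationTable(fx$paths[["annotations"]])
        gaf <- readGaf(fx$paths[["gaf"]])
    })
    expect_identical(lnFC(m), lnFC(ds$matrix))
    expect_identical(map, ds$map)
    expect_identical(GenomicRanges::start(loci[names(ds$loci)]),
                     GenomicRanges::start(ds$loci))
    expect_identical(GenomicRanges::width(loci[names(ds$loci)]),
                     GenomicRanges::width(ds$loci))
    expect_equal(unname(tis[rownames(ds$tissue), ]),
                 unname(ds$tissue), tolerance = 1e-9)
    expect_identical(length(v), length(ds$variants))
    expect_identical(isDiseaseSnp(v), isDiseaseSnp(ds$variants))
    expect_identical(nrow(e), nrow(ds$edges))
    expect_identical(ann$gene_id, ds$annotations$gene_id)
    cl <- subcellularClasses(gaf)
    expect_identical(cl[order(cl$gene_id), "class"],
                     ds$classes[order(ds$classes$gene_id), "class"])
})

test_that("null fixtures rarely show any BH-significant comparison", {
    clean <- 0L
    for (seed in 501:510) {
        ds <- generateDataset(fixtureConfig("null", seed = seed))
        gcts <- suppressMessages(
            aggregateToGenes(countRegulation(ds$matrix), ds$map))
        res <- runFullAnalysis(gcts, featuresFromDataset(ds),
                               nTopLast = 250, seed = seed + 1)
        clean <- clean + all(res$p_bh >= 0.05)
    }
    expect_gte(clean, 9L)
})
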