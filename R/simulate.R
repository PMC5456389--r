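#' Configuration for the synthetic dataset generator
#'
#' The generator emulates the structure of a drug-perturbation compendium at
#' desk scale: heavy-tailed per-gene regulation propensities (producing a
#' power-law-like DEN distribution), and per-gene features linked to the
#' standardized propensity `z` through configurable planted effects. An
#' effect size of 0 removes the link entirely (the null); size 1 shifts the
#' feature's link function by one unit per standard deviation of propensity.
#'
#' Effect keys: `tes_up`, `tes_down` (logit shift of the dominant-tissue
#' share), `cluster_high` (contraction of the positional spread of
#' high-propensity genes around a per-chromosome center), `snp_density_high`
#' (log-linear SNP rate), `dsnp_frac_high` (logit-linear per-SNP disease
#' probability), `degree_up`, `degree_down` (log-linear expected degree),
#' `homolog_high` (log-linear negative-binomial mean), `ees_up`, `ees_down`
#' (proportional-odds shift toward later stages).
#'
#' @param nGenes number of genes.
#' @param probesPerGene probes per gene (all probes of a gene share its
#'   regulation events; magnitudes differ).
#' @param nSamples number of treated samples.
#' @param propensityLaw list: `family` `"pareto"` (with `alpha`, `xmin`) or
#'   `"lognormal"` (with `mu`, `sigma`). Default pareto(1.5, 1), a
#'   heavy-tailed law whose top 15% of genes carry most of the total DEN.
#' @param effectSizes named numeric vector; missing keys default to 0.
#' @param nTissues number of tissues in the expression matrix (default 79).
#' @param nChromosomes number of chromosomes (default 20).
#' @param missingRate fraction of matrix cells set to missing.
#' @param snpRate baseline SNP rate per bp (default 5e-3, about 100 SNPs
#'   for a typical 20 kb gene span -- conservative relative to dbSNP, and
#'   large enough that per-chromosome contingency cells stay in the regime
#'   where the chi-squared approximation is trustworthy, as they are for
#'   genome-scale data).
#' @param seed integer seed (mandatory).
#' @return validated list of class `syntheticConfig`.
#' @export
syntheticConfig <- function(nGenes, probesPerGene = 1L, nSamples = 100L,
                            propensityLaw = list(family = "pareto",
                                                 alpha = 1.5, xmin = 1),
                            effectSizes = numeric(), nTissues = 79L,
                            nChromosomes = 20L, missingRate = 0,
                            snpRate = 5e-3, seed) {
    if (missing(seed)) stop("seed is mandatory")
    stopifnot(nGenes >= 10L, probesPerGene >= 1L, nSamples >= 1L,
              nTissues >= 2L, nChromosomes >= 1L,
              missingRate >= 0, missingRate < 1)
    keys <- c("tes_up", "tes_down", "cluster_high", "snp_density_high",
              "dsnp_frac_high", "degree_up", "degree_down", "homolog_high",
              "ees_up", "ees_down")
    eff <- setNames(numeric(length(keys)), keys)
    if (length(effectSizes)) {
        unknown <- setdiff(names(effectSizes), keys)
        if (length(unknown))
            stop("unknown effect key(s): ", paste(unknown, collapse = ", "))
        eff[names(effectSizes)] <- effectSizes
    }
    if (!propensityLaw$family %in% c("pareto", "lognormal"))
        stop("propensityLaw$family must be 'pareto' or 'lognormal'")
    structure(list(nGenes = as.integer(nGenes),
                   probesPerGene = as.integer(probesPerGene),
                   nSamples = as.integer(nSamples),
                   propensityLaw = propensityLaw, effectSizes = eff,
                   nTissues = as.integer(nTissues),
                   nChromosomes = as.integer(nChromosomes),
                   missingRate = missingRate, snpRate = snpRate,
                   seed = as.integer(seed)),
              class = "syntheticConfig")
}

PHYLETIC_LEVELS <- c("early_eukaryote", "metazoa", "vertebrata",
                     "mammalia", "primates")

# Normalized propensity: van der Waerden normal scores of the propensity
# ranks. Monotone in the propensity but bounded (about +/-3.5 at n = 2000),
# so the log- and logit-linear planted links stay well behaved under
# heavy-tailed laws.
.normalScores <- function(x) {
    n <- length(x)
    stats::qnorm((rank(x, ties.method = "average") - 0.5) / n)
}

.drawPropensity <- function(law, n) {
    raw <- switch(law$family,
        pareto = law$xmin / runif(n)^(1 / law$alpha),
        lognormal = rlnorm(n, law$mu, law$sigma))
    # deterministic rescale into (0, 0.5): linear in the law's body, with
    # the extreme tail (top 0.1%) saturating at the maximal rate. A fixed
    # scale (the law's theoretical 99.9th percentile) keeps genes
    # independent -- dividing by a sample statistic such as max(raw) would
    # couple every gene in a replicate through one draw -- and preserves
    # enough of the tail that the top 15% of genes carry most of the total
    # DEN under pareto(1.5).
    qs <- switch(law$family,
        pareto = law$xmin * (1 / 0.001)^(1 / law$alpha),
        lognormal = stats::qlnorm(0.999, law$mu, law$sigma))
    pmin(0.5 * raw / qs, 0.5 * (1 - 1e-9))
}

#' Generate a complete synthetic dataset
#'
#' Produces every input of the pipeline -- lnFC matrix, probe map, gene
#' loci, tissue expression matrix, variants, interaction edges, annotation
#' table, subcellular classes -- plus the generating truth (per-gene
#' propensities and standardized scores) for parameter-recovery tests.
#' Regulation events are drawn at the gene-by-sample level with probability
#' `p_up`/`p_down` per cell, so the expected gene-level DEN (under the `max`
#' aggregation policy) is `nSamples * propensity`; all probes of a gene
#' share its events. Background cells are drawn strictly inside the open
#' threshold interval so thresholding is unambiguous.
#'
#' @param config a [syntheticConfig()].
#' @return list with elements `matrix` ([FoldChangeMatrix-class]), `map`,
#'   `loci`, `tissue`, `variants`, `edges`, `annotations`, `classes`,
#'   `truth`, `config`.
#' @export
generateDataset <- function(config) {
    stopifnot(inherits(config, "syntheticConfig"))
    set.seed(config$seed)
    n <- config$nGenes
    m <- config$nSamples
    eff <- config$effectSizes
    th <- denThresholds()
    genes <- sprintf("g%05d", seq_len(n))

    pUp <- .drawPropensity(config$propensityLaw, n)
    pDn <- .drawPropensity(config$propensityLaw, n)
    zUp <- .normalScores(pUp)
    zDn <- .normalScores(pDn)
    zHi <- .normalScores(pUp + pDn)

    ## lnFC matrix: one uniform per gene x sample decides the event state
    u <- matrix(runif(n * m), nrow = n)
    evUp <- u < pUp
    evDn <- !evUp & (u < pUp + pDn)
    geneVal <- function() {
        v <- matrix(runif(n * m, th$downCut, th$upCut), nrow = n)
        v[evUp] <- th$upCut + runif(sum(evUp)) * 1.5
        v[evDn] <- th$downCut - runif(sum(evDn)) * 1.5
        v
    }
    k <- config$probesPerGene
    vals <- do.call(rbind, lapply(seq_len(k), function(j) geneVal()))
    probeOfGene <- rep(seq_len(k), each = n)
    probes <- sprintf("p%05d_%d", rep(seq_len(n), k), probeOfGene)
    rownames(vals) <- probes
    colnames(vals) <- sprintf("s%04d", seq_len(m))
    if (config$missingRate > 0) {
        nm <- length(vals)
        vals[sample(nm, round(config$missingRate * nm))] <- NA_real_
    }
    fcm <- FoldChangeMatrix(vals)
    map <- data.frame(probe_id = probes,
                      gene_id = rep(genes, k), stringsAsFactors = FALSE)

    ## loci: per-chromosome center, spread contracted for high-z genes
    chromLen <- 1e8
    chrom <- paste0("chr", sample.int(config$nChromosomes, n, replace = TRUE))
    centers <- setNames(runif(config$nChromosomes, 0.25, 0.75) * chromLen,
                        paste0("chr", seq_len(config$nChromosomes)))
    spread <- 0.3 * chromLen * exp(-eff["cluster_high"] * pmax(zHi, 0))
    mid <- centers[chrom] + spread * rnorm(n)
    lo <- 1e6; hiB <- chromLen - 1e6
    mid <- ifelse(mid < lo, 2 * lo - mid, mid)
    mid <- ifelse(mid > hiB, 2 * hiB - mid, mid)
    mid <- pmin(pmax(mid, lo), hiB)
    glen <- pmin(pmax(round(rlnorm(n, log(2e4), 0.6)), 1000), 2e5)
    startBed <- pmax(round(mid - glen / 2), 0)
    loci <- GRanges(chrom, IRanges(startBed + 1, startBed + glen),
                    strand = sample(c("+", "-"), n, replace = TRUE),
                    gene_id = genes)
    names(loci) <- genes

    ## tissue expression with planted TES link
    Tn <- config$nTissues
    s <- 1 / Tn + (1 - 1 / Tn) *
        stats::plogis(stats::qlogis(0.2) + eff["tes_up"] * zUp +
                          eff["tes_down"] * zDn + rnorm(n))
    domIdx <- sample.int(Tn, n, replace = TRUE)
    g <- matrix(rgamma(n * (Tn - 1), shape = 5), nrow = n)
    g <- g / rowSums(g) * (1 - s)
    tissue <- matrix(0, nrow = n, ncol = Tn,
                     dimnames = list(genes, sprintf("tissue%02d",
                                                    seq_len(Tn))))
    for (i in seq_len(n)) {
        tissue[i, -domIdx[i]] <- g[i, ]
        tissue[i, domIdx[i]] <- s[i]
    }
    tissue <- tissue * rlnorm(n, log(100), 0.5)

    ## variants: Poisson counts (log-linear rate), logit-linear dSNP labels
    lam <- glen * config$snpRate * exp(eff["snp_density_high"] * zHi)
    snpN <- rpois(n, lam)
    owner <- rep.int(seq_len(n), snpN)
    total <- length(owner)
    pos <- startBed[owner] + 1 + floor(runif(total) * glen[owner])
    pd <- stats::plogis(stats::qlogis(0.05) + eff["dsnp_frac_high"] * zHi)
    isD <- runif(total) < pd[owner]
    rs <- sprintf("rs%07d", seq_len(total))
    rs[!isD & runif(total) < 0.05] <- NA_character_   # some IDless SNPs
    benignPool <- c("benign", "likely_benign", "uncertain_significance",
                    "not_provided")
    labs <- character(total)
    labs[isD] <- "pathogenic"
    labs[!isD] <- sample(benignPool, sum(!isD), replace = TRUE)
    noLab <- !isD & runif(total) < 0.10
    labs[noLab] <- ""
    variants <- GRanges(chrom[owner], IRanges(pos, pos))
    labList <- strsplit(labs, ";", fixed = TRUE)   # "" -> character(0)
    mcols(variants)$rs_id <- rs
    mcols(variants)$clin_sig <- CharacterList(labList)

    ## interaction edges: fixed-size fitness random graph + decoy edges
    fit <- exp(log(6) + eff["degree_up"] * zUp + eff["degree_down"] * zDn)
    fit <- pmin(fit, n / 4)
    nEdges <- min(round(sum(fit) / 2), floor(0.3 * choose(n, 2)))
    gph <- igraph::sample_fitness(nEdges, fitness.out = fit,
                                  loops = FALSE, multiple = FALSE)
    el <- igraph::as_edgelist(gph, names = FALSE)
    edges <- data.frame(gene_a = genes[el[, 1L]], gene_b = genes[el[, 2L]],
                        system_class = "physical",
                        modification = NA_character_,
                        stringsAsFactors = FALSE)
    nDecoy <- max(1L, round(0.05 * nrow(edges)))
    decoy <- function(sys, mod) data.frame(
        gene_a = genes[sample.int(n, nDecoy, replace = TRUE)],
        gene_b = genes[sample.int(n, nDecoy, replace = TRUE)],
        system_class = sys, modification = mod, stringsAsFactors = FALSE)
    edges <- rbind(edges, decoy("genetic", NA_character_),
                   decoy("physical", "Ubiquitination"))
    swap <- edges$gene_a > edges$gene_b
    tmp <- edges$gene_a[swap]
    edges$gene_a[swap] <- edges$gene_b[swap]
    edges$gene_b[swap] <- tmp
    edges <- edges[!duplicated(edges), , drop = FALSE]
    rownames(edges) <- NULL

    ## annotations: homolog counts, phyletic age, earliest expression stage
    homolog <- rnbinom(n, size = 2,
                       mu = exp(log(8) + eff["homolog_high"] * zHi))
    phyletic <- sample(PHYLETIC_LEVELS, n, replace = TRUE,
                       prob = c(0.30, 0.25, 0.20, 0.15, 0.10))
    eesBase <- c(0.08, 0.08, 0.20, 0.14, 0.12, 0.13, 0.25)
    cuts <- stats::qlogis(cumsum(eesBase)[1:6])
    latent <- rlogis(n, location = eff["ees_up"] * zUp +
                         eff["ees_down"] * zDn)
    eesOrd <- 1L + findInterval(latent, cuts)
    annotations <- data.frame(gene_id = genes, homolog_count = homolog,
                              phyletic_age = phyletic,
                              ees_stage = DEV_STAGES[eesOrd],
                              stringsAsFactors = FALSE)

    ## one subcellular class per gene (no planted link)
    classes <- data.frame(
        gene_id = genes,
        class = sample(unname(SUBCELL_GO_TERMS), n, replace = TRUE,
                       prob = c(0.15, 0.30, 0.30, 0.25)),
        stringsAsFactors = FALSE)

    truth <- data.frame(gene_id = genes, p_up = pUp, p_down = pDn,
                        z_up = zUp, z_down = zDn, z_high = zHi,
                        stringsAsFactors = FALSE)

    list(matrix = fcm, map = map, loci = loci, tissue = tissue,
         variants = variants, edges = edges, annotations = annotations,
         classes = classes, truth = truth, config = config)
}

#' Feature bundle from an in-memory synthetic dataset
#'
#' Convenience wrapper running the feature operations
#' ([tissueSpecificity()], [earliestStage()], [variantSummary()],
#' [ppiDegrees()]) over a [generateDataset()] result and assembling a
#' [denFeatures()] bundle, exactly as the file-based pipeline would after
#' re-reading the fixture from disk.
#'
#' @param ds a [generateDataset()] result.
#' @return a [denFeatures()] bundle.
#' @export
featuresFromDataset <- function(ds) {
    ann <- ds$annotations
    deg <- ppiDegrees(ds$edges)
    denFeatures(
        loci = ds$loci,
        tes = tissueSpecificity(ds$tissue),
        ees = earliestStage(setNames(ann$ees_stage, ann$gene_id)),
        homolog = setNames(as.numeric(ann$homolog_count), ann$gene_id),
        phyletic = setNames(ann$phyletic_age, ann$gene_id),
        phyleticLevels = PHYLETIC_LEVELS,
        variants = variantSummary(ds$loci, ds$variants),
        degree = setNames(deg$degree, deg$gene_id),
        classes = ds$classes)
}

#' Named fixture configurations
#'
#' `tiny`: 50 genes x 20 samples, 2 probes per gene, 2% missing cells, no
#' planted effects -- for unit and smoke tests. `null`: 1000 genes x 100
#' samples, every effect 0 -- for calibration studies. `planted`:
#' 2000 genes x 100 samples with unit-size effects whose signs mirror the
#' reported associations (TES up +, down -; degree up -, down +; positional
#' clustering +; SNP density +; dSNP fraction +; homolog count -; EES up
#' later, down earlier).
#'
#' @param name fixture name.
#' @param seed integer seed.
#' @return a [syntheticConfig()].
#' @export
fixtureConfig <- function(name = c("tiny", "null", "planted"),
                          seed = 1L) {
    name <- match.arg(name)
    switch(name,
        tiny = syntheticConfig(nGenes = 50, probesPerGene = 2,
                               nSamples = 20, nTissues = 12,
                               nChromosomes = 5, missingRate = 0.02,
                               seed = seed),
        null = syntheticConfig(nGenes = 1000, nSamples = 100, seed = seed),
        planted = syntheticConfig(
            nGenes = 2000, nSamples = 100,
            effectSizes = c(tes_up = 1, tes_down = -1, cluster_high = 1,
                            snp_density_high = 1, dsnp_frac_high = 1,
                            degree_up = -1, degree_down = 1,
                            homolog_high = -1, ees_up = 1, ees_down = -1),
            seed = seed))
}

#' Write a named fixture dataset to disk
#'
#' Generates the fixture with [generateDataset()] and writes every file in
#' the dialects the readers consume: `matrix.tsv`, `probe_map.tsv`,
#' `loci.bed`, `tissue.tsv`, `variants.vcf`, `interactions.tsv`,
#' `annotations.tsv`, `go.gaf`, `truth.tsv`.
#'
#' @inheritParams fixtureConfig
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the in-memory `dataset` and the named
#'   file `paths`.
#' @export
makeFixture <- function(name = c("tiny", "null", "planted"),
                        dir, seed = 1L) {
    name <- match.arg(name)
    ds <- generateDataset(fixtureConfig(name, seed))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(matrix = file.path(dir, "matrix.tsv"),
               map = file.path(dir, "probe_map.tsv"),
               loci = file.path(dir, "loci.bed"),
               tissue = file.path(dir, "tissue.tsv"),
               variants = file.path(dir, "variants.vcf"),
               interactions = file.path(dir, "interactions.tsv"),
               annotations = file.path(dir, "annotations.tsv"),
               gaf = file.path(dir, "go.gaf"),
               truth = file.path(dir, "truth.tsv"))
    writeFoldChangeMatrix(ds$matrix, paths["matrix"])
    .writeTsv(ds$map, paths["map"])
    gr <- ds$loci
    bed <- data.frame(chrom = as.character(seqnames(gr)),
                      start = start(gr) - 1L, end = end(gr),
                      name = names(gr), score = 0L,
                      strand = as.character(strand(gr)))
    write.table(bed, paths["loci"], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    .writeTsv(data.frame(gene_id = rownames(ds$tissue),
                         as.data.frame(ds$tissue), check.names = FALSE),
              paths["tissue"])
    .writeVcf(ds$variants, paths["variants"])
    .writeTsv(ds$edges, paths["interactions"])
    .writeTsv(ds$annotations, paths["annotations"])
    .writeGaf(ds$classes, paths["gaf"])
    .writeTsv(ds$truth, paths["truth"], digits = 17L)
    invisible(list(dataset = ds, paths = paths))
}

.writeVcf <- function(variants, path) {
    id <- mcols(variants)$rs_id
    id[is.na(id)] <- "."
    cln <- vapply(as.list(mcols(variants)$clin_sig), paste, "",
                  collapse = ",")
    info <- ifelse(nzchar(cln), paste0("CLNSIG=", cln), ".")
    hdr <- c("##fileformat=VCFv4.2",
             paste0("##INFO=<ID=CLNSIG,Number=.,Type=String,",
                    "Description=\"Clinical significance\">"),
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", sep = "\t"))
    body <- paste(as.character(seqnames(variants)), start(variants), id,
                  "A", "G", ".", ".", info, sep = "\t")
    writeLines(c(hdr, body), path)
    invisible(path)
}

.writeGaf <- function(classes, path) {
    term <- names(SUBCELL_GO_TERMS)[match(classes$class, SUBCELL_GO_TERMS)]
    rows <- paste("SYNT", classes$gene_id, classes$gene_id, "", term,
                  "SYNT:0000001", "IDA", "", "C", "", "", "protein",
                  "taxon:9606", "20170602", "SYNT", "", "", sep = "\t")
    writeLines(c("!gaf-version: 2.1", rows), path)
    invisible(path)
}
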