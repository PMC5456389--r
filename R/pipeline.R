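#' Run configuration for the end-to-end pipeline
#'
#' Collects input paths, thresholds and tuning parameters. Unknown keys are
#' hard errors, so a typo in a YAML config cannot silently fall back to a
#' default. `matrix` and `map` are mandatory; every other input is optional
#' and simply disables the comparisons that need it.
#'
#' @param matrix path to the lnFC matrix (TSV).
#' @param map path to the probe-to-gene map (TSV).
#' @param loci,lociFormat gene loci path and format (`"bed"`/`"gff3"`).
#' @param tissue path to the gene-by-tissue expression matrix.
#' @param variants,variantsFormat variant file path and format
#'   (`"vcf"`/`"tsv"`).
#' @param interactions path to the PPI edge list.
#' @param annotations path to the per-gene annotation table (columns
#'   `homolog_count`, `phyletic_age`, `ees_stage` are used when present).
#' @param gaf path to GO annotations (GAF 2.x).
#' @param upCut,downCut lnFC thresholds (see [denThresholds()]).
#' @param aggregation probe-to-gene policy (see [aggregateToGenes()]).
#' @param fraction high-set fraction.
#' @param nTopLast top/last set size for the subcellular comparison.
#' @param distancePairing,maxPairs distance sampling (see
#'   [runFullAnalysis()]).
#' @param phyleticLevels optional ordered phyletic-age categories.
#' @param enabled comparisons to run.
#' @param seed integer master seed.
#' @param outDir output directory.
#' @return validated list of class `denRunConfig`.
#' @export
denRunConfig <- function(matrix, map, loci = NULL, lociFormat = "bed",
                         tissue = NULL, variants = NULL,
                         variantsFormat = "vcf", interactions = NULL,
                         annotations = NULL, gaf = NULL,
                         upCut = 0.69, downCut = -0.69,
                         aggregation = "max", fraction = 0.15,
                         nTopLast = 1000L,
                         distancePairing = "matched", maxPairs = 2e6,
                         phyleticLevels = NULL,
                         enabled = ALL_COMPARISONS,
                         seed = 1L, outDir = "den_out") {
    cfg <- list(matrix = matrix, map = map, loci = loci,
                lociFormat = lociFormat, tissue = tissue,
                variants = variants, variantsFormat = variantsFormat,
                interactions = interactions, annotations = annotations,
                gaf = gaf, upCut = upCut, downCut = downCut,
                aggregation = aggregation, fraction = fraction,
                nTopLast = as.integer(nTopLast),
                distancePairing = distancePairing, maxPairs = maxPairs,
                phyleticLevels = phyleticLevels, enabled = enabled,
                seed = as.integer(seed), outDir = outDir)
    denThresholds(cfg$upCut, cfg$downCut)          # validates
    stopifnot(cfg$fraction > 0, cfg$fraction < 1,
              cfg$aggregation %in% c("max", "sum", "mean"),
              cfg$distancePairing %in% c("matched", "all"))
    structure(cfg, class = "denRunConfig")
}

#' Read a run configuration from YAML
#'
#' Keys mirror the arguments of [denRunConfig()]; unknown keys are hard
#' errors.
#'
#' @param path YAML file path.
#' @return a `denRunConfig`.
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    known <- names(formals(denRunConfig))
    unknown <- setdiff(names(y), known)
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    do.call(denRunConfig, y)
}

#' Run the whole analysis from files
#'
#' Executes count -> aggregate -> partition -> features -> comparisons and
#' writes, under `config$outDir`: `den.tsv` (per-gene DENs and set labels),
#' `features.tsv`, `results.tsv` and `results.json`, top/last gene lists,
#' `report.md` and `run_metadata.json` (config echo, seed, package version,
#' input checksums). A failure at any stage leaves a `FAILED` marker file
#' naming the stage and re-raises the error.
#'
#' @param config a [denRunConfig()] or path to a YAML config.
#' @return invisibly, the comparison results data.frame.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- readRunConfig(config)
    stopifnot(inherits(config, "denRunConfig"))
    stage <- "validate"
    outDir <- config$outDir
    fail <- function(e) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        writeLines(paste("stage:", stage, "-", conditionMessage(e)),
                   file.path(outDir, "FAILED"))
        stop("pipeline failed at stage '", stage, "': ",
             conditionMessage(e), call. = FALSE)
    }
    tryCatch({
        for (p in c(config$matrix, config$map))
            if (!file.exists(p)) stop("missing input file: ", p)
        opt <- c("loci", "tissue", "variants", "interactions",
                 "annotations", "gaf")
        for (nm in opt)
            if (!is.null(config[[nm]]) && !file.exists(config[[nm]]))
                stop("missing input file: ", config[[nm]])
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        unlink(file.path(outDir, "FAILED"))

        stage <- "count"
        fcm <- readFoldChangeMatrix(config$matrix)
        probeCounts <- countRegulation(
            fcm, denThresholds(config$upCut, config$downCut))
        stage <- "aggregate"
        map <- readProbeGeneMap(config$map)
        geneCounts <- suppressMessages(
            aggregateToGenes(probeCounts, map, config$aggregation))

        stage <- "features"
        feats <- .loadFeatures(config)

        stage <- "partition"
        partUp <- partitionGenes(geneCounts, "up", config$fraction)
        partDn <- partitionGenes(geneCounts, "down", config$fraction)

        stage <- "compare"
        results <- runFullAnalysis(
            geneCounts, feats, fraction = config$fraction,
            nTopLast = config$nTopLast,
            distancePairing = config$distancePairing,
            maxPairs = config$maxPairs, seed = config$seed,
            enabled = config$enabled)

        stage <- "write"
        .writeOutputs(outDir, config, geneCounts, partUp, partDn, feats,
                      results)
        invisible(results)
    }, error = fail)
}

# Build the denFeatures bundle from whichever inputs the config names.
.loadFeatures <- function(config) {
    loci <- if (!is.null(config$loci))
        readGeneLoci(config$loci, config$lociFormat) else NULL
    tes <- if (!is.null(config$tissue))
        tissueSpecificity(readTissueMatrix(config$tissue)) else NULL
    ees <- homolog <- phyletic <- NULL
    if (!is.null(config$annotations)) {
        ann <- readAnnotationTable(config$annotations)
        if ("ees_stage" %in% names(ann))
            ees <- suppressWarnings(
                earliestStage(setNames(ann$ees_stage, ann$gene_id)))
        if ("homolog_count" %in% names(ann))
            homolog <- setNames(as.numeric(ann$homolog_count), ann$gene_id)
        if ("phyletic_age" %in% names(ann))
            phyletic <- setNames(as.character(ann$phyletic_age), ann$gene_id)
    }
    variants <- if (!is.null(config$variants) && !is.null(loci)) {
        v <- readVariants(config$variants, config$variantsFormat)
        variantSummary(loci, v)
    } else NULL
    degree <- if (!is.null(config$interactions)) {
        d <- ppiDegrees(readInteractions(config$interactions))
        setNames(d$degree, d$gene_id)
    } else NULL
    classes <- if (!is.null(config$gaf))
        subcellularClasses(readGaf(config$gaf)) else NULL
    denFeatures(loci = loci, tes = tes, ees = ees, homolog = homolog,
                phyletic = phyletic,
                phyleticLevels = config$phyleticLevels,
                variants = variants, degree = degree, classes = classes)
}

.writeOutputs <- function(outDir, config, geneCounts, partUp, partDn,
                          feats, results) {
    k <- regCounts(geneCounts)
    den <- data.frame(
        gene_id = k$unit_id, up_count = k$up_count,
        down_count = k$down_count,
        up_label = ifelse(k$unit_id %in% highSet(partUp), "up_h", "up_l"),
        down_label = ifelse(k$unit_id %in% highSet(partDn), "down_h",
                            "down_l"),
        stringsAsFactors = FALSE)
    den <- den[.radixOrder(den$gene_id), ]
    .writeTsv(den, file.path(outDir, "den.tsv"))

    ft <- data.frame(gene_id = den$gene_id, stringsAsFactors = FALSE)
    pull <- function(x) if (is.null(x)) NA else unname(x[ft$gene_id])
    ft$tes <- pull(feats$tes)
    ft$ees_ordinal <- pull(feats$ees)
    ft$homolog_count <- pull(feats$homolog)
    ft$phyletic_age <- pull(feats$phyletic)
    if (!is.null(feats$variants)) {
        vi <- match(ft$gene_id, feats$variants$gene_id)
        ft$snp_count <- feats$variants$snp_count[vi]
        ft$dsnp_count <- feats$variants$dsnp_count[vi]
        ft$snp_density <- feats$variants$snp_density[vi]
    }
    ft$degree <- pull(feats$degree)
    if (!is.null(feats$classes)) {
        cl <- vapply(split(feats$classes$class, feats$classes$gene_id),
                     paste, "", collapse = ";")
        ft$classes <- unname(cl[ft$gene_id])
    }
    .writeTsv(ft, file.path(outDir, "features.tsv"))

    .writeTsv(results, file.path(outDir, "results.tsv"))
    jsonlite::write_json(results, file.path(outDir, "results.json"),
                         dataframe = "rows", na = "null", digits = NA,
                         pretty = TRUE)
    sk <- attr(results, "skipped")
    if (!is.null(sk) && nrow(sk))
        .writeTsv(sk, file.path(outDir, "skipped.tsv"))

    nGenes <- nrow(k)
    if (2L * config$nTopLast <= nGenes) {
        for (dirn in c("up", "down")) {
            tl <- topLastN(geneCounts, dirn, config$nTopLast)
            suf <- toupper(substr(dirn, 1, 1))
            writeLines(tl$top, file.path(
                outDir, sprintf("T%d%s.txt", config$nTopLast, suf)))
            writeLines(tl$last, file.path(
                outDir, sprintf("L%d%s.txt", config$nTopLast, suf)))
        }
    }

    writeLines(summarizeReport(results), file.path(outDir, "report.md"))

    inputs <- Filter(Negate(is.null),
                     config[c("matrix", "map", "loci", "tissue", "variants",
                              "interactions", "annotations", "gaf")])
    meta <- list(
        package = "denfreq",
        version = as.character(utils::packageVersion("denfreq")),
        seed = config$seed,
        config = unclass(config),
        input_md5 = as.list(tools::md5sum(unlist(inputs))),
        n_genes = nGenes,
        n_comparisons = nrow(results))
    jsonlite::write_json(meta, file.path(outDir, "run_metadata.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    invisible(outDir)
}
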