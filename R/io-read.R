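#' Read a probe-by-sample log fold change matrix
#'
#' Parses a delimited matrix whose first row names the treated samples and
#' whose first column names the probesets; every other cell is a natural-log
#' fold change. Empty cells and the sentinels `NA`/`NaN` become missing
#' values. Duplicate probe or sample identifiers and non-numeric cells are
#' hard errors naming the offender.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A [FoldChangeMatrix-class].
#' @export
readFoldChangeMatrix <- function(path, dialect = c("tsv", "csv")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("file not found: ", path)
    sep <- if (dialect == "tsv") "\t" else ","
    dt <- data.table::fread(path, sep = sep, header = TRUE,
                            colClasses = "character", na.strings = NULL,
                            data.table = FALSE)
    if (ncol(dt) < 2L) stop("matrix needs a probe column and >= 1 sample")
    probes <- as.character(dt[[1L]])
    samples <- colnames(dt)[-1L]
    if (anyDuplicated(probes))
        stop("duplicated probe id: ", probes[duplicated(probes)][1L])
    if (anyDuplicated(samples))
        stop("duplicated sample id: ", samples[duplicated(samples)][1L])
    vals <- matrix(NA_real_, nrow = length(probes), ncol = length(samples),
                   dimnames = list(probes, samples))
    for (j in seq_along(samples)) {
        raw <- trimws(dt[[j + 1L]])
        missing <- raw %in% c("", "NA", "NaN", "nan", "na")
        num <- suppressWarnings(as.numeric(raw))
        bad <- is.na(num) & !missing
        if (any(bad)) {
            i <- which(bad)[1L]
            stop(sprintf("non-numeric cell '%s' at probe '%s', sample '%s'",
                         raw[i], probes[i], samples[j]))
        }
        num[missing] <- NA_real_
        vals[, j] <- num
    }
    FoldChangeMatrix(vals)
}

#' Write a FoldChangeMatrix to a delimited file
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces every double exactly.
#'
#' @param x a [FoldChangeMatrix-class].
#' @param path output file path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
writeFoldChangeMatrix <- function(x, path, dialect = c("tsv", "csv")) {
    dialect <- match.arg(dialect)
    sep <- if (dialect == "tsv") "\t" else ","
    v <- lnFC(x)
    body <- matrix(sprintf("%.17g", v), nrow = nrow(v))
    body[is.na(v)] <- "NA"
    lines <- c(paste(c("probe_id", colnames(v)), collapse = sep),
               paste(rownames(v), apply(body, 1L, paste, collapse = sep),
                     sep = sep))
    writeLines(lines, path)
    invisible(path)
}

#' Read a probe-to-gene mapping table
#'
#' Two-column delimited file (header `probe_id`, `gene_id`, or the first two
#' columns). Each probe maps to exactly one gene; many probes may share a
#' gene.
#'
#' @param path file path.
#' @return data.frame with columns `probe_id`, `gene_id`.
#' @export
readProbeGeneMap <- function(path) {
    df <- read.delim(path, colClasses = "character")
    if (ncol(df) < 2L) stop("probe map needs two columns")
    if (all(c("probe_id", "gene_id") %in% names(df)))
        df <- df[, c("probe_id", "gene_id")]
    else {
        df <- df[, 1:2]
        names(df) <- c("probe_id", "gene_id")
    }
    if (anyDuplicated(df$probe_id))
        stop("duplicated probe id in map: ",
             df$probe_id[duplicated(df$probe_id)][1L])
    if (any(!nzchar(trimws(df$gene_id))))
        stop("empty gene id in probe map")
    df
}

#' Read gene loci from BED or GFF3
#'
#' Returns one locus per gene as a `GRanges` (1-based, closed intervals, the
#' native convention of the GenomicRanges stack; a BED record `start,end`
#' becomes `[start+1, end]`, so `width()` equals the BED length, and GFF3
#' records import natively). Multiple records of one gene on the same
#' chromosome are merged to their spanning interval; if a gene has records on
#' several chromosomes only the chromosome with the longest span is kept,
#' with a warning. Zero- or negative-width records are rejected with a
#' warning.
#'
#' @param path file path.
#' @param format `"bed"` or `"gff3"`.
#' @return named `GRanges` with metadata column `gene_id`.
#' @export
readGeneLoci <- function(path, format = c("bed", "gff3")) {
    format <- match.arg(format)
    gr <- rtracklayer::import(path, format = format)
    md <- mcols(gr)
    gid <- if (format == "bed") md$name
           else if (!is.null(md$gene_id)) md$gene_id
           else if (!is.null(md$ID)) md$ID
           else md$Name
    gid <- as.character(gid)
    if (any(is.na(gid) | !nzchar(gid)))
        stop("locus record without a gene identifier")
    bad <- width(gr) < 1L
    if (any(bad)) {
        warning(sum(bad), " locus record(s) with non-positive length rejected")
        gr <- gr[!bad]
        gid <- gid[!bad]
    }
    df <- data.frame(gene_id = gid, chrom = as.character(seqnames(gr)),
                     start = start(gr), end = end(gr),
                     strand = as.character(strand(gr)))
    # merge per (gene, chromosome) to the spanning interval
    key <- paste(df$gene_id, df$chrom, sep = "\r")
    agg <- data.frame(
        gene_id = df$gene_id[!duplicated(key)],
        chrom = df$chrom[!duplicated(key)],
        start = as.integer(tapply(df$start, key, min)[unique(key)]),
        end = as.integer(tapply(df$end, key, max)[unique(key)]),
        strand = df$strand[!duplicated(key)])
    multi <- unique(agg$gene_id[duplicated(agg$gene_id)])
    if (length(multi)) {
        warning("gene(s) with loci on multiple chromosomes, keeping the ",
                "longest span: ", paste(head(multi, 5L), collapse = ", "))
        agg <- agg[.radixOrder(agg$gene_id, -(agg$end - agg$start)), ]
        agg <- agg[!duplicated(agg$gene_id), ]
    }
    agg <- agg[.radixOrder(agg$gene_id), ]
    out <- GRanges(agg$chrom, IRanges(agg$start, agg$end),
                   strand = agg$strand, gene_id = agg$gene_id)
    names(out) <- agg$gene_id
    out
}

# Split a raw clinical-significance string into a normalized label set.
.splitClinSig <- function(x) {
    parts <- strsplit(x, "[,;/|]")
    lapply(parts, function(p) {
        p <- .normLabel(p)
        p[nzchar(p) & p != "."]
    })
}

#' Read variants from VCF or a ClinVar-style table
#'
#' VCF records use their native 1-based `POS`; `ID` equal to `.` means the
#' variant has no dbSNP identifier. Clinical significance is taken from the
#' `CLNSIG` INFO field (VCF) or a `clinical_significance` column (TSV,
#' 1-based `position` column) and split on commas, semicolons, slashes and
#' pipes into a normalized (lower-case, underscore) label set. Records with
#' an unparseable position are dropped with a warning.
#'
#' @param path file path.
#' @param format `"vcf"` or `"tsv"`.
#' @return `GRanges` (width-1 positions) with metadata columns `rs_id`
#'   (NA when absent) and `clin_sig` (a `CharacterList`).
#' @export
readVariants <- function(path, format = c("vcf", "tsv")) {
    format <- match.arg(format)
    if (format == "vcf") {
        v <- vcfR::read.vcfR(path, verbose = FALSE)
        fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
        chrom <- fix$CHROM
        pos <- suppressWarnings(as.integer(fix$POS))
        id <- fix$ID
        info <- fix$INFO
        cln <- rep(NA_character_, length(info))
        hit <- regmatches(info, regexpr("CLNSIG=[^;]*", info))
        has <- grepl("CLNSIG=", info)
        cln[has] <- sub("^CLNSIG=", "", hit)
    } else {
        df <- read.delim(path, colClasses = "character")
        need <- c("rs_id", "chromosome", "position", "clinical_significance")
        if (!all(need %in% names(df)))
            stop("variant table needs columns: ", paste(need, collapse = ", "))
        chrom <- df$chromosome
        pos <- suppressWarnings(as.integer(df$position))
        id <- df$rs_id
        cln <- df$clinical_significance
    }
    bad <- is.na(pos) | pos < 1L
    if (any(bad)) {
        warning(sum(bad), " variant record(s) with malformed position dropped")
        chrom <- chrom[!bad]; pos <- pos[!bad]; id <- id[!bad]
        cln <- cln[!bad]
    }
    id[is.na(id) | id == "." | !nzchar(trimws(id))] <- NA_character_
    cln[is.na(cln)] <- ""
    gr <- GRanges(chrom, IRanges(pos, pos))
    mcols(gr)$rs_id <- id
    mcols(gr)$clin_sig <- CharacterList(.splitClinSig(cln))
    gr
}

#' Read a protein-protein interaction edge list
#'
#' Tab-separated, BioGRID-like. Interactor columns are `gene_a`/`gene_b` or
#' BioGRID's official-symbol columns; the experimental system type column is
#' mapped to `physical`/`genetic`; an optional modification column (e.g.
#' `Ubiquitination`) is carried through for downstream filtering. Edges are
#' undirected: each is canonicalized (endpoints in C-locale order) and exact
#' duplicates are collapsed.
#'
#' @param path file path.
#' @return data.frame with columns `gene_a`, `gene_b`, `system_class`,
#'   `modification` (NA when absent).
#' @export
readInteractions <- function(path) {
    df <- read.delim(path, colClasses = "character", check.names = FALSE)
    pick <- function(cands) {
        hit <- intersect(cands, names(df))
        if (length(hit)) df[[hit[1L]]] else NULL
    }
    a <- pick(c("gene_a", "Official Symbol Interactor A",
                "OFFICIAL_SYMBOL_A", "InteractorA"))
    b <- pick(c("gene_b", "Official Symbol Interactor B",
                "OFFICIAL_SYMBOL_B", "InteractorB"))
    if (is.null(a) || is.null(b))
        stop("interaction table is missing an interactor column")
    sys <- pick(c("system_class", "Experimental System Type",
                  "EXPERIMENTAL_SYSTEM_TYPE"))
    if (is.null(sys)) sys <- rep("physical", length(a))
    mod <- pick(c("modification", "Modification", "Post Translational Modifications"))
    if (is.null(mod)) mod <- rep(NA_character_, length(a))
    keep <- nzchar(trimws(a)) & nzchar(trimws(b))
    a <- trimws(a[keep]); b <- trimws(b[keep])
    sys <- ifelse(grepl("genetic", tolower(sys[keep])), "genetic", "physical")
    mod <- mod[keep]
    mod[!is.na(mod) & !nzchar(trimws(mod))] <- NA_character_
    # canonical endpoint order in the C locale
    lev <- sort(unique(c(a, b)), method = "radix")
    swap <- match(a, lev) > match(b, lev)
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    out <- data.frame(gene_a = a, gene_b = b, system_class = sys,
                      modification = mod, stringsAsFactors = FALSE)
    out[!duplicated(out), , drop = FALSE]
}

#' Read a gene-by-tissue expression matrix
#'
#' First column holds gene identifiers, remaining columns one tissue each.
#' Multiple rows for one gene are averaged per tissue; negative values
#' (possible in processed microarray data) are clipped to zero.
#'
#' @param path file path.
#' @return numeric matrix, genes in rows (rownames), tissues in columns.
#' @export
readTissueMatrix <- function(path) {
    df <- read.delim(path, check.names = FALSE)
    genes <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    if (anyDuplicated(genes)) {
        m <- rowsum(m, group = genes, reorder = TRUE)
        cnt <- table(genes)
        m <- m / as.vector(cnt[rownames(m)])
        genes <- rownames(m)
    }
    m[m < 0] <- 0
    rownames(m) <- genes
    m
}

#' Read a per-gene annotation table
#'
#' Wide delimited table: a `gene_id` column plus one column per feature
#' (homolog count, phyletic age, earliest expression stage, ...). Each gene
#' may appear only once.
#'
#' @param path file path.
#' @return data.frame keyed by `gene_id`.
#' @export
readAnnotationTable <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    if (!"gene_id" %in% names(df)) {
        names(df)[1L] <- "gene_id"
    }
    df$gene_id <- as.character(df$gene_id)
    if (anyDuplicated(df$gene_id))
        stop("duplicated gene id in annotation table: ",
             df$gene_id[duplicated(df$gene_id)][1L])
    df
}

#' Read GO annotations from a GAF 2.x file
#'
#' Comment lines (`!`) are skipped. Returns the columns needed for
#' subcellular classification: gene symbol (column 3), qualifier (column 4),
#' GO id (column 5) and aspect (column 9).
#'
#' @param path file path.
#' @return data.frame with columns `gene_id`, `qualifier`, `go_id`, `aspect`.
#' @export
readGaf <- function(path) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
    if (!length(lines))
        return(data.frame(gene_id = character(), qualifier = character(),
                          go_id = character(), aspect = character()))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    short <- vapply(parts, length, 0L) < 9L
    if (any(short)) stop("malformed GAF line (fewer than 9 columns) at line ",
                         which(short)[1L])
    data.frame(gene_id = vapply(parts, `[[`, "", 3L),
               qualifier = vapply(parts, `[[`, "", 4L),
               go_id = vapply(parts, `[[`, "", 5L),
               aspect = vapply(parts, `[[`, "", 9L),
               stringsAsFactors = FALSE)
}
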