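#' Human-readable summary of a comparison suite
#'
#' Formats the rows of a [runFullAnalysis()] result as a markdown report
#' with one section per analysis axis. Every number in the report is taken
#' verbatim from the results table; nothing is recomputed, so the report is
#' byte-identical whenever the results are.
#'
#' @param results data.frame of ComparisonResult rows.
#' @return character vector of markdown lines.
#' @export
summarizeReport <- function(results) {
    if (is.null(results) || !nrow(results))
        stop("no comparison results to report")
    fmtP <- function(p) ifelse(p < 1e-4, sprintf("%.3e", p),
                               sprintf("%.4f", p))
    fmtRow <- function(r) {
        sprintf("- **%s** (%s, %s vs %s): statistic %.4g, p = %s%s, %s",
                r$feature, r$test, r$group_high, r$group_low, r$statistic,
                fmtP(r$p_value),
                ifelse(is.na(r$flag), "", paste0(" [", r$flag, "]")),
                switch(r$direction,
                       high_greater = paste0(r$group_high, " greater"),
                       low_greater = paste0(r$group_low, " greater"),
                       "no direction"))
    }
    section <- function(title, rows) {
        if (!nrow(rows)) return(character())
        c(paste("##", title), "",
          vapply(seq_len(nrow(rows)), function(i) fmtRow(rows[i, ]), ""),
          "")
    }
    axes <- list(
        "Chromosomal clustering" = "chrom_distance",
        "Baseline expression" = c("tes", "tes_vs_den", "ees"),
        "Evolution" = c("homolog_count", "phyletic_age"),
        "SNP and disease-SNP" = c("snp_density", "dsnp_fraction"),
        "Interaction network and localization" =
            c("ppi_degree", "degree_vs_den", "subcellular"))
    out <- c("# DEN comparison report", "",
             sprintf("%d comparisons (%d up, %d down).",
                     nrow(results),
                     sum(results$den_direction == "up"),
                     sum(results$den_direction == "down")), "")
    for (ti in names(axes))
        out <- c(out, section(ti, results[results$feature %in% axes[[ti]], ,
                                          drop = FALSE]))
    perChrom <- results[startsWith(results$feature, "dsnp_fraction_"), ,
                        drop = FALSE]
    out <- c(out, section("Per-chromosome disease-SNP fraction", perChrom))
    ud <- results[startsWith(results$feature, "chrom_updown"), ,
                  drop = FALSE]
    out <- c(out, section("Per-chromosome up vs down regulation", ud))
    out
}
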