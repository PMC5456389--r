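# Deterministic C-locale ordering (radix), used for every ranking so that
# partitions are byte-identical across platforms and locales.
.radixOrder <- function(...) order(..., method = "radix")

# Normalize a label: trim, lower-case, spaces -> underscores.
.normLabel <- function(x) {
    x <- tolower(trimws(x))
    gsub("[[:space:]]+", "_", x)
}

# Deterministic TSV writer. Numeric columns are formatted with up to
# `digits` significant digits via C's %g, so output bytes do not depend on
# options(digits) or locale.
.writeTsv <- function(df, path, digits = 10L) {
    out <- df
    for (j in seq_along(out)) {
        if (is.double(out[[j]]))
            out[[j]] <- sprintf(paste0("%.", digits, "g"), out[[j]])
        if (is.list(out[[j]]))
            out[[j]] <- vapply(out[[j]], paste, "", collapse = ";")
    }
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE, na = "NA")
    invisible(path)
}

# Moment skewness (population form); NA if fewer than 3 values or zero sd.
.skewness <- function(x) {
    x <- x[!is.na(x)]
    n <- length(x)
    if (n < 3L) return(NA_real_)
    s <- sd(x) * sqrt((n - 1) / n)
    if (s == 0) return(NA_real_)
    mean((x - mean(x))^3) / s^3
}

# Round half up to integer (R's round() is round-half-even).
.roundHalfUp <- function(x) floor(x + 0.5)

# Derive a stream of child seeds from one master seed, all < 2^31.
.childSeeds <- function(seed, n) {
    set.seed(seed)
    sample.int(.Machine$integer.max - 1L, n)
}
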