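# Fixture builders used across the suite; everything is generated in code.

# Panel from a dosage matrix with an auto-generated map (one chromosome
# unless chrom/pos given).
makePanel <- function(d, chrom = NULL, pos = NULL, alleleA = "A",
                      alleleB = "G", lineIds = NULL, groups = NULL) {
    d <- as.matrix(d)
    n <- nrow(d)
    if (is.null(chrom)) chrom <- rep("1", n)
    if (is.null(pos)) pos <- seq_len(n) * 100L
    if (is.null(lineIds)) lineIds <- sprintf("L%02d", seq_len(ncol(d)))
    map <- data.frame(snp_id = sprintf("s%03d", seq_len(n)),
                      chromosome = as.character(chrom),
                      position_bp = as.integer(pos),
                      allele_a = alleleA, allele_b = alleleB)
    GenotypePanel(d, map, lineIds, groups = groups)
}

# Random dosage panel: SNPs x lines with given missing probability.
randomPanel <- function(nSnps, nLines, pMissing = 0.05, chrom = NULL,
                        pos = NULL, groups = NULL) {
    d <- matrix(sample(0:2, nSnps * nLines, replace = TRUE), nSnps)
    d[matrix(runif(nSnps * nLines) < pMissing, nSnps)] <- NA
    makePanel(d, chrom = chrom, pos = pos, groups = groups)
}

# 5-SNP x 4-line fixture with all call states and an unplaced SNP.
smallFixturePanel <- function() {
    d <- matrix(c(0L, 1L, 2L, NA, 0L,
                  2L, 1L, 0L, 1L, NA,
                  NA, 0L, 2L, 2L, 1L,
                  1L, 2L, NA, 0L, 0L), nrow = 5)
    map <- data.frame(
        snp_id = paste0("s", 1:5),
        chromosome = c("1", "1", "2", "2", "unknown"),
        position_bp = c(100L, 20000000L, 500L, 900L, NA),
        allele_a = c("A", "C", "G", "A", "T"),
        allele_b = c("G", "T", "A", "C", "C"))
    GenotypePanel(d, map, c("La", "Lb", "Lc", "Ld"))
}

# Independent scalar oracles.
oracleGd <- function(freqs) 1 - sum(freqs * freqs)
oraclePic <- function(freqs) {
    k <- length(freqs)
    s <- 0
    for (u in seq_len(k - 1)) for (v in (u + 1):k)
        s <- s + 2 * freqs[u]^2 * freqs[v]^2
    1 - sum(freqs^2) - s
}
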