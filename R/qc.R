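#' Per-locus summary statistics
#'
#' For every SNP: number of called lines, missing rate, heterozygosity
#' (fraction of non-missing calls that are heterozygous), `allele_b`
#' frequency among non-missing allele copies (a heterozygote contributes
#' one copy of each allele), minor allele frequency, and the uncorrected
#' gene diversity and PIC implied by the allele frequency. SNPs with no
#' non-missing call get `missing_rate` 1 and `NA` frequencies — never a
#' division by zero.
#'
#' @param panel a [GenotypePanel-class]
#' @param lines optional character vector restricting to a subset of lines
#' @return data.frame with one row per SNP: `snp_id`, `n_called`,
#'   `missing_rate`, `het_rate`, `freq_b`, `maf`, `gene_diversity`, `pic`
#' @examples
#' gp <- GenotypePanel(matrix(c(0L, 1L, NA, 2L), 1),
#'                     data.frame(snp_id = "s1", chromosome = "1",
#'                                position_bp = 1L, allele_a = "A",
#'                                allele_b = "G"),
#'                     lineIds = paste0("L", 1:4))
#' locusSummaries(gp)
#' @export
locusSummaries <- function(panel, lines = NULL) {
    d <- dosage(panel)
    if (!is.null(lines)) d <- d[, lines, drop = FALSE]
    if (ncol(d) == 0L) stop("panel has no lines")
    called <- !is.na(d)
    n_called <- rowSums(called)
    n_lines <- ncol(d)
    db <- d
    db[!called] <- 0L
    count_b <- rowSums(db)
    freq_b <- ifelse(n_called > 0, count_b / (2 * n_called), NA_real_)
    het <- rowSums(d == 1L, na.rm = TRUE)
    p <- freq_b
    q <- 1 - p
    data.frame(
        snp_id = snpMap(panel)$snp_id,
        n_called = as.integer(n_called),
        missing_rate = 1 - n_called / n_lines,
        het_rate = ifelse(n_called > 0, het / n_called, NA_real_),
        freq_b = freq_b,
        maf = pmin(p, q),
        gene_diversity = 1 - p^2 - q^2,
        pic = 1 - (p^2 + q^2) - 2 * p^2 * q^2,
        row.names = NULL)
}

#' Primary SNP quality filter
#'
#' Keeps SNPs passing the panel-level quality tier: missing rate at most
#' `maxMissing`, heterozygosity at most `maxHet`, and minor allele
#' frequency at least `minMaf`. Exclusion is strict (`>`, `>`, `<`), so
#' boundary values are retained. SNPs with undefined frequency (no calls)
#' are excluded. Order is preserved; the filter is idempotent.
#'
#' @param summaries output of [locusSummaries()]
#' @param maxMissing,maxHet,minMaf filter thresholds
#' @return integer indices (rows of `summaries`) of the kept SNPs
#' @export
filterPrimary <- function(summaries, maxMissing = 0.20, maxHet = 0.20,
                          minMaf = 0.05) {
    keep <- summaries$missing_rate <= maxMissing &
        !is.na(summaries$het_rate) & summaries$het_rate <= maxHet &
        !is.na(summaries$maf) & summaries$maf >= minMaf
    which(keep)
}

#' Stringent SNP subset for structure analysis
#'
#' Second, stricter tier used to pick a diverse SNP subset: missing rate
#' strictly below `maxMissing` and gene diversity strictly above `minGd`
#' (both inequalities strict). Gene diversity is the uncorrected
#' panel-wide estimate carried in `summaries`.
#'
#' @param summaries output of [locusSummaries()]
#' @param maxMissing,minGd thresholds
#' @return integer indices of the kept SNPs
#' @export
filterStructureSubset <- function(summaries, maxMissing = 0.05,
                                  minGd = 0.45) {
    keep <- summaries$missing_rate < maxMissing &
        !is.na(summaries$gene_diversity) & summaries$gene_diversity > minGd
    which(keep)
}
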