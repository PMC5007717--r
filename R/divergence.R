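#' Allele counts per SNP within two groups
#'
#' Counts allele copies among non-missing calls in each of two groups:
#' a heterozygote contributes one copy of each allele, a missing call
#' none. Lines outside the two named groups (including `"Mixed"`) are
#' ignored. SNPs with zero called alleles in either group are marked
#' untestable; their number is reported as an attribute.
#'
#' @param panel a [GenotypePanel-class] with a group assignment
#' @param groupA,groupB group labels to compare
#' @return data.frame per SNP: `snp_id`, `chromosome`, `position_bp`,
#'   `count_a_A`, `count_b_A`, `freq_b_A`, `count_a_B`, `count_b_B`,
#'   `freq_b_B`, `testable`; attribute `n_untestable`
#' @export
groupAlleleCounts <- function(panel, groupA, groupB) {
    g <- groupAssignment(panel)
    if (is.null(g)) stop("panel has no group assignment")
    la <- names(g)[!is.na(g) & g == groupA]
    lb <- names(g)[!is.na(g) & g == groupB]
    if (!length(la) || !length(lb))
        stop("both groups must be non-empty")
    map <- snpMap(panel)
    cnt <- function(lines) {
        d <- dosage(panel)[, lines, drop = FALSE]
        called <- !is.na(d)
        d[!called] <- 0L
        b <- rowSums(d)
        tot <- 2 * rowSums(called)
        list(a = tot - b, b = b, tot = tot)
    }
    A <- cnt(la)
    B <- cnt(lb)
    testable <- A$tot > 0 & B$tot > 0
    res <- data.frame(
        snp_id = map$snp_id, chromosome = map$chromosome,
        position_bp = map$position_bp,
        count_a_A = A$a, count_b_A = A$b,
        freq_b_A = ifelse(A$tot > 0, A$b / A$tot, NA_real_),
        count_a_B = B$a, count_b_B = B$b,
        freq_b_B = ifelse(B$tot > 0, B$b / B$tot, NA_real_),
        testable = testable)
    attr(res, "n_untestable") <- sum(!testable)
    if (any(!testable))
        message(sum(!testable),
                " SNP(s) with no called alleles in a group excluded",
                " from divergence tests")
    res
}

#' Screen private-allele ("unique") SNPs between two groups
#'
#' A SNP is credited as unique to a group when both alleles segregate in
#' that group (both counts positive) while the other group carries exactly
#' one allele. With `credit = "monomorphic"` the inverse reading is used:
#' the SNP is credited to the group in which it is monomorphic.
#'
#' @param counts output of [groupAlleleCounts()]
#' @param credit which group the SNP is credited to: the polymorphic one
#'   (default) or the monomorphic one
#' @return `counts` with a `unique_to` column in
#'   `{"none", "groupA", "groupB"}`, plus attribute `per_chromosome`, a
#'   per-chromosome tally of unique SNPs credited to each group
#' @export
screenUniqueSnps <- function(counts, credit = c("polymorphic",
                                                "monomorphic")) {
    credit <- match.arg(credit)
    polyA <- counts$count_a_A > 0 & counts$count_b_A > 0
    polyB <- counts$count_a_B > 0 & counts$count_b_B > 0
    monoA <- xor(counts$count_a_A > 0, counts$count_b_A > 0)
    monoB <- xor(counts$count_a_B > 0, counts$count_b_B > 0)
    uA <- polyA & monoB
    uB <- polyB & monoA
    counts$unique_to <- ifelse(uA, if (credit == "polymorphic") "groupA"
                               else "groupB",
                        ifelse(uB, if (credit == "polymorphic") "groupB"
                               else "groupA", "none"))
    chr <- factor(counts$chromosome,
                  levels = .chromLevels(counts$chromosome))
    tallyA <- table(chr[counts$unique_to == "groupA"])
    tallyB <- table(chr[counts$unique_to == "groupB"])
    attr(counts, "per_chromosome") <- data.frame(
        chromosome = levels(chr),
        unique_groupA = as.integer(tallyA),
        unique_groupB = as.integer(tallyB))
    counts
}

#' Chi-square test of allele-frequency divergence per SNP
#'
#' Pearson chi-square (df = 1, no continuity correction) on the 2x2
#' allele-count table of each SNP between the two groups, with
#' significance at `p < alpha`. A zero marginal (allele absent in both
#' groups, or no calls in a group) makes the test undefined and the
#' record untestable. An expected count below 5 in any cell sets a
#' `low_count` advisory flag but the statistic is still computed.
#'
#' @param counts output of [groupAlleleCounts()] (optionally after
#'   [screenUniqueSnps()])
#' @param alpha per-SNP significance level (default 0.001; no
#'   multiple-testing correction is applied)
#' @return `counts` with columns `chi2_statistic`, `p_value`,
#'   `significant`, `low_count`, `freq_variation` (absolute difference of
#'   `allele_b` frequencies) and an updated `testable`
#' @export
chisqDivergence <- function(counts, alpha = 0.001) {
    a <- as.numeric(counts$count_a_A)
    b <- as.numeric(counts$count_b_A)
    c <- as.numeric(counts$count_a_B)
    d <- as.numeric(counts$count_b_B)
    n <- a + b + c + d
    m1 <- a + c          # allele_a marginal
    m2 <- b + d          # allele_b marginal
    g1 <- a + b          # group A total
    g2 <- c + d          # group B total
    testable <- counts$testable & m1 > 0 & m2 > 0
    chi2 <- ifelse(testable, n * (a * d - b * c)^2 / (g1 * g2 * m1 * m2),
                   NA_real_)
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
    expmin <- pmin(g1 * m1, g1 * m2, g2 * m1, g2 * m2) / n
    counts$chi2_statistic <- chi2
    counts$p_value <- p
    counts$significant <- !is.na(p) & p < alpha
    counts$low_count <- testable & expmin < 5
    counts$freq_variation <- abs(counts$freq_b_A - counts$freq_b_B)
    counts$testable <- testable
    counts
}

#' Allele-frequency variation between two groups
#'
#' Absolute difference of the designated allele's frequency between the
#' groups; invariant to which allele is designated since
#' `|p - q| = |(1-p) - (1-q)|`.
#'
#' @param freqA,freqB frequencies of the same allele in the two groups
#' @return value in `[0, 1]`
#' @examples
#' alleleFrequencyVariation(0.888, 0.118)  # 0.770
#' @export
alleleFrequencyVariation <- function(freqA, freqB) {
    abs(freqA - freqB)
}

#' Top SNPs by allele-frequency variation
#'
#' Ranks records by descending `freq_variation`, ties broken by
#' (chromosome, position) ascending, and returns the first `k` — a core
#' marker set distinguishing the two groups.
#'
#' @param records output of [chisqDivergence()]
#' @param k number of SNPs to return (all records if `k` exceeds the
#'   record count)
#' @return the top-`k` rows with columns `snp_id`, `chromosome`,
#'   `position_bp`, `freq_b_A`, `freq_b_B`, `freq_variation`
#' @export
topVariantSnps <- function(records, k = 10L) {
    ok <- records[!is.na(records$freq_variation), , drop = FALSE]
    ord <- order(-ok$freq_variation,
                 match(ok$chromosome, .chromLevels(ok$chromosome)),
                 ok$position_bp)
    ok <- ok[ord, , drop = FALSE]
    head(ok[, c("snp_id", "chromosome", "position_bp", "freq_b_A",
                "freq_b_B", "freq_variation")],
         min(k, nrow(ok)))
}

#' Binned ratio of divergent SNPs
#'
#' Per genomic bin, the number of significantly divergent SNPs, the
#' number of testable SNPs, their ratio, and the complementary
#' non-variant ratio. Untestable SNPs enter neither numerator nor
#' denominator. Bin-grid semantics follow [binnedScan()].
#'
#' @param map SNP map aligned with `records`
#' @param records output of [chisqDivergence()]
#' @param spec a [binSpec()]
#' @return data.frame per bin: `chromosome`, `bin_start_bp`,
#'   `bin_end_bp`, `n_snps` (testable), `n_significant`, `statistic`
#'   (variant ratio), `nonvariant_ratio`, `flag`
#' @export
binnedVariantRatio <- function(map, records, spec = binSpec()) {
    stopifnot(nrow(map) == nrow(records))
    placed <- map$chromosome != "unknown" & !is.na(map$position_bp)
    map <- map[placed, , drop = FALSE]
    testable <- records$testable[placed]
    sig <- records$significant[placed] & testable
    out <- list()
    for (chr in .chromLevels(map$chromosome)) {
        i <- map$chromosome == chr
        bin <- .binIndex(map$position_bp[i], spec$binSizeBp)
        nb <- max(bin) + 1L
        nTest <- tabulate(bin[testable[i]] + 1L, nbins = nb)
        nSig <- tabulate(bin[sig[i]] + 1L, nbins = nb)
        dropped <- nTest < spec$minSnpsPerBin
        ratio <- ifelse(dropped, NA_real_, nSig / nTest)
        out[[chr]] <- data.frame(
            chromosome = chr,
            bin_start_bp = (seq_len(nb) - 1L) * spec$binSizeBp,
            bin_end_bp = seq_len(nb) * spec$binSizeBp,
            n_snps = nTest,
            n_significant = ifelse(dropped, NA_integer_, nSig),
            statistic = ratio,
            nonvariant_ratio = 1 - ratio,
            flag = ifelse(dropped, "dropped", "none"))
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}
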