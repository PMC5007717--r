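#' Gene diversity of one locus
#'
#' Gene diversity (expected heterozygosity) is the probability that two
#' alleles drawn at random from the population differ. The uncorrected
#' estimator is \eqn{\hat D = 1 - \sum_u \tilde p_u^2}{D = 1 - sum(p^2)};
#' the small-sample/inbreeding correction divides by
#' \eqn{1 - (1+f)/n}{1 - (1+f)/n}, where `f` is the inbreeding coefficient
#' and `n` the number of sampled individuals. The default is the
#' uncorrected form, whose biallelic maximum is exactly 0.5 at equal
#' frequencies; the corrected form is available via `correct = TRUE`.
#'
#' @param freqs numeric allele-frequency vector summing to 1 (any number
#'   of alleles; biallelic in typical use)
#' @param correct apply the `(1 - (1+f)/n)` denominator?
#' @param f inbreeding coefficient in `[0, 1]` (used when `correct`)
#' @param n sample size (individuals; used when `correct`)
#' @return gene diversity value
#' @examples
#' geneDiversity(c(0.5, 0.5))            # 0.5, the biallelic maximum
#' geneDiversity(c(0.9, 0.1))            # 0.18
#' geneDiversity(c(0.9, 0.1), correct = TRUE, f = 1, n = 10)  # 0.225
#' @export
geneDiversity <- function(freqs, correct = FALSE, f = 0, n = NULL) {
    .checkFreqs(freqs)
    d <- 1 - sum(freqs^2)
    if (!correct) return(d)
    if (is.null(n)) stop("sample size n is required when correct = TRUE")
    denom <- 1 - (1 + f) / n
    if (denom <= 0)
        stop("correction denominator 1 - (1+f)/n must be positive")
    d / denom
}

#' Polymorphism information content of one locus
#'
#' \eqn{PIC = 1 - \sum_u \tilde p_u^2 -
#'   \sum_{u<v} 2 \tilde p_u^2 \tilde p_v^2}{
#'   PIC = 1 - sum(p^2) - sum_{u<v} 2 p_u^2 p_v^2}.
#' For a biallelic locus the maximum is 0.375 at equal frequencies.
#'
#' @param freqs numeric allele-frequency vector summing to 1
#' @return PIC value
#' @examples
#' pic(c(0.5, 0.5))   # 0.375
#' pic(c(1, 0))       # 0, monomorphic
#' @export
pic <- function(freqs) {
    .checkFreqs(freqs)
    p2 <- freqs^2
    cross <- (sum(p2)^2 - sum(p2^2)) / 2   # sum over unordered pairs u<v
    1 - sum(p2) - 2 * cross
}

#' Group-wise diversity summary
#'
#' Recomputes allele frequencies within each group's lines only and
#' summarizes gene diversity and PIC across SNPs, one row per group
#' (plus optionally the entire panel). Groups with fewer than two lines
#' are skipped with a warning. Intended for SNP sets that already passed
#' the primary filter; pass `snps` to restrict.
#'
#' @param panel a [GenotypePanel-class] with a group assignment
#' @param snps optional integer/character index of SNPs to use
#' @param includeEntire add an `"Entire"` row over all lines?
#' @return data.frame: `group`, `n_lines`, mean/min/max `gene_diversity`
#'   and `pic` (over SNPs with defined frequency in that group)
#' @export
groupDiversityTable <- function(panel, snps = NULL, includeEntire = TRUE) {
    g <- groupAssignment(panel)
    if (is.null(g)) stop("panel has no group assignment")
    sub <- if (is.null(snps)) panel else panel[snps, ]
    grps <- unique(g[!is.na(g)])
    grps <- grps[order(match(grps, c(setdiff(grps, "Mixed"), "Mixed")))]
    rows <- list()
    for (lab in grps) {
        ln <- names(g)[!is.na(g) & g == lab]
        if (length(ln) < 2L) {
            warning("group '", lab, "' has fewer than 2 lines; skipped")
            next
        }
        rows[[lab]] <- .diversityRow(sub, ln, lab)
    }
    if (includeEntire)
        rows[["Entire"]] <- .diversityRow(sub, lineIds(sub), "Entire")
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

.diversityRow <- function(panel, lines, label) {
    s <- locusSummaries(panel, lines = lines)
    gd <- s$gene_diversity[!is.na(s$gene_diversity)]
    pv <- s$pic[!is.na(s$pic)]
    data.frame(group = label, n_lines = length(lines),
               mean_gd = mean(gd), min_gd = min(gd), max_gd = max(gd),
               mean_pic = mean(pv), min_pic = min(pv), max_pic = max(pv))
}

#' Specification of a genomic bin grid
#'
#' Bins tile each chromosome as half-open intervals
#' `[k * binSizeBp, (k+1) * binSizeBp)` in 0-based coordinates, indexed
#' from the chromosome start; bins holding fewer than `minSnpsPerBin`
#' SNPs are flagged `dropped` in scans (limited statistical power).
#'
#' @param binSizeBp bin width in bp (default 10 Mb)
#' @param minSnpsPerBin minimum SNPs for a bin to be scored (default 30)
#' @return a `binSpec` list
#' @export
binSpec <- function(binSizeBp = 1e7, minSnpsPerBin = 30L) {
    stopifnot(binSizeBp > 0, minSnpsPerBin >= 1)
    structure(list(binSizeBp = binSizeBp,
                   minSnpsPerBin = as.integer(minSnpsPerBin)),
              class = "binSpec")
}

#' Binned genome scan of a per-SNP statistic
#'
#' Averages a per-SNP value over the SNPs falling in each genomic bin.
#' Only placed SNPs (known chromosome and position) participate. Every
#' bin from the chromosome start up to the last SNP-bearing bin is
#' reported; bins with fewer than `spec$minSnpsPerBin` SNPs are flagged
#' `dropped` and carry `NA` statistic.
#'
#' @param map SNP map (data.frame as from [snpMap()])
#' @param values numeric per-SNP values aligned with `map` rows
#' @param spec a [binSpec()]
#' @return data.frame: `chromosome`, `bin_start_bp`, `bin_end_bp`
#'   (0-based half-open), `n_snps`, `statistic`, `flag`
#'   (`"none"` or `"dropped"`)
#' @export
binnedScan <- function(map, values, spec = binSpec()) {
    stopifnot(length(values) == nrow(map))
    placed <- map$chromosome != "unknown" & !is.na(map$position_bp)
    map <- map[placed, , drop = FALSE]
    values <- values[placed]
    out <- list()
    for (chr in .chromLevels(map$chromosome)) {
        i <- map$chromosome == chr
        bin <- .binIndex(map$position_bp[i], spec$binSizeBp)
        nb <- max(bin) + 1L
        cnt <- tabulate(bin + 1L, nbins = nb)
        ssum <- rep(0, nb)
        ok <- !is.na(values[i])
        agg <- tapply(values[i][ok], bin[ok], sum)
        ssum[as.integer(names(agg)) + 1L] <- agg
        cntv <- tabulate(bin[ok] + 1L, nbins = nb)
        dropped <- cnt < spec$minSnpsPerBin
        stat <- ifelse(dropped | cntv == 0, NA_real_, ssum / cntv)
        out[[chr]] <- data.frame(
            chromosome = chr,
            bin_start_bp = (seq_len(nb) - 1L) * spec$binSizeBp,
            bin_end_bp = seq_len(nb) * spec$binSizeBp,
            n_snps = cnt,
            statistic = stat,
            flag = ifelse(dropped, "dropped", "none"))
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Call diversity hotspots across one or more scans
#'
#' Flags bins whose statistic is strictly below `lowCutoff` as low
#' hotspots and strictly above `highCutoff` as high hotspots, per scan;
#' a bin is a *common* hotspot when it carries the same (non-`none`,
#' non-dropped) flag in every supplied scan. Values exactly at a cutoff
#' are not hotspots.
#'
#' @param scans named list of [binnedScan()] results on the same bin grid
#'   (e.g. entire panel plus each group)
#' @param lowCutoff,highCutoff hotspot cutoffs (defaults 0.25 / 0.40,
#'   the conventional gene-diversity hotspot bounds)
#' @return list with `perPanel` (each scan with a `hotspot` column) and
#'   `common` (data.frame of bins flagged identically in all scans)
#' @export
callHotspots <- function(scans, lowCutoff = 0.25, highCutoff = 0.40) {
    stopifnot(length(scans) >= 1)
    key <- function(s) paste(s$chromosome, s$bin_start_bp)
    k0 <- key(scans[[1]])
    for (s in scans[-1])
        if (!identical(key(s), k0))
            stop("scans are not on the same bin grid")
    flagged <- lapply(scans, function(s) {
        s$hotspot <- ifelse(is.na(s$statistic), "none",
                     ifelse(s$statistic < lowCutoff, "low_hotspot",
                     ifelse(s$statistic > highCutoff, "high_hotspot",
                            "none")))
        s
    })
    fl <- vapply(flagged, function(s) s$hotspot, character(nrow(scans[[1]])))
    fl <- matrix(fl, nrow = nrow(scans[[1]]))
    same <- apply(fl, 1L, function(r) length(unique(r)) == 1L)
    common <- same & fl[, 1L] != "none"
    cm <- scans[[1]][common, c("chromosome", "bin_start_bp", "bin_end_bp"),
                     drop = FALSE]
    cm$hotspot <- fl[common, 1L]
    rownames(cm) <- NULL
    list(perPanel = flagged, common = cm)
}
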