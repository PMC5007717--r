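#' Identity-by-state similarity of two lines
#'
#' A SNP scores 1 when both calls are non-missing and identical as
#' unordered genotypes (heterozygote matches heterozygote; a heterozygote
#' never matches a homozygote), else 0. The similarity ratio is the score
#' sum divided by the number of SNPs called in both lines
#' (`denominator = "shared"`, the default) or by the full SNP count
#' (`denominator = "all"`, the literal total-SNP reading, which deflates
#' ratios for lines with missing data).
#'
#' @param calls_i,calls_j aligned dosage vectors (`{0,1,2,NA}`)
#' @param denominator `"shared"` or `"all"`
#' @return list: `n_compared`, `n_matching`, `similarity_ratio` (`NA`
#'   when the denominator is zero)
#' @export
similarityRatio <- function(calls_i, calls_j,
                            denominator = c("shared", "all")) {
    denominator <- match.arg(denominator)
    stopifnot(length(calls_i) == length(calls_j))
    both <- !is.na(calls_i) & !is.na(calls_j)
    m <- sum(calls_i[both] == calls_j[both])
    nc <- sum(both)
    den <- if (denominator == "shared") nc else length(calls_i)
    list(n_compared = nc, n_matching = m,
         similarity_ratio = if (den > 0) m / den else NA_real_)
}

#' All-pairs similarity matrix
#'
#' Identity-by-state similarity for every unordered pair of lines,
#' with a report of the panel mean and the extreme pairs.
#'
#' @param panel a [GenotypePanel-class] (at least 2 lines)
#' @param denominator see [similarityRatio()]
#' @return list: `similarity` (symmetric lines x lines matrix, unit
#'   diagonal), `mean` (over unordered off-diagonal pairs), `max_pair`
#'   and `min_pair` (list of `lines`, `value`)
#' @export
similarityMatrix <- function(panel, denominator = c("shared", "all")) {
    denominator <- match.arg(denominator)
    d <- dosage(panel)
    if (ncol(d) < 2L) stop("need at least 2 lines")
    called <- !is.na(d)
    M <- matrix(0, ncol(d), ncol(d))
    for (gval in 0:2) {
        ind <- d == gval & called
        M <- M + crossprod(ind)
    }
    N <- crossprod(called)
    den <- if (denominator == "shared") N else nrow(d)
    S <- M / den
    S[N == 0] <- NA_real_
    diag(S) <- 1
    dimnames(S) <- list(colnames(d), colnames(d))
    off <- S[upper.tri(S)]
    pairIdx <- which(upper.tri(S), arr.ind = TRUE)
    wmax <- which.max(off)
    wmin <- which.min(off)
    list(similarity = S,
         mean = mean(off, na.rm = TRUE),
         max_pair = list(lines = colnames(d)[pairIdx[wmax, ]],
                         value = off[wmax]),
         min_pair = list(lines = colnames(d)[pairIdx[wmin, ]],
                         value = off[wmin]))
}

#' Most similar lines to a focal line
#'
#' The `k` lines with highest similarity to the focal line, descending,
#' ties broken by line id ascending.
#'
#' @param similarity symmetric similarity matrix (as from
#'   [similarityMatrix()]`$similarity`)
#' @param focal focal line id
#' @param k subset size (all other lines if `k` is larger)
#' @return data.frame: `line_id`, `similarity`
#' @export
mostSimilarLines <- function(similarity, focal, k = 30L) {
    if (!(focal %in% rownames(similarity)))
        stop("focal line '", focal, "' not in similarity matrix")
    s <- similarity[focal, ]
    s <- s[names(s) != focal]
    ord <- order(-s, names(s))
    top <- head(ord, min(k, length(s)))
    data.frame(line_id = names(s)[top], similarity = unname(s[top]))
}

#' Per-bin similarity of a subset to a focal line
#'
#' Similarity ratio of the focal line to each subset line restricted to
#' the SNPs of each genomic bin, plus the subset mean per bin and per
#' chromosome. Bins with fewer than `spec$minSnpsPerBin` SNPs are
#' flagged dropped; a line x bin cell with zero jointly called SNPs is
#' undefined (`NA`).
#'
#' @param panel a [GenotypePanel-class]
#' @param focal focal line id
#' @param subset character vector of comparison line ids (non-empty)
#' @param spec a [binSpec()]
#' @return list: `bins` (data.frame per bin: chromosome, bounds,
#'   `n_snps`, `flag`, `subset_mean`, plus one similarity column per
#'   subset line), `chromosome_means` (focal-vs-subset mean by
#'   chromosome)
#' @export
binnedSimilarity <- function(panel, focal, subset, spec = binSpec()) {
    stopifnot(length(subset) >= 1)
    map <- snpMap(panel)
    placed <- map$chromosome != "unknown" & !is.na(map$position_bp)
    d <- dosage(panel)[placed, c(focal, subset), drop = FALSE]
    map <- map[placed, , drop = FALSE]
    df <- d[, focal]
    match01 <- (d[, subset, drop = FALSE] == df) & !is.na(df)
    called <- !is.na(d[, subset, drop = FALSE]) & !is.na(df)
    match01[!called] <- FALSE
    out <- list()
    chrRows <- list()
    for (chr in .chromLevels(map$chromosome)) {
        i <- map$chromosome == chr
        bin <- .binIndex(map$position_bp[i], spec$binSizeBp)
        nb <- max(bin) + 1L
        cnt <- tabulate(bin + 1L, nbins = nb)
        sim <- matrix(NA_real_, nb, length(subset),
                      dimnames = list(NULL, subset))
        for (b in seq_len(nb) - 1L) {
            rows <- which(bin == b)
            if (!length(rows)) next
            mc <- colSums(match01[i, , drop = FALSE][rows, , drop = FALSE])
            nc <- colSums(called[i, , drop = FALSE][rows, , drop = FALSE])
            sim[b + 1L, ] <- ifelse(nc > 0, mc / nc, NA_real_)
        }
        dropped <- cnt < spec$minSnpsPerBin
        bins <- data.frame(
            chromosome = chr,
            bin_start_bp = (seq_len(nb) - 1L) * spec$binSizeBp,
            bin_end_bp = seq_len(nb) * spec$binSizeBp,
            n_snps = cnt,
            flag = ifelse(dropped, "dropped", "none"),
            subset_mean = ifelse(dropped, NA_real_,
                                 rowMeans(sim, na.rm = TRUE)))
        out[[chr]] <- cbind(bins, as.data.frame(sim, optional = TRUE))
        mc <- colSums(match01[i, , drop = FALSE])
        nc <- colSums(called[i, , drop = FALSE])
        chrRows[[chr]] <- data.frame(
            chromosome = chr,
            subset_mean = mean(ifelse(nc > 0, mc / nc, NA_real_),
                               na.rm = TRUE))
    }
    list(bins = do.call(rbind, c(out, list(make.row.names = FALSE))),
         chromosome_means = do.call(rbind,
             c(chrRows, list(make.row.names = FALSE))))
}

#' Conserved regions from binned similarity
#'
#' Maximal runs of adjacent non-dropped bins whose subset-mean
#' similarity strictly exceeds the threshold, merged per chromosome —
#' the breeding-conserved segments shared between a focal line and its
#' derived lines.
#'
#' @param binned output of [binnedSimilarity()]
#' @param threshold similarity threshold (default 0.85)
#' @return data.frame per region: `chromosome`, `start_bp`, `end_bp`,
#'   `n_bins`, `n_snps`, `mean_similarity`
#' @export
conservedRegions <- function(binned, threshold = 0.85) {
    bins <- binned$bins
    res <- list()
    for (chr in unique(bins$chromosome)) {
        b <- bins[bins$chromosome == chr, , drop = FALSE]
        b <- b[b$flag != "dropped", , drop = FALSE]
        if (!nrow(b)) next
        hi <- !is.na(b$subset_mean) & b$subset_mean > threshold
        if (!any(hi)) next
        # runs over adjacent scored bins (adjacent in bin coordinates)
        adjacent <- b$bin_start_bp[-1] == b$bin_end_bp[-nrow(b)]
        runId <- cumsum(c(TRUE, !(hi[-1] & hi[-nrow(b)] & adjacent)))
        for (r in unique(runId[hi])) {
            rows <- which(runId == r & hi)
            if (!length(rows)) next
            res[[length(res) + 1L]] <- data.frame(
                chromosome = chr,
                start_bp = b$bin_start_bp[rows[1]],
                end_bp = b$bin_end_bp[rows[length(rows)]],
                n_bins = length(rows),
                n_snps = sum(b$n_snps[rows]),
                mean_similarity = stats::weighted.mean(
                    b$subset_mean[rows], b$n_snps[rows]))
        }
    }
    if (!length(res))
        return(data.frame(chromosome = character(), start_bp = numeric(),
                          end_bp = numeric(), n_bins = integer(),
                          n_snps = integer(), mean_similarity = numeric()))
    do.call(rbind, res)
}

#' VanRaden genomic relationship matrix
#'
#' \eqn{K = Z Z^\top / (2 \sum_k p_k (1 - p_k))}{K = Z Z' / (2 sum p(1-p))}
#' where `Z` is the dosage matrix with each SNP centred by twice its
#' panel `allele_b` frequency. Missing dosages are mean-imputed per SNP
#' (centring them to zero); monomorphic SNPs are excluded from numerator
#' and denominator.
#'
#' @param panel a [GenotypePanel-class]
#' @return symmetric lines x lines kinship matrix
#' @examples
#' # one SNP, p = 0.5, dosages (2, 0): K = [[2, -2], [-2, 2]]
#' @export
vanRadenKinship <- function(panel) {
    d <- dosage(panel)
    called <- !is.na(d)
    p <- rowSums(d, na.rm = TRUE) / (2 * rowSums(called))
    poly <- !is.na(p) & p > 0 & p < 1
    if (!any(poly)) stop("all SNPs are monomorphic; kinship undefined")
    d <- d[poly, , drop = FALSE]
    p <- p[poly]
    Z <- d - 2 * p
    Z[is.na(Z)] <- 0            # mean imputation after centring
    K <- crossprod(Z) / (2 * sum(p * (1 - p)))
    dimnames(K) <- list(colnames(d), colnames(d))
    K
}

#' Distribution summary of pairwise kinship
#'
#' Off-diagonal kinship coefficients, with negatives optionally clipped
#' to zero (reporting only — the stored matrix is never modified), a
#' histogram at the stated bin width, and the fraction exactly zero
#' after clipping.
#'
#' @param K kinship matrix from [vanRadenKinship()]
#' @param binWidth histogram bin width (default 0.05)
#' @param clipNegative clip negative estimates to 0 before summarizing?
#' @return list: `values` (off-diagonal estimates after optional
#'   clipping), `fraction_zero`, `fraction_0_to_0.5` (share in `[0, 0.5]`),
#'   `histogram` (data.frame `lower`, `upper`, `count`)
#' @export
kinshipDistribution <- function(K, binWidth = 0.05, clipNegative = TRUE) {
    v <- K[upper.tri(K)]
    if (clipNegative) v <- pmax(v, 0)
    top <- max(v, binWidth)
    breaks <- seq(0, ceiling(top / binWidth) * binWidth, by = binWidth)
    cnt <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                                 left.open = FALSE),
                    nbins = length(breaks) - 1L)
    list(values = v,
         fraction_zero = mean(v == 0),
         fraction_0_to_0.5 = mean(v >= 0 & v <= 0.5),
         histogram = data.frame(lower = breaks[-length(breaks)],
                                upper = breaks[-1L],
                                count = cnt))
}
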