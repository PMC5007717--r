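#' Default LD distance-interval grid
#'
#' Half-open physical-distance intervals (bp) used for LD decay
#' profiling: 0–0.1, 0.1–0.25, 0.25–0.5, 0.5–0.75, 0.75–1, 1–1.5, 1.5–2,
#' 2–2.5, 2.5–3, 3–3.5, 3.5–4, 4–5, 5–10 Mb and beyond 10 Mb.
#'
#' @return numeric vector of interval breakpoints in bp (with `Inf`)
#' @export
defaultLdGrid <- function() {
    c(0, 0.1, 0.25, 0.5, 0.75, 1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 10, Inf) * 1e6
}

#' Pairwise r-squared between SNPs on one chromosome
#'
#' Composite (dosage-correlation) linkage disequilibrium: for each pair
#' of placed SNPs on the chromosome, the squared Pearson correlation of
#' the two dosage vectors over lines non-missing at both SNPs. No
#' phasing is attempted — for near-inbred lines dosage r-squared and
#' haplotype r-squared coincide almost exactly. Pairs farther apart than
#' `maxDistanceBp` are skipped; pairs where either SNP is monomorphic
#' within the jointly called lines are dropped with a tally.
#'
#' @param panel a [GenotypePanel-class]
#' @param chromosome chromosome label
#' @param maxDistanceBp maximum pair distance (default 50 Mb; `Inf` for
#'   all pairs)
#' @param lines optional subset of line ids (e.g. one group)
#' @return data.frame per pair: `snp_i`, `snp_j`, `distance_bp`, `r2`,
#'   `n_lines`; attribute `n_monomorphic_skipped`
#' @export
pairwiseR2 <- function(panel, chromosome, maxDistanceBp = 5e7,
                       lines = NULL) {
    map <- snpMap(panel)
    sel <- map$chromosome == chromosome & !is.na(map$position_bp)
    if (sum(sel) < 2L)
        stop("need at least 2 placed SNPs on chromosome ", chromosome)
    d <- dosage(panel)[sel, , drop = FALSE]
    if (!is.null(lines)) d <- d[, lines, drop = FALSE]
    pos <- map$position_bp[sel]
    ids <- map$snp_id[sel]
    ord <- order(pos)
    d <- d[ord, , drop = FALSE]
    pos <- pos[ord]
    ids <- ids[ord]
    # pairwise-deletion Pearson correlation via BLAS crossproducts
    dm <- t(d)                                   # lines x SNPs
    M <- !is.na(dm)
    X0 <- dm
    X0[!M] <- 0
    storage.mode(X0) <- "double"
    storage.mode(M) <- "double"
    nmat <- crossprod(M)
    Sx <- crossprod(X0, M)                       # sum of x over joint lines
    Sxy <- crossprod(X0)
    Sxx <- crossprod(X0^2, M)
    vx <- nmat * Sxx - Sx^2                      # n^2 * var-type terms
    cov <- nmat * Sxy - Sx * t(Sx)
    den <- vx * t(vx)
    cc <- matrix(NA_real_, ncol(dm), ncol(dm))
    pos_den <- den > 0
    cc[pos_den] <- cov[pos_den] / sqrt(den[pos_den])
    p <- nrow(d)
    i <- rep.int(seq_len(p - 1L), (p - 1L):1L)
    j <- sequence((p - 1L):1L, from = 2:p)
    dist <- pos[j] - pos[i]
    keep <- dist <= maxDistanceBp
    i <- i[keep]; j <- j[keep]; dist <- dist[keep]
    r <- cc[cbind(i, j)]
    mono <- is.na(r)
    res <- data.frame(snp_i = ids[i][!mono], snp_j = ids[j][!mono],
                      distance_bp = dist[!mono], r2 = r[!mono]^2,
                      n_lines = nmat[cbind(i, j)][!mono])
    attr(res, "n_monomorphic_skipped") <- sum(mono)
    res
}

#' LD decay profile over distance intervals
#'
#' Means r-squared within each physical-distance interval and derives
#' the decay interval: scanning intervals in ascending distance, the
#' first whose mean r-squared falls strictly below `cutoff` (subsequent
#' intervals need not stay below; set `requireSustained = TRUE` to demand
#' that every later non-empty interval also stays below). Intervals with
#' no pairs are skipped in the scan and flagged.
#'
#' @param pairs data.frame from [pairwiseR2()] (possibly row-bound over
#'   chromosomes/pools)
#' @param grid interval breakpoints in bp (default [defaultLdGrid()])
#' @param cutoff r-squared threshold (default 0.1)
#' @param requireSustained see description
#' @return list: `profile` (data.frame `lower_bp`, `upper_bp`, `n_pairs`,
#'   `mean_r2`), `decay_interval` (`c(lower, upper)` in bp, or `NULL`),
#'   `beyond_grid` (logical: no interval fell below the cutoff)
#' @export
decayProfile <- function(pairs, grid = defaultLdGrid(), cutoff = 0.1,
                         requireSustained = FALSE) {
    if (!nrow(pairs)) stop("no SNP pairs supplied")
    iv <- cut(pairs$distance_bp, breaks = grid, right = FALSE,
              include.lowest = FALSE)
    nInt <- length(grid) - 1L
    npairs <- tabulate(iv, nbins = nInt)
    means <- rep(NA_real_, nInt)
    agg <- tapply(pairs$r2, iv, mean)
    means[!is.na(agg)] <- agg[!is.na(agg)]
    prof <- data.frame(lower_bp = grid[-length(grid)],
                       upper_bp = grid[-1L],
                       n_pairs = npairs, mean_r2 = means)
    nonEmpty <- which(npairs > 0)
    below <- nonEmpty[means[nonEmpty] < cutoff]
    decay <- NULL
    if (length(below)) {
        k <- below[1L]
        ok <- TRUE
        if (requireSustained) {
            later <- nonEmpty[nonEmpty >= k]
            ok <- all(means[later] < cutoff)
            if (!ok) {
                for (kk in below) {
                    later <- nonEmpty[nonEmpty >= kk]
                    if (all(means[later] < cutoff)) {
                        k <- kk; ok <- TRUE; break
                    }
                }
            }
        }
        if (ok) decay <- c(lower = grid[k], upper = grid[k + 1L])
    }
    if (any(npairs == 0))
        message(sum(npairs == 0),
                " empty distance interval(s) skipped in decay scan")
    list(profile = prof, decay_interval = decay,
         beyond_grid = is.null(decay))
}

#' LD decay intervals by panel and chromosome
#'
#' For the entire panel and each named group, per chromosome and pooled
#' over all chromosomes, the decay interval at the r-squared cutoff.
#' Groups smaller than 10 lines are computed with a warning.
#'
#' @param panel a [GenotypePanel-class] with a group assignment
#' @param grid interval breakpoints (bp)
#' @param cutoff r-squared threshold
#' @param maxDistanceBp maximum pair distance considered
#' @param includeMixed include the `"Mixed"` group as a panel?
#' @return data.frame: `panel`, `chromosome` (label or `"Total"`),
#'   `decay_lower_bp`, `decay_upper_bp` (`NA` when beyond the grid)
#' @export
decayByPanelAndChromosome <- function(panel, grid = defaultLdGrid(),
                                      cutoff = 0.1, maxDistanceBp = 5e7,
                                      includeMixed = FALSE) {
    g <- groupAssignment(panel)
    pools <- list(Entire = lineIds(panel))
    if (!is.null(g)) {
        grps <- unique(g[!is.na(g)])
        if (!includeMixed) grps <- setdiff(grps, "Mixed")
        for (lab in grps) pools[[lab]] <- names(g)[!is.na(g) & g == lab]
    }
    map <- snpMap(panel)
    chrs <- .chromLevels(map$chromosome[map$chromosome != "unknown"])
    rows <- list()
    for (pn in names(pools)) {
        ln <- pools[[pn]]
        if (length(ln) < 10L)
            warning("panel '", pn, "' has fewer than 10 lines")
        all_pairs <- list()
        for (chr in chrs) {
            pr <- pairwiseR2(panel, chr, maxDistanceBp, lines = ln)
            all_pairs[[chr]] <- pr
            dec <- suppressMessages(decayProfile(pr, grid, cutoff))
            rows[[paste(pn, chr)]] <- data.frame(
                panel = pn, chromosome = chr,
                decay_lower_bp = if (is.null(dec$decay_interval))
                    NA_real_ else dec$decay_interval[["lower"]],
                decay_upper_bp = if (is.null(dec$decay_interval))
                    NA_real_ else dec$decay_interval[["upper"]])
        }
        pooled <- do.call(rbind, all_pairs)
        dec <- suppressMessages(decayProfile(pooled, grid, cutoff))
        rows[[paste(pn, "Total")]] <- data.frame(
            panel = pn, chromosome = "Total",
            decay_lower_bp = if (is.null(dec$decay_interval))
                NA_real_ else dec$decay_interval[["lower"]],
            decay_upper_bp = if (is.null(dec$decay_interval))
                NA_real_ else dec$decay_interval[["upper"]])
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
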