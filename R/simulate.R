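#' Configuration for a synthetic structured inbred panel
#'
#' Defines the generating conditions of [simulatePanel()]: a multi-group
#' inbred panel with Balding–Nichols group divergence, distance-decaying
#' within-group haplotype correlation, admixed lines, forced
#' high-divergence windows, and founder-derived lines sharing long
#' conserved segments.
#'
#' @param seed integer seed; identical seeds give identical panels
#' @param nChromosomes number of chromosomes (default 10, maize-like)
#' @param chromosomeLengthBp length of each chromosome (default 150 Mb)
#' @param nSnps total SNPs to place (uniform positions per chromosome,
#'   equal share per chromosome); the post-hoc MAF floor can remove some
#' @param groups list of group definitions, each a list with `label`,
#'   `nLines` (>= 2), `fst` (Balding–Nichols divergence F in (0, 1)) and
#'   `ldLambdaBp` (haplotype correlation length: latent correlation
#'   between adjacent SNPs is `exp(-d / ldLambdaBp)`)
#' @param nAdmixed number of admixed (`"Mixed"`) lines
#' @param admixtureProportions per-group ancestry proportions of admixed
#'   lines (default uniform); ancestry is drawn per chromosome so that
#'   within-chromosome LD is preserved
#' @param residualHetRate probability a homozygous call is flipped to
#'   heterozygous (residual heterozygosity of near-inbred lines;
#'   default 0.02)
#' @param missingRate probability a call is set missing (default 0.01)
#' @param divergentWindows list of windows forcing an allele-frequency
#'   gap between the first two groups, each a list with `chromosome`,
#'   `startBp`, `endBp`, `gap` in `[0, 1]` (group 1 frequency becomes
#'   `0.5 + gap/2`, group 2 `0.5 - gap/2`)
#' @param founderSegments list of founder-derived segment definitions,
#'   each a list with `group`, `chromosome`, `startBp`, `endBp`,
#'   `nDerived` and `retention` (per-SNP probability a derived line
#'   copies the founder's call inside the window). The founder is the
#'   group's first line, the derived lines the following `nDerived`.
#' @param mafFloor panel minor-allele-frequency floor applied post hoc to
#'   mimic array ascertainment (default 0.05; 0 disables)
#' @param ascertainGroup optional group label; SNPs observed monomorphic
#'   in that group are discarded, mimicking the ascertainment bias of an
#'   array whose SNPs were discovered in one germplasm pool
#' @return a `simulationConfig` list
#' @seealso [simulatePanel()], [demoPanelConfig()]
#' @export
simulationConfig <- function(seed,
                             nChromosomes = 10L,
                             chromosomeLengthBp = 1.5e8,
                             nSnps = 5000L,
                             groups = list(),
                             nAdmixed = 0L,
                             admixtureProportions = NULL,
                             residualHetRate = 0.02,
                             missingRate = 0.01,
                             divergentWindows = list(),
                             founderSegments = list(),
                             mafFloor = 0.05,
                             ascertainGroup = NULL) {
    stopifnot(length(groups) >= 1,
              residualHetRate >= 0, residualHetRate <= 1,
              missingRate >= 0, missingRate <= 1,
              mafFloor >= 0, mafFloor < 0.5)
    for (g in groups)
        stopifnot(!is.null(g$label), g$nLines >= 2,
                  g$fst > 0, g$fst < 1, g$ldLambdaBp > 0)
    for (w in divergentWindows) {
        if (w$gap < 0 || w$gap > 1)
            stop("infeasible frequency gap ", w$gap,
                 ": must lie in [0, 1]")
        if (w$startBp < 0 || w$endBp > chromosomeLengthBp)
            stop("divergent window outside chromosome bounds")
    }
    for (s in founderSegments) {
        stopifnot(s$retention >= 0, s$retention <= 1, s$nDerived >= 1)
        if (s$startBp < 0 || s$endBp > chromosomeLengthBp)
            stop("founder segment outside chromosome bounds")
    }
    if (is.null(admixtureProportions))
        admixtureProportions <- rep(1 / length(groups), length(groups))
    structure(list(seed = as.integer(seed),
                   nChromosomes = as.integer(nChromosomes),
                   chromosomeLengthBp = chromosomeLengthBp,
                   nSnps = as.integer(nSnps), groups = groups,
                   nAdmixed = as.integer(nAdmixed),
                   admixtureProportions = admixtureProportions,
                   residualHetRate = residualHetRate,
                   missingRate = missingRate,
                   divergentWindows = divergentWindows,
                   founderSegments = founderSegments,
                   mafFloor = mafFloor,
                   ascertainGroup = ascertainGroup),
              class = "simulationConfig")
}

#' Simulate a structured inbred SNP panel with known truth
#'
#' Generates a panel under the conditions of a [simulationConfig()]:
#'
#' * SNP positions uniform per chromosome; ancestral allele frequencies
#'   uniform on (0.05, 0.95).
#' * Per-group frequencies from the Balding–Nichols model,
#'   `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the ancestral `p`.
#' * Within each line, allele states follow a first-order latent-Gaussian
#'   Markov process along each chromosome with correlation
#'   `exp(-d / ldLambdaBp)` between adjacent SNPs, so r-squared decays
#'   with distance at the group's correlation length.
#' * Admixed lines draw per-chromosome ancestry with the configured
#'   proportions and are labelled `"Mixed"`.
#' * Divergent windows override the first two groups' frequencies to
#'   enforce the configured gap; founder segments copy the founder's
#'   calls into derived lines with the configured retention.
#' * Lines are homozygous except for the residual heterozygosity rate;
#'   missingness is applied uniformly; finally SNPs below the panel MAF
#'   floor are removed.
#'
#' All randomness comes from the config seed: identical configs give
#' identical panels.
#'
#' @param config a [simulationConfig()]
#' @return list: `panel` (a [GenotypePanel-class] with group
#'   assignment) and `truth`, a manifest list with `snpMap`,
#'   `ancestralFreq`, `groupFreqs` (SNP x group matrix, the frequencies
#'   actually used, after window overrides), `windows`, `segments`
#'   (including founder and derived line ids), `lineGroups`, and
#'   `admixture` (per admixed line, per-chromosome ancestry labels)
#' @export
simulatePanel <- function(config) {
    stopifnot(inherits(config, "simulationConfig"))
    .withSeed(config$seed, .simulatePanelImpl(config))
}

.simulatePanelImpl <- function(cf) {
    nchr <- cf$nChromosomes
    perChr <- rep(cf$nSnps %/% nchr, nchr)
    extra <- cf$nSnps %% nchr
    if (extra) perChr[seq_len(extra)] <- perChr[seq_len(extra)] + 1L
    chrLabs <- as.character(seq_len(nchr))
    pos <- lapply(seq_len(nchr), function(k)
        sort(sample.int(cf$chromosomeLengthBp, perChr[k])))
    map <- data.frame(
        snp_id = sprintf("snp%05d", seq_len(cf$nSnps)),
        chromosome = rep(chrLabs, perChr),
        position_bp = unlist(pos),
        stringsAsFactors = FALSE)
    nts <- c("A", "C", "G", "T")
    aIdx <- sample.int(4L, cf$nSnps, replace = TRUE)
    bOff <- sample.int(3L, cf$nSnps, replace = TRUE)
    map$allele_a <- nts[aIdx]
    map$allele_b <- nts[(aIdx - 1L + bOff) %% 4L + 1L]

    pAnc <- stats::runif(cf$nSnps, 0.05, 0.95)
    nGroups <- length(cf$groups)
    gLabs <- vapply(cf$groups, `[[`, "", "label")
    gFreq <- matrix(NA_real_, cf$nSnps, nGroups,
                    dimnames = list(map$snp_id, gLabs))
    for (k in seq_len(nGroups)) {
        F <- cf$groups[[k]]$fst
        gFreq[, k] <- stats::rbeta(cf$nSnps, pAnc * (1 - F) / F,
                                   (1 - pAnc) * (1 - F) / F)
    }
    for (w in cf$divergentWindows) {
        inw <- map$chromosome == as.character(w$chromosome) &
            map$position_bp >= w$startBp & map$position_bp < w$endBp
        if (nGroups < 2) stop("divergent windows need two groups")
        gFreq[inw, 1L] <- 0.5 + w$gap / 2
        gFreq[inw, 2L] <- 0.5 - w$gap / 2
    }

    lineGroups <- character(0)
    lineIds <- character(0)
    for (k in seq_len(nGroups)) {
        ids <- sprintf("%s_%03d", gLabs[k],
                       seq_len(cf$groups[[k]]$nLines))
        lineIds <- c(lineIds, ids)
        lineGroups <- c(lineGroups, rep(gLabs[k], length(ids)))
    }
    admixIds <- if (cf$nAdmixed > 0)
        sprintf("Mixed_%03d", seq_len(cf$nAdmixed)) else character(0)
    lineIds <- c(lineIds, admixIds)
    lineGroups <- c(lineGroups, rep("Mixed", cf$nAdmixed))
    nLines <- length(lineIds)

    # per-chromosome ancestry of each line (groups: fixed; admixed: drawn)
    ancestry <- matrix(rep(match(lineGroups, gLabs), each = nchr),
                       nrow = nchr)
    admixTruth <- NULL
    if (cf$nAdmixed > 0) {
        cols <- which(lineGroups == "Mixed")
        for (j in cols)
            ancestry[, j] <- sample.int(nGroups, nchr, replace = TRUE,
                                        prob = cf$admixtureProportions)
        admixTruth <- ancestry[, cols, drop = FALSE]
        dimnames(admixTruth) <- list(chrLabs, admixIds)
        admixTruth[] <- gLabs[admixTruth]
    }

    # allele states via latent-Gaussian AR(1) per line per chromosome
    lambda <- vapply(cf$groups, `[[`, 0, "ldLambdaBp")
    allele <- matrix(0L, cf$nSnps, nLines)
    row0 <- 0L
    for (k in seq_len(nchr)) {
        m <- perChr[k]
        rows <- row0 + seq_len(m)
        dgap <- diff(pos[[k]])
        x <- stats::rnorm(nLines)
        lam <- lambda[ancestry[k, ]]
        grpOfLine <- ancestry[k, ]
        thr <- stats::qnorm(gFreq[rows, grpOfLine, drop = FALSE])
        allele[rows[1L], ] <- as.integer(x < thr[1L, ])
        for (t in seq_len(m - 1L)) {
            rho <- exp(-dgap[t] / lam)
            x <- rho * x + sqrt(1 - rho^2) * stats::rnorm(nLines)
            allele[rows[t + 1L], ] <- as.integer(x < thr[t + 1L, ])
        }
        row0 <- row0 + m
    }
    d <- 2L * allele

    segTruth <- list()
    for (s in cf$founderSegments) {
        gl <- which(lineGroups == s$group)
        if (length(gl) < s$nDerived + 1L)
            stop("group '", s$group, "' too small for founder segment")
        founder <- gl[1L]
        derived <- gl[1L + seq_len(s$nDerived)]
        inw <- which(map$chromosome == as.character(s$chromosome) &
                         map$position_bp >= s$startBp &
                         map$position_bp < s$endBp)
        for (j in derived) {
            keep <- stats::runif(length(inw)) < s$retention
            d[inw[keep], j] <- d[inw[keep], founder]
        }
        segTruth[[length(segTruth) + 1L]] <- list(
            chromosome = as.character(s$chromosome),
            startBp = s$startBp, endBp = s$endBp,
            retention = s$retention,
            founder = lineIds[founder], derived = lineIds[derived])
    }

    if (cf$residualHetRate > 0) {
        flip <- stats::runif(length(d)) < cf$residualHetRate
        d[flip] <- 1L
    }
    if (cf$missingRate > 0) {
        miss <- stats::runif(length(d)) < cf$missingRate
        d[miss] <- NA_integer_
    }

    keepSnp <- rep(TRUE, cf$nSnps)
    if (cf$mafFloor > 0) {
        called <- !is.na(d)
        fb <- rowSums(d, na.rm = TRUE) / (2 * rowSums(called))
        maf <- pmin(fb, 1 - fb)
        keepSnp <- !is.na(maf) & maf >= cf$mafFloor
    }
    if (!is.null(cf$ascertainGroup)) {
        cols <- which(lineGroups == cf$ascertainGroup)
        if (!length(cols)) stop("ascertainGroup not among group labels")
        dg <- d[, cols, drop = FALSE]
        fb <- rowSums(dg, na.rm = TRUE) / (2 * rowSums(!is.na(dg)))
        keepSnp <- keepSnp & !is.na(fb) & fb > 0 & fb < 1
    }
    map <- map[keepSnp, , drop = FALSE]
    rownames(map) <- NULL
    d <- d[keepSnp, , drop = FALSE]

    groups <- stats::setNames(lineGroups, lineIds)
    panel <- GenotypePanel(d, map, lineIds, groups = groups)
    truth <- list(snpMap = map,
                  ancestralFreq = pAnc[keepSnp],
                  groupFreqs = gFreq[keepSnp, , drop = FALSE],
                  windows = cf$divergentWindows,
                  segments = segTruth,
                  lineGroups = groups,
                  admixture = admixTruth,
                  config = cf)
    list(panel = panel, truth = truth)
}

#' Ready-made two-group demonstration panel
#'
#' A reduced-scale maize-like study design: ten 150-Mb chromosomes with
#' 5,000 array SNPs; a temperate-like group (140 lines, F = 0.25 — the
#' stronger drift of selected elite material, hence lower diversity —
#' with long haplotype correlation, 1.5 Mb) and a tropical-like group
#' (120 lines, F = 0.15, correlation length five times shorter, 0.3 Mb);
#' 20 admixed
#' lines; one forced high-divergence window at 130–140 Mb of
#' chromosome 2 (frequency gap 0.8); and one founder with 30 derived
#' lines sharing a 30–120 Mb conserved segment on chromosome 7
#' (retention 0.95). Residual heterozygosity 2%, missingness 1%, panel
#' MAF floor 0.05.
#'
#' @param seed integer seed
#' @return a [simulationConfig()]
#' @seealso [simulatePanel()]
#' @export
demoPanelConfig <- function(seed = 1L) {
    simulationConfig(
        seed = seed,
        nChromosomes = 10L,
        chromosomeLengthBp = 1.5e8,
        nSnps = 5000L,
        groups = list(
            list(label = "Temperate", nLines = 140L, fst = 0.25,
                 ldLambdaBp = 1.5e6),
            list(label = "Tropical", nLines = 120L, fst = 0.15,
                 ldLambdaBp = 3e5)),
        nAdmixed = 20L,
        residualHetRate = 0.02,
        missingRate = 0.01,
        divergentWindows = list(
            list(chromosome = "2", startBp = 1.3e8, endBp = 1.4e8,
                 gap = 0.8)),
        founderSegments = list(
            list(group = "Tropical", chromosome = "7", startBp = 3e7,
                 endBp = 1.2e8, nDerived = 30L, retention = 0.95)),
        mafFloor = 0.05)
}

#' Simulate the demonstration panel
#'
#' Convenience wrapper: [simulatePanel()] on [demoPanelConfig()].
#'
#' @param seed integer seed
#' @return as [simulatePanel()]
#' @export
simulateDemoPanel <- function(seed = 1L) {
    simulatePanel(demoPanelConfig(seed))
}
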