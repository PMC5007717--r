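test_that("gene diversity matches hand evaluations", {
    expect_equal(geneDiversity(c(0.5, 0.5)), 0.5)
    expect_equal(geneDiversity(c(0.9, 0.1)), 0.18)
    expect_equal(geneDiversity(c(0.9, 0.1), correct = TRUE, f = 1, n = 10),
                 0.225)
    expect_error(geneDiversity(c(0.9, 0.1), correct = TRUE, f = 1, n = 2),
                 "denominator")
    expect_error(geneDiversity(c(0.6, 0.6)), "sum to 1")
})

test_that("PIC matches hand evaluations and is zero at monomorphism", {
    expect_equal(pic(c(0.5, 0.5)), 0.375)
    expect_equal(pic(c(0.9, 0.1)), 1 - 0.82 - 2 * 0.81 * 0.01)
    expect_equal(pic(c(1, 0)), 0)
})

test_that("GD and PIC equal independent oracles and obey PIC <= GD <= 0.5", {
    set.seed(21)
    for (i in 1:200) {
        k <- sample(2:5, 1)
        f <- as.vector(stats::rgamma(k, 1)); f <- f / sum(f)
        expect_equal(geneDiversity(f), oracleGd(f))
        expect_equal(pic(f), oraclePic(f))
        expect_equal(geneDiversity(sample(f)), geneDiversity(f))
        expect_equal(pic(sample(f)), pic(f))
        f2 <- c(f[1], 1 - f[1])
        expect_equal(geneDiversity(f2), 2 * f2[1] * (1 - f2[1]))
        expect_lte(pic(f2), geneDiversity(f2) + 1e-12)
        expect_lte(geneDiversity(f2), 0.5 + 1e-12)
    }
})

test_that("group diversity recomputes frequencies within groups", {
    d <- rbind(c(0L, 0L, 0L, 2L), c(2L, 2L, 1L, 0L), c(0L, 0L, 2L, 2L))
    gp <- makePanel(d, groups = c(L01 = "A", L02 = "A", L03 = "B",
                                  L04 = "B"))
    tab <- groupDiversityTable(gp)
    # group A lines are identical and homozygous: GD 0 across SNPs
    expect_equal(tab$mean_gd[tab$group == "A"], 0)
    # whole-panel row equals panel-wide locus summaries
    s <- locusSummaries(gp)
    expect_equal(tab$mean_gd[tab$group == "Entire"],
                 mean(s$gene_diversity))
    expect_equal(tab$mean_pic[tab$group == "Entire"], mean(s$pic))
    expect_true(all(tab$min_gd <= tab$mean_gd & tab$mean_gd <= tab$max_gd))
})

test_that("a more diverged pooled group shows higher mean gene diversity", {
    cfg <- function(f2) simulationConfig(
        seed = 303, nChromosomes = 2, chromosomeLengthBp = 5e7,
        nSnps = 600,
        groups = list(list(label = "g1", nLines = 60, fst = 0.02,
                           ldLambdaBp = 1e5),
                      list(label = "g2", nLines = 60, fst = f2,
                           ldLambdaBp = 1e5)),
        mafFloor = 0)
    excess <- function(panel) {
        pooled <- mean(locusSummaries(panel)$gene_diversity, na.rm = TRUE)
        within <- groupDiversityTable(panel, includeEntire = FALSE)
        pooled - mean(within$mean_gd)
    }
    # folding strongly diverged subpopulations inflates pooled GD over
    # the within-group mean, and more so at higher divergence
    eLow <- excess(simulatePanel(cfg(0.02))$panel)
    eHigh <- excess(simulatePanel(cfg(0.45))$panel)
    expect_gt(eHigh, 0)
    expect_gt(eHigh, eLow)
})

test_that("binned scans mean per bin, drop thin bins, match brute force", {
    pos30 <- as.integer(seq(1e6, 9e6, length.out = 30))
    pos29 <- as.integer(seq(11e6, 19e6, length.out = 29))
    gp <- makePanel(matrix(0L, 59, 2), chrom = rep("1", 59),
                    pos = c(pos30, pos29))
    sc <- binnedScan(snpMap(gp), rep(0.4, 59))
    expect_equal(sc$statistic[1], 0.4)
    expect_equal(sc$flag, c("none", "dropped"))
    expect_true(is.na(sc$statistic[2]))

    set.seed(22)
    n <- 1000
    chrom <- sample(c("1", "2"), n, replace = TRUE)
    pos <- sample.int(9e7, n)
    vals <- runif(n)
    map <- data.frame(snp_id = paste0("s", 1:n), chromosome = chrom,
                      position_bp = pos, allele_a = "A", allele_b = "G")
    sc <- binnedScan(map, vals, binSpec(1e7, 5L))
    for (r in sample(nrow(sc), min(20, nrow(sc)))) {
        inBin <- map$chromosome == sc$chromosome[r] &
            (map$position_bp - 1) >= sc$bin_start_bp[r] &
            (map$position_bp - 1) < sc$bin_end_bp[r]
        expect_equal(sc$n_snps[r], sum(inBin))
        if (sc$flag[r] == "none")
            expect_equal(sc$statistic[r], mean(vals[inBin]))
    }
    # bins tile without overlap
    for (ch in unique(sc$chromosome)) {
        b <- sc[sc$chromosome == ch, ]
        expect_equal(b$bin_start_bp[-1], b$bin_end_bp[-nrow(b)])
    }
})

test_that("hotspot calls are strict and common only when shared", {
    mk <- function(stat) data.frame(chromosome = "1",
                                    bin_start_bp = c(0, 1e7),
                                    bin_end_bp = c(1e7, 2e7),
                                    n_snps = 50L, statistic = stat,
                                    flag = "none")
    hs <- callHotspots(list(a = mk(c(0.24, 0.25)), b = mk(c(0.24, 0.50)),
                            c = mk(c(0.24, 0.41))))
    expect_equal(hs$common$hotspot, "low_hotspot")
    expect_equal(hs$common$bin_start_bp, 0)
    # exact cutoff value 0.25 is not a hotspot; 0.41 > 0.40 is
    expect_equal(hs$perPanel$a$hotspot, c("low_hotspot", "none"))
    expect_equal(hs$perPanel$c$hotspot, c("low_hotspot", "high_hotspot"))
    hs2 <- callHotspots(list(a = mk(c(0.24, 0.3)), b = mk(c(0.30, 0.3))))
    expect_equal(nrow(hs2$common), 0L)
    expect_error(callHotspots(list(mk(0.2), mk(0.2)[1, ])), "bin grid")
})

test_that("a window fixed near monomorphism in all groups is a common low hotspot", {
    cfg <- simulationConfig(
        seed = 99, nChromosomes = 2, chromosomeLengthBp = 5e7,
        nSnps = 2500,
        groups = list(list(label = "T1", nLines = 80, fst = 0.1,
                           ldLambdaBp = 1e5),
                      list(label = "T2", nLines = 80, fst = 0.1,
                           ldLambdaBp = 1e5)),
        divergentWindows = list(list(chromosome = "1", startBp = 2e7,
                                     endBp = 3e7, gap = 0)),
        mafFloor = 0)
    sim <- simulatePanel(cfg)
    # gap 0 pins both groups to 0.5 inside the window; to plant a *low*
    # diversity window instead, overwrite with near-fixed frequencies
    truthMap <- snpMap(sim$panel)
    spec <- binSpec(1e7, 10L)
    gp <- sim$panel
    inw <- truthMap$chromosome == "1" & truthMap$position_bp > 2e7 &
        truthMap$position_bp <= 3e7
    d <- dosage(gp)
    d[inw, ] <- 0L
    d[inw, 1:2] <- 2L   # keep just-polymorphic so SNPs survive scans
    gp <- GenotypePanel(d, truthMap, lineIds(gp),
                        groups = groupAssignment(gp))
    s <- locusSummaries(gp)
    scans <- list(
        entire = binnedScan(snpMap(gp), s$gene_diversity, spec),
        T1 = binnedScan(snpMap(gp),
                        locusSummaries(gp, groupLines(gp, "T1"))$gene_diversity,
                        spec),
        T2 = binnedScan(snpMap(gp),
                        locusSummaries(gp, groupLines(gp, "T2"))$gene_diversity,
                        spec))
    hs <- callHotspots(scans)
    low <- hs$common[hs$common$hotspot == "low_hotspot", ]
    expect_true(any(low$chromosome == "1" & low$bin_start_bp == 2e7))
})

test_that("estimated GD recovers generating frequencies closely", {
    cfg <- simulationConfig(
        seed = 404, nChromosomes = 2, chromosomeLengthBp = 5e7,
        nSnps = 500,
        groups = list(list(label = "G", nLines = 1000, fst = 0.2,
                           ldLambdaBp = 1e5)),
        residualHetRate = 0, missingRate = 0, mafFloor = 0)
    sim <- simulatePanel(cfg)
    s <- locusSummaries(sim$panel)
    truth <- sim$truth$groupFreqs[, "G"]
    gdTruth <- 2 * truth * (1 - truth)
    expect_lt(mean(abs(s$gene_diversity - gdTruth)), 0.01)
})
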