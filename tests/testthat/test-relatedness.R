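test_that("similarity ratio counts whole-genotype matches over shared calls", {
    expect_equal(similarityRatio(c(0L, 1L, 2L, 0L),
                                 c(0L, 1L, 0L, 0L))$similarity_ratio, 0.75)
    r <- similarityRatio(c(0L, NA), c(0L, 2L))
    expect_equal(r$similarity_ratio, 1)
    expect_equal(r$n_compared, 1L)
    ident <- similarityRatio(c(0L, 1L, 2L), c(0L, 1L, 2L))
    expect_equal(ident$similarity_ratio, 1)
    # het vs matching homozygote is a mismatch
    expect_equal(similarityRatio(1L, 2L)$similarity_ratio, 0)
    # literal denominator variant
    expect_equal(similarityRatio(c(0L, NA), c(0L, 2L),
                                 denominator = "all")$similarity_ratio, 0.5)
    expect_true(is.na(similarityRatio(NA_integer_,
                                      0L)$similarity_ratio))
})

test_that("similarity matrix matches brute force, is symmetric, unit diagonal", {
    set.seed(51)
    gp <- randomPanel(200, 10, pMissing = 0.1)
    sm <- similarityMatrix(gp)
    S <- sm$similarity
    d <- dosage(gp)
    for (i in 1:9) for (j in (i + 1):10) {
        ref <- similarityRatio(d[, i], d[, j])$similarity_ratio
        expect_equal(S[i, j], ref)
        expect_equal(S[j, i], ref)
    }
    expect_equal(unname(diag(S)), rep(1, 10))
    expect_equal(sm$mean, mean(S[upper.tri(S)]))
    # permuting line order permutes but does not change pair values
    perm <- sample(lineIds(gp))
    gp2 <- GenotypePanel(dosage(gp)[, perm], snpMap(gp), perm)
    S2 <- similarityMatrix(gp2)$similarity
    expect_equal(S2[rownames(S), colnames(S)], S)
    # a panel of identical lines is all ones
    gp3 <- makePanel(matrix(rep(c(0L, 2L), 15), 10, 3))
    expect_equal(similarityMatrix(gp3)$mean, 1)
})

test_that("most similar lines rank descending with lexicographic ties", {
    S <- matrix(c(1, 0.9, 0.8, 0.8,
                  0.9, 1, 0.2, 0.3,
                  0.8, 0.2, 1, 0.4,
                  0.8, 0.3, 0.4, 1), 4,
                dimnames = list(c("F", "Lb", "La", "Lc"),
                                c("F", "Lb", "La", "Lc")))
    top <- mostSimilarLines(S, "F", k = 3)
    expect_equal(top$line_id, c("Lb", "La", "Lc"))  # tie 0.8 -> La first
    expect_equal(nrow(mostSimilarLines(S, "F", k = 99)), 3L)
    set.seed(52)
    s <- runif(200)
    names(s) <- sprintf("L%03d", sample(200))
    S2 <- diag(201)
    rownames(S2) <- colnames(S2) <- c("focal", names(s))
    S2["focal", names(s)] <- s
    S2[names(s), "focal"] <- s
    got <- mostSimilarLines(S2, "focal", k = 30)
    ref <- names(sort(-s))[1:30]   # no exact ties among runif draws
    expect_equal(got$line_id, ref)
})

test_that("binned similarity agrees with whole-genome and brute force", {
    set.seed(53)
    gp <- randomPanel(150, 6, pMissing = 0.05,
                      pos = sort(sample.int(3e7, 150)))
    ids <- lineIds(gp)
    bs <- binnedSimilarity(gp, ids[1], ids[2:4], binSpec(1e7, 1L))
    d <- dosage(gp)
    map <- snpMap(gp)
    for (r in seq_len(nrow(bs$bins))) {
        inBin <- (map$position_bp - 1) >= bs$bins$bin_start_bp[r] &
            (map$position_bp - 1) < bs$bins$bin_end_bp[r]
        for (ln in ids[2:4]) {
            ref <- similarityRatio(d[inBin, ids[1]],
                                   d[inBin, ln])$similarity_ratio
            expect_equal(bs$bins[[ln]][r], ref)
        }
    }
    # one giant bin reproduces the whole-genome ratio
    one <- binnedSimilarity(gp, ids[1], ids[2], binSpec(1e9, 1L))
    expect_equal(one$bins[[ids[2]]][1],
                 similarityRatio(d[, ids[1]], d[, ids[2]])$similarity_ratio)
    # subset = focal itself: all defined cells 1.0
    self <- binnedSimilarity(gp, ids[1], ids[1], binSpec(1e7, 1L))
    expect_true(all(self$bins[[ids[1]]] == 1, na.rm = TRUE))
})

test_that("conserved regions are maximal runs of adjacent high bins", {
    bins <- data.frame(chromosome = "1",
                       bin_start_bp = c(0, 1, 2, 3) * 1e7,
                       bin_end_bp = c(1, 2, 3, 4) * 1e7,
                       n_snps = 40L, flag = "none",
                       subset_mean = c(0.9, 0.88, 0.7, 0.86))
    cr <- conservedRegions(list(bins = bins))
    expect_equal(nrow(cr), 2L)
    expect_equal(cr$start_bp, c(0, 3e7))
    expect_equal(cr$n_bins, c(2L, 1L))
    bins$subset_mean <- c(0.85, 0.2, 0.3, 0.84)  # 0.85 is not > 0.85
    expect_equal(nrow(conservedRegions(list(bins = bins))), 0L)
    # a dropped bin breaks a run
    bins$subset_mean <- c(0.9, 0.9, 0.9, 0.9)
    bins$flag <- c("none", "dropped", "none", "none")
    cr2 <- conservedRegions(list(bins = bins))
    expect_equal(cr2$n_bins, c(1L, 2L))
})

test_that("founder-derived segments are recovered near their true bounds", {
    reps <- lapply(1:5, function(s) {
        cfg <- simulationConfig(
            seed = 500 + s, nChromosomes = 3, chromosomeLengthBp = 1e8,
            nSnps = 2400,
            groups = list(list(label = "G", nLines = 60, fst = 0.15,
                               ldLambdaBp = 2e5)),
            founderSegments = list(list(group = "G", chromosome = "2",
                                        startBp = 3e7, endBp = 8e7,
                                        nDerived = 20L,
                                        retention = 0.95)),
            mafFloor = 0.05)
        sim <- simulatePanel(cfg)
        seg <- sim$truth$segments[[1]]
        bs <- binnedSimilarity(sim$panel, seg$founder, seg$derived,
                               binSpec(1e7, 10L))
        cr <- conservedRegions(bs, threshold = 0.85)
        cr <- cr[cr$chromosome == "2", , drop = FALSE]
        main <- cr[which.max(cr$n_bins), ]
        c(start = main$start_bp, end = main$end_bp)
    })
    for (r in reps) {
        expect_lte(abs(r[["start"]] - 3e7), 1e7)   # within one bin
        expect_lte(abs(r[["end"]] - 8e7), 1e7)
    }
})

test_that("VanRaden kinship matches the closed form and brute force", {
    gp <- makePanel(matrix(c(2L, 0L), 1))
    K <- vanRadenKinship(gp)
    expect_equal(unname(K), matrix(c(2, -2, -2, 2), 2))
    set.seed(54)
    gp2 <- randomPanel(50, 20, pMissing = 0.06)
    K2 <- vanRadenKinship(gp2)
    d <- dosage(gp2)
    called <- !is.na(d)
    p <- rowSums(d, na.rm = TRUE) / (2 * rowSums(called))
    poly <- p > 0 & p < 1
    denom <- 2 * sum(p[poly] * (1 - p[poly]))
    for (i in 1:20) for (j in i:20) {
        zi <- ifelse(is.na(d[poly, i]), 0, d[poly, i] - 2 * p[poly])
        zj <- ifelse(is.na(d[poly, j]), 0, d[poly, j] - 2 * p[poly])
        expect_equal(K2[i, j], sum(zi * zj) / denom)
    }
    expect_equal(K2, t(K2))
    # SNP order is irrelevant
    perm <- sample(nrow(d))
    gp3 <- GenotypePanel(d[perm, ], snpMap(gp2)[perm, ], lineIds(gp2))
    expect_equal(vanRadenKinship(gp3), K2)
    # duplicated lines coincide and attain the maximal off-diagonal
    dupIds <- c(lineIds(gp2), "dup")
    gp4 <- GenotypePanel(cbind(d, d[, 1]), snpMap(gp2), dupIds)
    K4 <- vanRadenKinship(gp4)
    expect_equal(unname(K4["dup", 1]), unname(K4[1, 1]))
    expect_equal(unname(which.max(K4["dup", -21])), 1L)
    expect_error(vanRadenKinship(makePanel(matrix(0L, 2, 3))),
                 "monomorphic")
})

test_that("kinship distribution clips, tallies and conserves counts", {
    K <- matrix(c(1, -0.2, 0.3, -0.2, 1, -0.1, 0.3, -0.1, 1), 3)
    kd <- kinshipDistribution(K)
    expect_equal(kd$fraction_zero, 2 / 3)
    expect_equal(sum(kd$histogram$count), 3L)
    kdRaw <- kinshipDistribution(K, clipNegative = FALSE)
    expect_equal(sort(kdRaw$values), c(-0.2, -0.1, 0.3))
    allNeg <- matrix(c(1, -0.5, -0.5, 1), 2)
    expect_equal(kinshipDistribution(allNeg)$fraction_zero, 1)
})
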