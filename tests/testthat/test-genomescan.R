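test_that("windows tile the chromosome and partition the SNPs", {
    ge <- randomFourGroupGe(2000, seed = 5)
    # positions are 100, 200, ..., 200000; force a known chrom length
    w <- windowedFd(ge, "P1", "P2", "P3", "O", w = 10000L, minSnps = 1L,
                    chromLengths = c(chr1 = 1000000L))
    expect_equal(nrow(w), 100L)
    expect_true(all(w$end - w$start == 10000L))
    f <- derivedFrequencies(ge, "P1", "P2", "P3", "O")
    expect_equal(sum(w$nSnps), nrow(f))
    # each SNP in exactly one window
    expect_true(all(w$start %% 10000L == 0))
})

test_that("a window with p2 = p3 throughout and ABBA excess has fd = 1", {
    # P2 individuals duplicate P3: p2 == p3 at every site
    set.seed(8)
    p <- runif(200, 0.5, 1)
    d <- sapply(1:4, function(j) rbinom(200, 2L, p))
    p1 <- matrix(0L, 200, 4)
    og <- matrix(0L, 200, 4)
    ge <- geFromDosage(cbind(p1, d, d, og),
                       groups = rep(c("P1", "P2", "P3", "O"), each = 4))
    w <- windowedFd(ge, "P1", "P2", "P3", "O", w = 100000L, minSnps = 1L)
    expect_equal(w$fd, 1, tolerance = 1e-12)
})

test_that("outlier calling follows the inclusive-tie quantile rule", {
    win <- data.frame(chrom = "chr1", start = (0:9999) * 10000,
                      end = (1:10000) * 10000, nSnps = 50,
                      fd = seq(0, 1, length.out = 10000))
    out <- callOutliers(win, q = 0.999)
    expect_equal(nrow(out), 10L)        # distinct values: exactly 10
    winEq <- within(win, fd <- 0.5)
    expect_equal(nrow(callOutliers(winEq, q = 0.999)), 10000L)  # all tied
    expect_error(callOutliers(win, q = 1.5), "q must be")
})

test_that("gene-proximity annotation respects the 10-kb expansion", {
    win <- data.frame(chrom = "chr1", start = c(0, 50000, 990000),
                      end = c(10000, 60000, 1000000), nSnps = 50,
                      fd = c(0.1, 0.9, 0.9))
    out <- callOutliers(win, q = 0.5,
                        geneInterval = list(chrom = "chr1",
                                            start = 45001, end = 48000))
    expect_true(out$withinProximity[out$start == 50000])   # within 10 kb
    expect_false(out$withinProximity[out$start == 990000])
})

test_that("diagnostic-site filter applies tau and missingness caps", {
    # 3 donor homAlt vs 3 background homRef -> diagnostic, allele = alt
    ge <- geFromDosage(rbind(c(2L, 2L, 2L, 0L, 0L, 0L)),
                       groups = rep(c("A", "B"), each = 3))
    ds <- diagnosticSites(ge, "A", "B", tauA = 0.9, tauB = 0.9,
                          missA = 0, missB = 0)
    expect_equal(nrow(ds), 1L)
    expect_equal(ds$donorAllele, "alt")
    # donor frequency 5/6 < 0.9 -> excluded
    ge2 <- geFromDosage(rbind(c(2L, 2L, 1L, 0L, 0L, 0L)),
                        groups = rep(c("A", "B"), each = 3))
    expect_equal(nrow(diagnosticSites(ge2, "A", "B", 0.9, 0.9, 0, 0)), 0L)
    # 2/10 donor individuals missing (20%) vs a <10% cap -> excluded
    gt3 <- rbind(c(rep(2L, 8), NA, NA, rep(0L, 10)))
    ge3 <- geFromDosage(gt3, groups = rep(c("A", "B"), each = 10))
    expect_equal(nrow(diagnosticSites(ge3, "A", "B", 0.9, 0.9,
                                      missA = 0.09, missB = 0.09)), 0L)
    expect_equal(nrow(diagnosticSites(ge3, "A", "B", 0.9, 0.9,
                                      missA = 0.4, missB = 0.3)), 1L)
})

test_that("diagnostic sites are symmetric in the group labels", {
    ge <- randomFourGroupGe(500, seed = 12, missRate = 0.1)
    ab <- diagnosticSites(ge, "P3", "P1", 0.9, 0.9, 0.3, 0.3)
    ba <- diagnosticSites(ge, "P1", "P3", 0.9, 0.9, 0.3, 0.3)
    expect_equal(ab$pos, ba$pos)
    expect_equal(ab$donorAllele, ifelse(ba$donorAllele == "alt",
                                        "ref", "alt"))
})

test_that("raising tau never adds diagnostic sites", {
    for (s in 1:3) {
        ge <- randomFourGroupGe(400, seed = s, missRate = 0.1)
        n90 <- nrow(diagnosticSites(ge, "P3", "P1", 0.9, 0.9, 0.3, 0.3))
        n100 <- nrow(diagnosticSites(ge, "P3", "P1", 1, 1, 0.3, 0.3))
        expect_lte(n100, n90)
    }
})

test_that("block calling honours run and gap-tolerance rules", {
    # recipient states: donorHom, donorHom, backgroundHom, donorHom
    gt <- cbind(A = c(2L, 2L, 2L, 2L), B = c(0L, 0L, 0L, 0L),
                rec = c(2L, 2L, 0L, 2L))
    ge <- geFromDosage(gt, groups = c("A", "B", "R"),
                       pos = c(100L, 200L, 300L, 400L))
    ds <- diagnosticSites(ge, "A", "B", 1, 1, 0, 0)
    expect_equal(nrow(ds), 4L)
    res0 <- paintAndCallBlocks(ds, ge, "rec", gapTolerance = 0L)
    expect_equal(length(res0$blocks), 2L)
    expect_equal(GenomicRanges::start(res0$blocks), c(100L, 400L))
    expect_equal(GenomicRanges::end(res0$blocks), c(200L, 400L))
    res1 <- paintAndCallBlocks(ds, ge, "rec", gapTolerance = 1L)
    expect_equal(length(res1$blocks), 1L)
    expect_equal(GenomicRanges::start(res1$blocks), 100L)
    expect_equal(GenomicRanges::end(res1$blocks), 400L)
    # donor fraction: 6 donor alleles of 8 called in the merged block
    expect_equal(res1$blocks$donorFraction, 6 / 8)
})

test_that("species-level painting is a majority vote with het ties", {
    gt <- cbind(A = 2L, B = 0L, r1 = 2L, r2 = 2L, r3 = 0L)
    ge <- geFromDosage(gt, groups = c("A", "B", "R", "R", "R"))
    ds <- diagnosticSites(ge, "A", "B", 1, 1, 0, 0)
    p <- paintAndCallBlocks(ds, ge, "R")$painting
    expect_equal(unname(p[1, "R"]), "donorHom")
    gt2 <- cbind(A = 2L, B = 0L, r1 = 2L, r2 = 0L)
    ge2 <- geFromDosage(gt2, groups = c("A", "B", "R", "R"))
    ds2 <- diagnosticSites(ge2, "A", "B", 1, 1, 0, 0)
    p2 <- paintAndCallBlocks(ds2, ge2, "R")$painting
    expect_equal(unname(p2[1, "R"]), "het")   # tie -> het
})

test_that("shared core is the interval intersection", {
    b <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(100L, 150L, 140L),
                                                 c(300L, 280L, 208L)))
    core <- sharedCore(b)
    expect_equal(GenomicRanges::start(core), 150L)
    expect_equal(GenomicRanges::end(core), 208L)
    disj <- GenomicRanges::GRanges("chr1",
                                   IRanges::IRanges(c(100L, 500L),
                                                    c(200L, 600L)))
    expect_length(sharedCore(disj), 0L)
    diffChr <- GenomicRanges::GRanges(c("chr1", "chr2"),
                                      IRanges::IRanges(c(1L, 1L), c(10L, 10L)))
    expect_error(sharedCore(diffChr), "different chromosomes")
})

test_that("blocks are covered by diagnostic sites and contain the core", {
    sim <- noiselessTractSim(list(Rec1 = c(400001L, 460000L),
                                  Rec2 = c(410001L, 450000L)), seed = 21)
    ds <- diagnosticSites(sim$genotypes, "Donor", "Bg", 1, 1, 0, 0)
    res <- paintAndCallBlocks(ds, sim$genotypes, c("Rec1_1", "Rec2_1"))
    expect_gte(length(res$blocks), 2L)
    for (i in seq_along(res$blocks)) {
        b <- res$blocks[i]
        inside <- ds$pos >= GenomicRanges::start(b) &
            ds$pos <= GenomicRanges::end(b)
        expect_equal(min(ds$pos[inside]), GenomicRanges::start(b))
        expect_equal(max(ds$pos[inside]), GenomicRanges::end(b))
    }
    core <- sharedCore(res$blocks)
    for (i in seq_along(res$blocks)) {
        expect_gte(GenomicRanges::start(core),
                   GenomicRanges::start(res$blocks[i]))
        expect_lte(GenomicRanges::end(core),
                   GenomicRanges::end(res$blocks[i]))
    }
})
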