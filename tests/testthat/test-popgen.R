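test_that("derived-allele frequencies follow the counting rules", {
    # outgroup all homRef -> derived is ALT; {het, missing} -> p = 0.5
    gt <- rbind(c(1L, NA, 2L, 2L, 1L, 0L, 0L))
    ge <- geFromDosage(gt, groups = c("P1", "P1", "P2", "P2", "P3", "O", "O"))
    f <- derivedFrequencies(ge, "P1", "P2", "P3", "O")
    expect_equal(f$p1, 0.5)
    expect_equal(f$p2, 1)
    expect_equal(f$derived, "alt")
    # group of 3 diploids {homAlt, homAlt, het} -> 5/6
    gt2 <- rbind(c(2L, 2L, 1L, 0L, 0L, 0L, 0L))
    ge2 <- geFromDosage(gt2, groups = c("P2", "P2", "P2", "P1", "P3", "O", "O"))
    f2 <- derivedFrequencies(ge2, "P1", "P2", "P3", "O")
    expect_equal(f2$p2, 5 / 6)
    # outgroup at exactly 0.5 -> ALT by tie-break
    gt3 <- rbind(c(0L, 2L, 2L, 1L, 1L))
    ge3 <- geFromDosage(gt3, groups = c("P1", "P2", "P3", "O", "O"))
    f3 <- derivedFrequencies(ge3, "P1", "P2", "P3", "O")
    expect_equal(f3$derived, "alt")
    expect_equal(f3$p4, 0.5)
})

test_that("sites with an uncalled group are excluded and counted", {
    gt <- rbind(c(1L, 1L, 0L, 0L),
                c(NA, 1L, 2L, 0L))
    ge <- geFromDosage(gt, groups = c("P1", "P2", "P3", "O"))
    f <- derivedFrequencies(ge, "P1", "P2", "P3", "O")
    expect_equal(nrow(f), 1L)
    expect_equal(attr(f, "nExcluded"), 1L)
})

test_that("overlapping four-taxon groups are rejected", {
    ge <- randomFourGroupGe(10, seed = 1)
    expect_error(derivedFrequencies(ge, "P1", "P1", "P3", "O"), "disjoint")
})

test_that("D matches its worked values", {
    expect_equal(dStatistic(data.frame(p1 = 0, p2 = 1, p3 = 1, p4 = 0))$D, 1)
    d <- dStatistic(data.frame(p1 = 0.2, p2 = 0.8, p3 = 0.6, p4 = 0))
    expect_equal(d$sumAbba, 0.384)
    expect_equal(d$sumBaba, 0.024)
    expect_equal(d$D, 0.36 / 0.408, tolerance = 1e-12)
    # p1 = p2 everywhere -> numerator cancels term-wise
    set.seed(1)
    p <- runif(50)
    eq <- data.frame(p1 = p, p2 = p, p3 = runif(50), p4 = runif(50) / 4)
    expect_equal(dStatistic(eq)$D, 0, tolerance = 1e-14)
    # all-zero weights -> undefined, not a crash
    expect_true(is.na(dStatistic(data.frame(p1 = 0, p2 = 0, p3 = 0,
                                            p4 = 0))$D))
})

test_that("swapping P1 and P2 negates D exactly", {
    for (s in 1:5) {
        set.seed(s)
        f <- data.frame(p1 = runif(40), p2 = runif(40), p3 = runif(40),
                        p4 = runif(40) / 3)
        sw <- data.frame(p1 = f$p2, p2 = f$p1, p3 = f$p3, p4 = f$p4)
        expect_equal(dStatistic(sw)$D, -dStatistic(f)$D, tolerance = 1e-14)
    }
})

test_that("f_d matches its worked values and conventions", {
    fd <- fdValue(data.frame(p1 = 0.2, p2 = 0.8, p3 = 0.6, p4 = 0))
    expect_equal(fd$denominator, 0.48, tolerance = 1e-12)
    expect_equal(fd$fd, 0.75, tolerance = 1e-12)
    # p2 = p3 with positive numerator -> fd = 1
    set.seed(2)
    p <- runif(30) * 0.5 + 0.4
    f <- data.frame(p1 = runif(30) * 0.2, p2 = p, p3 = p, p4 = 0)
    expect_equal(fdValue(f)$fd, 1, tolerance = 1e-12)
    # non-positive numerator -> 0
    f2 <- data.frame(p1 = 0.8, p2 = 0.2, p3 = 0.6, p4 = 0)
    expect_equal(fdValue(f2)$fd, 0)
})

test_that("streaming statistics equal the brute-force oracle", {
    for (s in 1:20) {
        ge <- randomFourGroupGe(nSites = sample(20:100, 1),
                                nPerGroup = sample(2:8, 1),
                                missRate = 0.1, seed = s)
        oracle <- bruteFourTaxonStats(ge)
        f <- derivedFrequencies(ge, "P1", "P2", "P3", "O")
        expect_equal(dStatistic(f)$D, oracle$D, tolerance = 1e-12)
        expect_equal(fdValue(f)$fd, oracle$fd, tolerance = 1e-12)
        expect_equal(f4Sum(f$p1, f$p2, f$p3, f$p4), oracle$f4,
                     tolerance = 1e-12)
    }
})

test_that("single-site f4 component is the direct product", {
    expect_equal(f4Sum(0.9, 0.1, 0.7, 0.2), 0.8 * 0.5, tolerance = 1e-14)
})

test_that("f4-ratio is ~1 in the full-admixture limit (P2 drawn from P3)", {
    cfg <- simConfig(fourTaxonTree(), nIndividualsPerSpecies = 4L,
                     chromLength = 1000000L, nSites = 20000L,
                     introgressionEvents = list(
                         list(donor = "P3", recipient = "P2", start = 1L,
                              end = 1000000L, rho = 1, mode = "fixed")),
                     outgroupSpecies = "O")
    ge <- simulateGenotypes(cfg, seed = 6)$genotypes
    a <- f4Ratio(ge, "P1", "P2", "P3", "O", seed = 8)
    expect_equal(a$alpha, 1, tolerance = 0.05)
})

test_that("block jackknife matches the closed-form toy computation", {
    # 4 informative sites, 2 blocks of 2; leave-one-out by hand
    f <- data.frame(p1 = c(0.1, 0.2, 0.0, 0.3),
                    p2 = c(0.9, 0.7, 0.8, 0.5),
                    p3 = c(0.8, 0.6, 0.9, 0.9),
                    p4 = c(0.0, 0.1, 0.0, 0.2))
    abba <- (1 - f$p1) * f$p2 * f$p3 * (1 - f$p4)
    baba <- f$p1 * (1 - f$p2) * f$p3 * (1 - f$p4)
    d <- sum(abba - baba) / sum(abba + baba)
    loo1 <- sum((abba - baba)[3:4]) / sum((abba + baba)[3:4])
    loo2 <- sum((abba - baba)[1:2]) / sum((abba + baba)[1:2])
    seHand <- sqrt(1 / 2 * ((loo1 - mean(c(loo1, loo2)))^2 +
                            (loo2 - mean(c(loo1, loo2)))^2))
    # drive the jackknife through genotypes of 10 diploids per group
    # whose per-site allele counts reproduce those frequencies exactly
    dosages <- function(p) t(sapply(as.integer(round(p * 20)), function(k) {
        v <- integer(10)
        v[seq_len(k %/% 2)] <- 2L
        if (k %% 2 == 1L) v[k %/% 2 + 1L] <- 1L
        v
    }))
    gt <- cbind(dosages(f$p1), dosages(f$p2), dosages(f$p3), dosages(f$p4))
    ge <- geFromDosage(gt, groups = rep(c("P1", "P2", "P3", "O"), each = 10))
    jk <- blockJackknife(ge, "P1", "P2", "P3", "O", "D", nBlocks = 2L)
    expect_equal(jk$value, d, tolerance = 1e-12)
    expect_equal(jk$se, seHand, tolerance = 1e-12)
    expect_equal(jk$z, d / seHand, tolerance = 1e-12)
})

test_that("identical blocks give SE = 0 and an undefined Z", {
    gt <- do.call(rbind, rep(list(c(0L, 0L, 2L, 2L, 2L, 2L, 0L, 0L)), 8))
    ge <- geFromDosage(gt, groups = rep(c("P1", "P2", "P3", "O"), each = 2))
    jk <- blockJackknife(ge, "P1", "P2", "P3", "O", "D", nBlocks = 4L)
    expect_equal(jk$se, 0)
    expect_true(is.na(jk$z))
})

test_that("too few informative sites for the block count errors", {
    ge <- randomFourGroupGe(50, seed = 3)
    expect_error(blockJackknife(ge, "P1", "P2", "P3", "O", "D",
                                nBlocks = 200L), "nBlocks")
})
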