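# fixtures are built in code; no data files

# GenotypeExperiment from a dosage matrix (sites x individuals)
geFromDosage <- function(gt, groups, pos = seq_len(nrow(gt)) * 100L,
                         chrom = "chr1",
                         ref = rep("A", nrow(gt)),
                         alt = rep("G", nrow(gt)),
                         ids = NULL) {
    if (is.null(ids))
        ids <- if (!is.null(colnames(gt))) colnames(gt)
               else paste0("ind", seq_len(ncol(gt)))
    gt <- matrix(as.integer(gt), nrow(gt), ncol(gt))
    colnames(gt) <- ids
    GenotypeExperiment(chrom = rep(chrom, nrow(gt)), pos = pos,
                       ref = ref, alt = alt, gt = gt, groups = groups)
}

# random genotype matrix with four groups and some missingness
randomFourGroupGe <- function(nSites, nPerGroup = 4L, missRate = 0.05,
                              seed = 1L) {
    set.seed(seed)
    groups <- rep(c("P1", "P2", "P3", "O"), each = nPerGroup)
    nInd <- length(groups)
    p <- matrix(runif(nSites * 4L), nSites, 4L,
                dimnames = list(NULL, c("P1", "P2", "P3", "O")))
    gt <- matrix(NA_integer_, nSites, nInd)
    for (j in seq_len(nInd))
        gt[, j] <- rbinom(nSites, 2L, p[, groups[j]])
    gt[matrix(runif(length(gt)) < missRate, nSites, nInd)] <- NA_integer_
    geFromDosage(gt, groups)
}

# independent brute-force oracle: per-site loops over individuals,
# counting alleles directly from the dosage matrix
bruteFourTaxonStats <- function(ge) {
    gt <- genotypeCalls(ge)
    sg <- as.character(sampleGroups(ge))
    labs <- c("P1", "P2", "P3", "O")
    sumA <- sumB <- sumDA <- sumDB <- f4 <- 0
    p1v <- p2v <- p3v <- p4v <- numeric(0)
    for (s in seq_len(nrow(gt))) {
        p <- numeric(4); ok <- TRUE
        for (g in seq_along(labs)) {
            der <- 0; tot <- 0
            for (j in which(sg == labs[g])) {
                d <- gt[s, j]
                if (!is.na(d)) { der <- der + d; tot <- tot + 2 }
            }
            if (tot == 0) { ok <- FALSE; break }
            p[g] <- der / tot
        }
        if (!ok) next
        if (p[4] > 0.5) p <- 1 - p    # polarize: outgroup minor, tie -> ALT
        abba <- (1 - p[1]) * p[2] * p[3] * (1 - p[4])
        baba <- p[1] * (1 - p[2]) * p[3] * (1 - p[4])
        pd <- max(p[2], p[3])
        sumA <- sumA + abba; sumB <- sumB + baba
        sumDA <- sumDA + (1 - p[1]) * pd * pd * (1 - p[4])
        sumDB <- sumDB + p[1] * (1 - pd) * pd * (1 - p[4])
        f4 <- f4 + (p[1] - p[2]) * (p[3] - p[4])
        p1v <- c(p1v, p[1]); p2v <- c(p2v, p[2])
        p3v <- c(p3v, p[3]); p4v <- c(p4v, p[4])
    }
    num <- sumA - sumB
    den <- sumDA - sumDB
    list(D = if (sumA + sumB > 0) num / (sumA + sumB) else NA_real_,
         fd = if (num <= 0) 0 else num / den,
         f4 = f4,
         freqs = data.frame(p1 = p1v, p2 = p2v, p3 = p3v, p4 = p4v))
}

# noiseless localization scenario: recipients are zero-length-branch
# sisters of the background species, so outside planted tracts they are
# genetically identical to it; large drift fixes donor/background
# differences
noiselessTractSim <- function(tracts, seed = 7L, nSites = 4000L,
                              chromLength = 1000000L) {
    tree <- ape::read.tree(
        text = "((Rec1:0,Rec2:0,Bg:0):3,Donor:3,Out:6);")
    events <- lapply(names(tracts), function(rec)
        list(donor = "Donor", recipient = rec,
             start = tracts[[rec]][1], end = tracts[[rec]][2],
             rho = 1, mode = "fixed"))
    cfg <- simConfig(tree, nIndividualsPerSpecies = 2L,
                     chromLength = chromLength, nSites = nSites,
                     driftScale = 1.0, introgressionEvents = events,
                     outgroupSpecies = "Out", quantizeTips = TRUE)
    simulateGenotypes(cfg, seed = seed)
}
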