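#' @importFrom stats rbeta rnorm rbinom runif rpois quantile rhyper setNames
#' @importFrom ape read.tree write.tree
NULL

#' Build a simulation configuration
#'
#' Validating constructor for [SimConfig-class].  The generative model:
#' site positions uniform without replacement on `[1, chromLength]`;
#' per-site ancestral ALT frequency from `Beta(rootFreqBeta)`; the
#' frequency evolves along each species-tree branch by a Gaussian
#' increment with variance `driftScale * branchLength`, clamped to
#' `[0, 1]` (so long inter-generic branches accumulate near-fixed
#' differences); diploid genotypes are binomial draws from the tip
#' frequency.  Introgression events replace the recipient's tip
#' frequency with the donor's at each tract site independently with
#' probability `rho` (`mode = "fixed"`), or thread a single donor
#' haplotype through named carrier individuals (`mode = "polymorphic"`).
#'
#' @param speciesTree ape `phylo` with branch lengths (drift-time units).
#' @param nIndividualsPerSpecies diploid individuals per species.
#' @param chromLength chromosome length in bp.
#' @param nSites number of SNP sites.
#' @param driftScale per-unit-branch-length variance of frequency change.
#' @param rootFreqBeta two Beta shape parameters for the root frequency.
#' @param introgressionEvents list of event lists; see [SimConfig-class].
#' @param outgroupSpecies tip label used as outgroup.
#' @param chromName chromosome name in the output.
#' @param quantizeTips round tip frequencies to 0/1 after drift (before
#'   events): a noiseless limit in which every lineage is fully sorted,
#'   so fixed differences and planted tracts are exact.  Default FALSE.
#' @return A validated [SimConfig-class].
#' @export
simConfig <- function(speciesTree,
                      nIndividualsPerSpecies = 4L,
                      chromLength = 1000000L,
                      nSites = 20000L,
                      driftScale = 0.08,
                      rootFreqBeta = c(0.8, 0.8),
                      introgressionEvents = list(),
                      outgroupSpecies,
                      chromName = "chr1",
                      quantizeTips = FALSE) {
    new("SimConfig",
        speciesTree = speciesTree,
        nIndividualsPerSpecies = as.integer(nIndividualsPerSpecies),
        chromLength = as.integer(chromLength),
        nSites = as.integer(nSites),
        driftScale = as.numeric(driftScale),
        rootFreqBeta = as.numeric(rootFreqBeta),
        introgressionEvents = introgressionEvents,
        outgroupSpecies = as.character(outgroupSpecies),
        chromName = chromName,
        quantizeTips = isTRUE(quantizeTips))
}

#' Default four-taxon study tree
#'
#' A pectinate (((P1,P2),P3),O) species tree with intra-clade branches of
#' length 1 and progressively longer inter-clade branches, mimicking two
#' closely related ingroup species, a diverged donor genus, and a deep
#' outgroup.
#'
#' @param tipLabels four tip labels, innermost pair first.
#' @return ape `phylo`.
#' @export
fourTaxonTree <- function(tipLabels = c("P1", "P2", "P3", "O")) {
    txt <- sprintf("(((%s:1,%s:1):2,%s:3):4,%s:7);",
                   tipLabels[1], tipLabels[2], tipLabels[3], tipLabels[4])
    read.tree(text = txt)
}

# Evolve per-site ALT frequencies down the tree by clamped Gaussian drift.
# Returns sites x tips matrix of tip frequencies.
.driftTipFrequencies <- function(tree, p0, driftScale) {
    nTip <- length(tree$tip.label)
    nNode <- nTip + tree$Nnode
    freq <- matrix(NA_real_, length(p0), nNode)
    rootNode <- nTip + 1L
    freq[, rootNode] <- p0
    # preorder edge traversal: ape trees store edges parent-before-child
    # after reorder()
    tree <- stats::reorder(tree)
    for (i in seq_len(nrow(tree$edge))) {
        par <- tree$edge[i, 1L]; child <- tree$edge[i, 2L]
        bl <- tree$edge.length[i]
        step <- if (driftScale > 0 && bl > 0)
            rnorm(length(p0), 0, sqrt(driftScale * bl)) else 0
        freq[, child] <- pmin(1, pmax(0, freq[, par] + step))
    }
    tips <- freq[, seq_len(nTip), drop = FALSE]
    colnames(tips) <- tree$tip.label
    tips
}

#' Simulate multi-species genotypes with planted introgression tracts
#'
#' Runs the generative model described in [simConfig()] and returns the
#' genotypes together with a truth set for recovery tests.  Identical
#' `(config, seed)` give identical output.
#'
#' @param config A [SimConfig-class].
#' @param seed integer seed.
#' @return list with elements `genotypes` (a
#'   [GenotypeExperiment-class]; individuals named `<species>_<i>` and
#'   grouped by species), `truth` (list: `tracts`, a `GRanges` of planted
#'   tracts with donor/recipient/rho/mode metadata; `tipFrequencies`,
#'   the post-event sites x species frequency matrix; `events`, the
#'   configured event list) and `popmap` (data.frame individual/group).
#' @export
simulateGenotypes <- function(config, seed = 1L) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    set.seed(as.integer(seed))
    tr <- config@speciesTree
    nS <- config@nSites
    pos <- sort(sample.int(config@chromLength, nS))
    p0 <- rbeta(nS, config@rootFreqBeta[1], config@rootFreqBeta[2])
    tipF <- .driftTipFrequencies(tr, p0, config@driftScale)
    if (config@quantizeTips) tipF <- round(tipF)
    preF <- tipF
    polyEvents <- list()
    for (ev in config@introgressionEvents) {
        inTract <- which(pos >= ev$start & pos <= ev$end)
        sel <- inTract[runif(length(inTract)) < ev$rho]
        if (ev$mode == "fixed") {
            tipF[sel, ev$recipient] <- tipF[sel, ev$donor]
        } else {
            polyEvents[[length(polyEvents) + 1L]] <-
                list(ev = ev, sites = sel)
        }
    }
    species <- tr$tip.label
    k <- config@nIndividualsPerSpecies
    ids <- as.vector(t(outer(species, seq_len(k), paste, sep = "_")))
    groups <- rep(species, each = k)
    gt <- matrix(NA_integer_, nS, length(ids), dimnames = list(NULL, ids))
    for (j in seq_along(ids))
        gt[, j] <- rbinom(nS, 2L, tipF[, groups[j]])
    # polymorphic events: one donor haplotype threaded through carriers
    for (pe in polyEvents) {
        ev <- pe$ev; sel <- pe$sites
        if (!length(sel)) next
        hap <- rbinom(length(sel), 1L, tipF[sel, ev$donor])
        for (ind in names(ev$carriers)) {
            cc <- ev$carriers[[ind]]
            bg <- rbinom(length(sel), 2L - cc, preF[sel, ev$recipient])
            gt[sel, ind] <- cc * hap + bg
        }
    }
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nS, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    ge <- GenotypeExperiment(chrom = config@chromName, pos = pos,
                             ref = ref, alt = alt, gt = gt, groups = groups)
    evs <- config@introgressionEvents
    tracts <- if (length(evs)) {
        GRanges(config@chromName,
                IRanges(vapply(evs, `[[`, numeric(1), "start"),
                        vapply(evs, `[[`, numeric(1), "end")),
                donor = vapply(evs, `[[`, character(1), "donor"),
                recipient = vapply(evs, `[[`, character(1), "recipient"),
                rho = vapply(evs, `[[`, numeric(1), "rho"),
                mode = vapply(evs, `[[`, character(1), "mode"))
    } else GRanges()
    list(genotypes = ge,
         truth = list(tracts = tracts, tipFrequencies = tipF,
                      preEventFrequencies = preF, events = evs,
                      speciesTree = tr),
         popmap = data.frame(individual = ids, group = groups))
}

# clade node set (internal nodes + tips) below `node`, inclusive
.descendantNodes <- function(tree, node) {
    out <- node
    stack <- node
    while (length(stack)) {
        cur <- stack[[1]]; stack <- stack[-1]
        kids <- tree$edge[tree$edge[, 1] == cur, 2]
        out <- c(out, kids)
        stack <- c(stack, kids[kids > length(tree$tip.label)])
    }
    out
}

#' Simulate gene trees with displaced recipient taxa
#'
#' Non-displaced loci return the species-tree topology with lognormal
#' branch-length jitter.  For each displacement event (applied to every
#' locus) the recipient tips are pruned and re-grafted onto a uniformly
#' chosen edge inside the donor clade's subtree, emulating the gene-tree
#' signature of introgression: the recipient falls on the branch
#' normally occupied by the donor.
#'
#' @param speciesTree rooted ape `phylo` with branch lengths.
#' @param displacementEvents list of lists with `donorClade` (character
#'   vector of tips) and `recipients` (character vector of tips); empty
#'   list for concordant loci.
#' @param nLoci number of gene trees.
#' @param seed integer seed.
#' @param jitterSd lognormal sd of branch-length jitter.
#' @return list of `phylo` gene trees.
#' @export
simulateGeneTrees <- function(speciesTree, displacementEvents = list(),
                              nLoci = 1L, seed = 1L, jitterSd = 0.1) {
    set.seed(as.integer(seed))
    for (ev in displacementEvents) {
        if (!all(c(ev$donorClade, ev$recipients) %in% speciesTree$tip.label))
            stop("displacement event names taxa absent from the species tree")
    }
    lapply(seq_len(nLoci), function(l) {
        g <- speciesTree
        g$edge.length <- g$edge.length * exp(rnorm(length(g$edge.length),
                                                   0, jitterSd))
        for (ev in displacementEvents) {
            for (rec in ev$recipients) {
                g <- ape::drop.tip(g, rec)
                mrca <- if (length(ev$donorClade) > 1L)
                    ape::getMRCA(g, ev$donorClade)
                else match(ev$donorClade, g$tip.label)
                cladeNodes <- .descendantNodes(g, mrca)
                edgeIdx <- which(g$edge[, 1] %in%
                                 cladeNodes[cladeNodes > length(g$tip.label)] &
                                 (g$edge[, 2] %in% cladeNodes))
                if (!length(edgeIdx))   # single-tip donor: its pendant edge
                    edgeIdx <- which(g$edge[, 2] == mrca)
                e <- if (length(edgeIdx) == 1L) edgeIdx else sample(edgeIdx, 1L)
                len <- mean(g$edge.length) * 0.5
                tipTree <- read.tree(text = sprintf("(%s:%g);", rec, len))
                g <- ape::bind.tree(g, tipTree, where = g$edge[e, 2L],
                                    position = runif(1) * g$edge.length[e])
            }
        }
        g
    })
}

#' Write a simulation to disk
#'
#' Emits the VCF, population map, truth-tract BED, species-tree Newick
#' and a JSON manifest of the configured events.
#'
#' @param sim result of [simulateGenotypes()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of written paths, invisibly.
#' @export
writeSimulation <- function(sim, dir, prefix = "sim") {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    p <- function(ext) file.path(dir, paste0(prefix, ext))
    writeGenotypeVcf(sim$genotypes, p(".vcf"))
    writePopmap(sim$popmap, p(".popmap.tsv"))
    tr <- sim$truth$tracts
    if (length(tr)) {
        bed <- tr
        mcols(bed) <- NULL
        mcols(bed)$name <- paste0(mcols(tr)$donor, ">", mcols(tr)$recipient)
        mcols(bed)$score <- round(1000 * mcols(tr)$rho)
        rtracklayer::export(bed, p(".tracts.bed"), format = "BED")
    }
    write.tree(sim$truth$speciesTree, p(".speciestree.nwk"))
    jsonlite::write_json(
        list(events = sim$truth$events,
             species = sim$truth$speciesTree$tip.label),
        p(".manifest.json"), auto_unbox = TRUE, digits = NA, force = TRUE)
    invisible(c(vcf = p(".vcf"), popmap = p(".popmap.tsv"),
                tree = p(".speciestree.nwk"), manifest = p(".manifest.json")))
}
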