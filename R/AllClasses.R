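#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges colData
NULL

#' GenotypeExperiment: biallelic diploid SNP genotypes with population labels
#'
#' A \linkS4class{RangedSummarizedExperiment} holding one assay, `"GT"`,
#' an integer matrix of per-site, per-individual ALT-allele dosages
#' (0 = homozygous REF, 1 = heterozygous, 2 = homozygous ALT, `NA` =
#' missing).  Sites live in `rowRanges()` (width-1 `GRanges` in 1-based
#' VCF coordinates) with metadata columns `ref` and `alt` (single-base
#' alleles).  Individuals are columns; `colData()$group` assigns each to
#' exactly one population/species group.
#'
#' Validity requires: sites sorted by (chromosome, position) and strictly
#' increasing within a chromosome; single-base REF/ALT differing at every
#' site; dosage values confined to \{0, 1, 2, NA\}; a non-empty `group`
#' factor with no `NA`.
#'
#' @seealso [GenotypeExperiment()] for the constructor,
#'   [readGenotypeVcf()] to build one from a VCF + population map.
#' @export
setClass("GenotypeExperiment", contains = "RangedSummarizedExperiment")

.validGenotypeExperiment <- function(object) {
    msg <- character()
    if (!"GT" %in% names(assays(object)))
        msg <- c(msg, "assay 'GT' is required")
    else {
        gt <- assay(object, "GT")
        if (!is.integer(gt) && !all(is.na(gt)))
            msg <- c(msg, "assay 'GT' must be an integer matrix")
        bad <- !(gt %in% c(0L, 1L, 2L) | is.na(gt))
        if (any(bad))
            msg <- c(msg, "genotype dosages must be 0, 1, 2 or NA")
    }
    rr <- rowRanges(object)
    if (length(rr)) {
        if (!all(c("ref", "alt") %in% names(mcols(rr))))
            msg <- c(msg, "rowRanges must carry 'ref' and 'alt' columns")
        else {
            ref <- mcols(rr)$ref; alt <- mcols(rr)$alt
            if (!all(nchar(ref) == 1L & nchar(alt) == 1L))
                msg <- c(msg, "REF and ALT must be single bases (biallelic SNPs)")
            if (any(ref == alt))
                msg <- c(msg, "REF and ALT must differ at every site")
        }
        if (any(width(rr) != 1L))
            msg <- c(msg, "sites must be width-1 ranges")
        bychr <- split(start(rr), as.character(seqnames(rr)))
        if (!all(vapply(bychr, function(p) all(diff(p) > 0), logical(1))))
            msg <- c(msg, "positions must be strictly increasing within chromosome")
    }
    if (!"group" %in% names(colData(object)))
        msg <- c(msg, "colData must carry a 'group' column")
    else if (anyNA(colData(object)$group))
        msg <- c(msg, "every individual needs a group assignment")
    if (length(msg)) msg else TRUE
}

setValidity("GenotypeExperiment", .validGenotypeExperiment)

#' Simulation configuration for synthetic multi-species genotype data
#'
#' Parameters of the truncated-Gaussian allele-frequency drift simulator
#' (see [simulateGenotypes()]).  `speciesTree` is an ape `phylo` with
#' branch lengths in drift-time units; `introgressionEvents` is a list of
#' lists with elements `donor`, `recipient`, `start`, `end` (1-based bp,
#' inclusive), `rho` (per-site retention probability in `[0,1]`),
#' `mode` (`"fixed"` or `"polymorphic"`), and for polymorphic mode
#' `carriers`, a named integer vector of donor-allele copy numbers
#' (0/1/2) per recipient individual.
#'
#' @seealso [simConfig()] for the validating constructor.
#' @export
setClass("SimConfig", representation(
    speciesTree = "ANY",
    nIndividualsPerSpecies = "integer",
    chromLength = "integer",
    nSites = "integer",
    driftScale = "numeric",
    rootFreqBeta = "numeric",
    introgressionEvents = "list",
    outgroupSpecies = "character",
    chromName = "character",
    quantizeTips = "logical"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    tr <- object@speciesTree
    if (!inherits(tr, "phylo"))
        msg <- c(msg, "speciesTree must be an ape 'phylo'")
    if (object@nSites < 1L)
        msg <- c(msg, "nSites must be >= 1")
    if (object@chromLength < object@nSites)
        msg <- c(msg, "chromLength must be >= nSites (positions are unique)")
    if (object@driftScale < 0)
        msg <- c(msg, "driftScale must be non-negative")
    if (length(object@rootFreqBeta) != 2L || any(object@rootFreqBeta <= 0))
        msg <- c(msg, "rootFreqBeta must be two positive shape parameters")
    if (inherits(tr, "phylo") && !(object@outgroupSpecies %in% tr$tip.label))
        msg <- c(msg, "outgroupSpecies must be a tip of speciesTree")
    for (ev in object@introgressionEvents) {
        need <- c("donor", "recipient", "start", "end", "rho", "mode")
        if (!all(need %in% names(ev))) {
            msg <- c(msg, "each event needs donor, recipient, start, end, rho, mode")
            next
        }
        if (ev$donor == ev$recipient)
            msg <- c(msg, "introgression donor and recipient must differ")
        if (ev$start < 1 || ev$end > object@chromLength || ev$start > ev$end)
            msg <- c(msg, "tract must lie within [1, chromLength]")
        if (ev$rho < 0 || ev$rho > 1)
            msg <- c(msg, "retention probability rho must be in [0, 1]")
        if (!ev$mode %in% c("fixed", "polymorphic"))
            msg <- c(msg, "fixation mode must be 'fixed' or 'polymorphic'")
        if (ev$mode == "polymorphic" &&
            (is.null(ev$carriers) || is.null(names(ev$carriers)) ||
             !all(ev$carriers %in% 0:2)))
            msg <- c(msg, "polymorphic mode needs named carrier copy numbers in 0:2")
        if (inherits(tr, "phylo") &&
            !all(c(ev$donor, ev$recipient) %in% tr$tip.label))
            msg <- c(msg, "event donor/recipient must be species-tree tips")
    }
    if (length(msg)) msg else TRUE
})

#' Exon structure of a single protein-coding gene
#'
#' `exons` are 1-based inclusive genomic intervals, stored in genomic
#' order; on the minus strand the spliced transcript reads them 3'-most
#' first after reverse complementation.
#'
#' @seealso [geneModel()], [spliceAndTranslate()].
#' @export
setClass("GeneModel", representation(
    chrom = "character",
    exons = "IRanges",
    strand = "character"
))

setValidity("GeneModel", function(object) {
    msg <- character()
    if (!object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be '+' or '-'")
    ex <- object@exons
    if (length(ex) == 0L)
        msg <- c(msg, "at least one exon required")
    if (length(ex) > 1L) {
        o <- order(IRanges::start(ex))
        so <- ex[o]
        if (any(IRanges::start(so)[-1L] <= IRanges::end(so)[-length(so)]))
            msg <- c(msg, "exons must not overlap")
    }
    if (length(msg)) msg else TRUE
})
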