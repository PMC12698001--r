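#' Construct a GenotypeExperiment
#'
#' @param chrom character vector of chromosome names, one per site.
#' @param pos integer vector of 1-based site positions (VCF convention).
#' @param ref,alt single-base REF/ALT alleles per site.
#' @param gt integer matrix (sites x individuals) of ALT dosages
#'   0/1/2/NA.
#' @param sampleIds ordered individual names (defaults to `colnames(gt)`).
#' @param groups character/factor of group labels, one per individual.
#' @return A [GenotypeExperiment-class] object.
#' @examples
#' ge <- GenotypeExperiment(
#'   chrom = c("chr1", "chr1"), pos = c(100L, 200L),
#'   ref = c("A", "C"), alt = c("G", "T"),
#'   gt = matrix(c(0L, 2L, 1L, NA), 2, 2,
#'               dimnames = list(NULL, c("s1", "s2"))),
#'   groups = c("spA", "spB"))
#' ge
#' @export
GenotypeExperiment <- function(chrom, pos, ref, alt, gt,
                               sampleIds = colnames(gt), groups) {
    gt <- as.matrix(gt)
    storage.mode(gt) <- "integer"
    if (is.null(sampleIds))
        stop("sampleIds required when gt has no column names")
    colnames(gt) <- sampleIds
    rr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L))
    mcols(rr)$ref <- as.character(ref)
    mcols(rr)$alt <- as.character(alt)
    o <- order(as.character(seqnames(rr)), start(rr))
    se <- SummarizedExperiment(
        assays = list(GT = gt[o, , drop = FALSE]),
        rowRanges = rr[o],
        colData = DataFrame(group = factor(as.character(groups)),
                            row.names = sampleIds))
    new("GenotypeExperiment", se)
}

#' Accessors for GenotypeExperiment
#'
#' `genotypeCalls()` returns the integer dosage matrix; `sitePositions()`
#' the 1-based positions; `siteChroms()` the chromosome per site;
#' `refAllele()`/`altAllele()` the alleles; `sampleGroups()` the
#' per-individual group factor; `groupMembers()` the individuals of one
#' group, in column order.
#'
#' @param x A [GenotypeExperiment-class].
#' @param group A group label present in `sampleGroups(x)`.
#' @return See individual descriptions.
#' @name genotype-accessors
NULL

#' @rdname genotype-accessors
#' @export
genotypeCalls <- function(x) assay(x, "GT")

#' @rdname genotype-accessors
#' @export
sitePositions <- function(x) start(rowRanges(x))

#' @rdname genotype-accessors
#' @export
siteChroms <- function(x) as.character(seqnames(rowRanges(x)))

#' @rdname genotype-accessors
#' @export
refAllele <- function(x) mcols(rowRanges(x))$ref

#' @rdname genotype-accessors
#' @export
altAllele <- function(x) mcols(rowRanges(x))$alt

#' @rdname genotype-accessors
#' @export
sampleGroups <- function(x) {
    g <- colData(x)$group
    names(g) <- colnames(x)
    g
}

#' @rdname genotype-accessors
#' @export
groupMembers <- function(x, group) {
    g <- sampleGroups(x)
    if (!group %in% g)
        stop("group '", group, "' has no individuals")
    names(g)[g == group]
}

setMethod("show", "GenotypeExperiment", function(object) {
    g <- colData(object)$group
    cat("GenotypeExperiment with", nrow(object), "biallelic SNP sites and",
        ncol(object), "individuals\n")
    cat("chromosomes:",
        paste(unique(as.character(seqnames(rowRanges(object)))), collapse = ", "),
        "\n")
    tab <- table(g)
    cat("groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
        "\n")
    miss <- mean(is.na(assay(object, "GT")))
    cat(sprintf("missingness: %.2f%%\n", 100 * miss))
})

#' Per-group ALT-allele frequencies and call counts
#'
#' For each site and each requested group, the ALT-allele frequency among
#' called alleles (each called diploid contributes two) and the number of
#' called alleles.  Missing genotypes are excluded from the denominator.
#'
#' @param x A [GenotypeExperiment-class].
#' @param groups character vector of group labels (default: all groups).
#' @return A list with matrices `freq` and `nCalled`
#'   (sites x groups); `freq` is `NaN` where a group has no called
#'   alleles at a site.
#' @export
groupAltFrequencies <- function(x, groups = levels(sampleGroups(x))) {
    gt <- genotypeCalls(x)
    sg <- sampleGroups(x)
    freq <- matrix(NA_real_, nrow(gt), length(groups),
                   dimnames = list(NULL, groups))
    ncall <- matrix(0L, nrow(gt), length(groups),
                    dimnames = list(NULL, groups))
    for (g in groups) {
        sub <- gt[, sg == g, drop = FALSE]
        called <- 2L * rowSums(!is.na(sub))
        altc <- rowSums(sub, na.rm = TRUE)
        freq[, g] <- altc / called
        ncall[, g] <- called
    }
    list(freq = freq, nCalled = ncall)
}
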