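#' @importFrom VariantAnnotation readVcf geno ref alt
#' @importFrom Biostrings DNAStringSet
#' @importFrom utils read.table write.table
NULL

.gtDosage <- function(gtChar) {
    # GT string -> ALT dosage; phasing ignored; any "." allele -> NA
    u <- unique(as.vector(gtChar))
    val <- vapply(u, function(s) {
        a <- strsplit(s, "[/|]")[[1]]
        if (any(a == ".") || length(a) == 0L) return(NA_integer_)
        sum(a == "1")
    }, integer(1))
    m <- matrix(val[match(as.vector(gtChar), u)], nrow(gtChar), ncol(gtChar))
    colnames(m) <- colnames(gtChar)
    m
}

#' Read a population map
#'
#' Two-column delimited text (individual, group); comment lines starting
#' with `#` are ignored.
#'
#' @param path File path.
#' @return data.frame with columns `individual` and `group`.
#' @export
readPopmap <- function(path) {
    pm <- read.table(path, header = FALSE, col.names = c("individual", "group"),
                     colClasses = "character", comment.char = "#")
    if (anyDuplicated(pm$individual))
        stop("popmap assigns an individual to more than one group")
    pm
}

#' @rdname readPopmap
#' @param popmap data.frame as returned by `readPopmap()`.
#' @export
writePopmap <- function(popmap, path) {
    write.table(popmap, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Load genotypes from a VCF and a population map
#'
#' Reads a VCF v4.x (the GT FORMAT field is sufficient), retains
#' biallelic SNP records only (multiallelic and non-SNP records are
#' skipped and counted), and attaches group labels from the population
#' map.  `./.` and `.|.` genotypes become missing; phasing is ignored.
#' Every individual in the VCF must appear in the popmap and vice versa.
#'
#' @param vcfPath Path to a VCF file.
#' @param popmapPath Path to a two-column (individual, group) text file.
#' @return A [GenotypeExperiment-class]; the number of skipped records is
#'   in `metadata(x)$nSkipped`.
#' @export
readGenotypeVcf <- function(vcfPath, popmapPath) {
    vcf <- suppressWarnings(readVcf(vcfPath, genome = "unknown"))
    if (!"GT" %in% names(geno(vcf)))
        stop("VCF has no GT field")
    altL <- alt(vcf)
    refS <- as.character(ref(vcf))
    altN <- S4Vectors::elementNROWS(altL)
    altFirst <- rep(NA_character_, length(altL))
    altFirst[altN >= 1L] <- as.character(unlist(altL))[
        cumsum(altN)[altN >= 1L] - altN[altN >= 1L] + 1L]
    keep <- altN == 1L & nchar(refS) == 1L & !is.na(altFirst) &
        nchar(altFirst) == 1L & altFirst %in% c("A", "C", "G", "T")
    nSkipped <- sum(!keep)
    if (nSkipped)
        message("skipped ", nSkipped, " multiallelic or non-SNP records")
    if (!any(keep))
        stop("no biallelic SNP records in VCF")
    gt <- .gtDosage(geno(vcf)$GT[keep, , drop = FALSE])
    pm <- readPopmap(popmapPath)
    vcfIds <- colnames(gt)
    if (!all(vcfIds %in% pm$individual))
        stop("VCF individuals missing from popmap: ",
             paste(setdiff(vcfIds, pm$individual), collapse = ", "))
    if (!all(pm$individual %in% vcfIds))
        stop("popmap individuals not in VCF: ",
             paste(setdiff(pm$individual, vcfIds), collapse = ", "))
    rr <- SummarizedExperiment::rowRanges(vcf)[keep]
    ge <- GenotypeExperiment(
        chrom = as.character(seqnames(rr)), pos = start(rr),
        ref = refS[keep], alt = altFirst[keep], gt = gt,
        groups = pm$group[match(vcfIds, pm$individual)])
    metadata(ge)$nSkipped <- nSkipped
    ge
}

#' Write a GenotypeExperiment as a minimal GT-only VCF
#'
#' Emits VCFv4.2 text with a GT FORMAT field only, unphased genotypes,
#' and missing calls written `./.`.  Output is byte-identical for
#' identical input, which makes simulator output reproducible.
#'
#' @param x A [GenotypeExperiment-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGenotypeVcf <- function(x, path) {
    gt <- genotypeCalls(x)
    gstr <- matrix(c("0/0", "0/1", "1/1")[gt + 1L], nrow(gt), ncol(gt))
    gstr[is.na(gt)] <- "./."
    lines <- c(
        "##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", colnames(gt)), collapse = "\t"),
        paste(siteChroms(x), sitePositions(x), ".", refAllele(x),
              altAllele(x), ".", ".", ".", "GT",
              apply(gstr, 1L, paste, collapse = "\t"), sep = "\t"))
    writeLines(lines, path)
    invisible(path)
}

#' Export haplotype blocks to BED
#'
#' Blocks carry 1-based inclusive coordinates internally; BED output is
#' 0-based half-open (BED6: name = individual/species label, score =
#' donor-allele fraction scaled 0-1000).
#'
#' @param blocks A `GRanges` as produced by [paintAndCallBlocks()], with
#'   metadata columns `label`, `nSites` and `donorFraction`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
exportBlocks <- function(blocks, path) {
    stopifnot(is(blocks, "GRanges"))
    if (length(blocks)) {
        byLab <- split(blocks, mcols(blocks)$label)
        ovl <- vapply(byLab, function(b)
            length(b) > 1L && !IRanges::isDisjoint(b), logical(1))
        if (any(ovl))
            stop("overlapping blocks for: ",
                 paste(names(byLab)[ovl], collapse = ", "))
    }
    out <- blocks
    mcols(out) <- NULL
    if (length(blocks)) {
        mcols(out)$name <- as.character(mcols(blocks)$label)
        mcols(out)$score <- round(1000 * mcols(blocks)$donorFraction)
    } else {
        mcols(out)$name <- character(0)
        mcols(out)$score <- numeric(0)
    }
    rtracklayer::export(out, path, format = "BED")
    invisible(path)
}
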