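#' @importFrom Biostrings DNAString AAString AAStringSet reverseComplement
#'   subseq translate
NULL

#' Construct a gene model
#'
#' @param chrom chromosome name.
#' @param starts,ends 1-based inclusive exon bounds (any order; sorted
#'   internally).
#' @param strand `"+"` or `"-"`.
#' @return A [GeneModel-class].
#' @export
geneModel <- function(chrom, starts, ends, strand = "+") {
    o <- order(starts)
    new("GeneModel", chrom = as.character(chrom),
        exons = IRanges(as.integer(starts[o]), as.integer(ends[o])),
        strand = strand)
}

#' Splice exons and translate
#'
#' Concatenates the exon sequences in genomic order, reverse-complements
#' the result for minus-strand models, and translates with the standard
#' genetic code.  Codons containing `N` or IUPAC ambiguity codes
#' translate to `X`; a trailing partial codon is dropped with a warning.
#'
#' @param genomeSeq the gene-region (or chromosome) sequence for one
#'   species: a `DNAString` or character string, 1-based coordinates
#'   matching the gene model.
#' @param model A [GeneModel-class].
#' @return list with `cds` (`DNAString`) and `protein` (`AAString`).
#' @export
spliceAndTranslate <- function(genomeSeq, model) {
    if (is.character(genomeSeq)) genomeSeq <- DNAString(genomeSeq)
    ex <- model@exons
    if (any(IRanges::start(ex) < 1L) ||
        any(IRanges::end(ex) > length(genomeSeq)))
        stop("exon coordinates outside the sequence")
    parts <- lapply(seq_along(ex), function(i)
        subseq(genomeSeq, IRanges::start(ex)[i], IRanges::end(ex)[i]))
    cds <- do.call(Biostrings::xscat, parts)
    if (model@strand == "-") cds <- reverseComplement(cds)
    rem <- length(cds) %% 3L
    if (rem) {
        warning("dropping trailing partial codon (", rem, " nt)")
        cds <- subseq(cds, 1L, length(cds) - rem)
    }
    protein <- if (length(cds))
        suppressWarnings(translate(cds, if.fuzzy.codon = "X"))
    else AAString("")
    list(cds = cds, protein = protein)
}

#' Residues diagnostic of a focal species set
#'
#' Scans an aligned protein matrix for positions where every non-missing
#' focal species carries one residue that no background species
#' carries.  `X` (within-species polymorphism or untranslatable codons)
#' and gaps are treated as missing and never match; positions with more
#' than `tolerance` missing focal species are skipped.
#'
#' @param alignment named `AAStringSet` (or named character vector) of
#'   equal-length aligned protein sequences, one per species.
#' @param focalSet species names forming the focal set; the rest are
#'   background.
#' @param tolerance maximum number of focal species allowed missing at a
#'   position (default 0).
#' @return data.frame with `position`, `focalResidue`,
#'   `backgroundResidues` (multiset collapsed to a string, e.g. `"KKQ"`).
#' @export
diagnosticResidues <- function(alignment, focalSet, tolerance = 0L) {
    if (is(alignment, "AAStringSet"))
        alignment <- setNames(as.character(alignment), names(alignment))
    if (is.null(names(alignment)))
        stop("alignment sequences must be named by species")
    if (!all(focalSet %in% names(alignment)))
        stop("focal species missing from alignment: ",
             paste(setdiff(focalSet, names(alignment)), collapse = ", "))
    background <- setdiff(names(alignment), focalSet)
    if (!length(background))
        stop("focal set covers all species; no contrast possible")
    lens <- nchar(alignment)
    if (length(unique(lens)) != 1L)
        stop("sequences are not aligned (unequal lengths)")
    mat <- do.call(rbind, strsplit(unname(alignment), ""))
    rownames(mat) <- names(alignment)
    missing <- mat %in% c("X", "-", "*", ".")
    dim(missing) <- dim(mat)
    res <- lapply(seq_len(ncol(mat)), function(j) {
        fr <- mat[focalSet, j]
        fm <- missing[match(focalSet, rownames(mat)), j]
        if (sum(fm) > tolerance) return(NULL)
        fr <- fr[!fm]
        if (!length(fr) || length(unique(fr)) != 1L) return(NULL)
        br <- mat[background, j]
        bm <- missing[match(background, rownames(mat)), j]
        br <- br[!bm]
        if (fr[1] %in% br) return(NULL)
        data.frame(position = j, focalResidue = fr[1],
                   backgroundResidues = paste(sort(br), collapse = ""))
    })
    out <- do.call(rbind, res)
    if (is.null(out))
        out <- data.frame(position = integer(0), focalResidue = character(0),
                          backgroundResidues = character(0))
    rownames(out) <- NULL
    out
}
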