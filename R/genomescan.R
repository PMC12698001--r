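#' Windowed f_d scan
#'
#' Tiles each chromosome with non-overlapping windows of width `w`
#' anchored at coordinate 0 (0-based half-open bounds) and computes the
#' f_d statistic from the sites falling in each window.  Windows with
#' fewer than `minSnps` usable sites report `NA`.
#'
#' @inheritParams derivedFrequencies
#' @param w window width in bp (default 10 kb).
#' @param minSnps minimum usable sites per window (default 10).
#' @param chromLengths optional named vector of chromosome lengths; when
#'   given, trailing empty windows out to the chromosome end are
#'   included (reported `NA`).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `nSnps`, `fd`.
#' @export
windowedFd <- function(x, p1g, p2g, p3g, og, w = 10000L, minSnps = 10L,
                       chromLengths = NULL) {
    if (w <= 0) stop("window width must be positive")
    freqs <- derivedFrequencies(x, p1g, p2g, p3g, og)
    out <- lapply(split(freqs, freqs$chrom), function(fc) {
        win <- (fc$pos - 1L) %/% w
        lastWin <- if (!is.null(chromLengths) &&
                       fc$chrom[1] %in% names(chromLengths))
            (chromLengths[[fc$chrom[1]]] - 1L) %/% w else max(win)
        nWin <- lastWin + 1L
        wAbba <- (1 - fc$p1) * fc$p2 * fc$p3 * (1 - fc$p4)
        wBaba <- fc$p1 * (1 - fc$p2) * fc$p3 * (1 - fc$p4)
        pd <- pmax(fc$p2, fc$p3)
        wdAbba <- (1 - fc$p1) * pd * pd * (1 - fc$p4)
        wdBaba <- fc$p1 * (1 - pd) * pd * (1 - fc$p4)
        num <- den <- numeric(nWin)
        rs <- rowsum(cbind(wAbba - wBaba, wdAbba - wdBaba), win)
        at <- as.integer(rownames(rs)) + 1L
        num[at] <- rs[, 1L]; den[at] <- rs[, 2L]
        nSnps <- tabulate(win + 1L, nWin)
        fd <- ifelse(num <= 0, 0, num / den)
        fd[num > 0 & den == 0] <- NA
        fd[nSnps < minSnps] <- NA
        data.frame(chrom = fc$chrom[1],
                   start = (0:lastWin) * w,
                   end = pmin((1:nWin) * w,
                              if (!is.null(chromLengths) &&
                                  fc$chrom[1] %in% names(chromLengths))
                                  chromLengths[[fc$chrom[1]]] else nWin * w),
                   nSnps = nSnps, fd = fd)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Flag outlier windows by empirical percentile
#'
#' A window is flagged when its f_d is at or above the `q` empirical
#' quantile of all non-`NA` windows (linear-interpolation quantile;
#' ties flagged inclusively).  When a gene interval is supplied, flagged
#' windows are annotated `withinProximity` if they overlap the interval
#' expanded by `proximity` bp on each side.
#'
#' @param windows data.frame from [windowedFd()].
#' @param q quantile in (0, 1), default 0.999.
#' @param geneInterval optional list/vector with `chrom`, `start`, `end`
#'   (1-based inclusive gene bounds).
#' @param proximity bp of expansion on each side (default 10 kb).
#' @return the flagged subset of `windows` with added columns
#'   `threshold` and (if `geneInterval` given) `withinProximity`.
#' @export
callOutliers <- function(windows, q = 0.999, geneInterval = NULL,
                         proximity = 10000L) {
    if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
    vals <- windows$fd[!is.na(windows$fd)]
    if (!length(vals)) stop("no non-NA windows")
    thr <- as.numeric(quantile(vals, q, type = 7))
    flag <- !is.na(windows$fd) & windows$fd >= thr
    out <- windows[flag, , drop = FALSE]
    out$threshold <- thr
    if (!is.null(geneInterval)) {
        gi <- as.list(geneInterval)
        lo <- as.numeric(gi$start) - proximity
        hi <- as.numeric(gi$end) + proximity
        # window [start,end) in 0-based vs gene in 1-based inclusive
        out$withinProximity <- out$chrom == gi$chrom &
            out$start < hi & out$end > lo - 1
    }
    rownames(out) <- NULL
    out
}

#' Diagnostic fixed-difference sites between two lineages
#'
#' Retains biallelic sites where group A carries one allele at frequency
#' >= `tauA`, group B carries the \emph{other} allele at frequency
#' >= `tauB`, and the fraction of individuals with missing genotypes in
#' each group is at most its cap.  Group A is conventionally the donor
#' lineage; the allele it carries is recorded as donor-diagnostic.
#'
#' @param x A [GenotypeExperiment-class].
#' @param groupA,groupB disjoint group labels (putative recipients must
#'   not be members of either).
#' @param tauA,tauB frequency thresholds in (0.5, 1]; 1.0 means fixed.
#' @param missA,missB missingness caps in \code{[0, 1)} (fraction of
#'   individuals missing).
#' @return data.frame with `chrom`, `pos`, `siteIndex`, `donorAllele`
#'   (`"ref"`/`"alt"`), `freqA`, `freqB` (frequency of the diagnostic
#'   allele in A and of the other allele in B).
#' @export
diagnosticSites <- function(x, groupA, groupB, tauA = 0.9, tauB = 0.9,
                            missA = 0.1, missB = 0.1) {
    if (groupA == groupB) stop("groups must be disjoint")
    if (tauA <= 0.5 || tauA > 1 || tauB <= 0.5 || tauB > 1)
        stop("tau must be in (0.5, 1]")
    sg <- sampleGroups(x)
    for (g in c(groupA, groupB))
        if (!g %in% sg) stop("group '", g, "' has no individuals")
    gt <- genotypeCalls(x)
    gA <- gt[, sg == groupA, drop = FALSE]
    gB <- gt[, sg == groupB, drop = FALSE]
    fracMissA <- rowMeans(is.na(gA))
    fracMissB <- rowMeans(is.na(gB))
    fAalt <- rowSums(gA, na.rm = TRUE) / (2 * rowSums(!is.na(gA)))
    fBalt <- rowSums(gB, na.rm = TRUE) / (2 * rowSums(!is.na(gB)))
    okMiss <- fracMissA <= missA & fracMissB <= missB &
        !is.nan(fAalt) & !is.nan(fBalt)
    altDiag <- okMiss & fAalt >= tauA & (1 - fBalt) >= tauB
    refDiag <- okMiss & (1 - fAalt) >= tauA & fBalt >= tauB
    keep <- which(altDiag | refDiag)
    data.frame(chrom = siteChroms(x)[keep],
               pos = sitePositions(x)[keep],
               siteIndex = keep,
               donorAllele = ifelse(altDiag[keep], "alt", "ref"),
               freqA = ifelse(altDiag[keep], fAalt[keep], 1 - fAalt[keep]),
               freqB = ifelse(altDiag[keep], 1 - fBalt[keep], fBalt[keep]),
               row.names = NULL)
}

.stateFromCount <- function(cnt) {
    s <- rep("missing", length(cnt))
    s[!is.na(cnt) & cnt == 0] <- "backgroundHom"
    s[!is.na(cnt) & cnt == 1] <- "het"
    s[!is.na(cnt) & cnt == 2] <- "donorHom"
    s
}

# majority state across individuals; missing excluded; ties -> het
.majorityState <- function(stateMat) {
    apply(stateMat, 1L, function(r) {
        r <- r[r != "missing"]
        if (!length(r)) return("missing")
        tab <- sort(table(r), decreasing = TRUE)
        if (length(tab) > 1L && tab[1] == tab[2]) "het" else names(tab)[1]
    })
}

#' Paint recipient genotypes at diagnostic sites and call blocks
#'
#' For each recipient (an individual name, or a group label painted by
#' majority state across its members) the donor-diagnostic allele count
#' at each diagnostic site gives a state in
#' \{`donorHom`, `het`, `backgroundHom`, `missing`\}.  Haplotype blocks
#' are maximal runs of consecutive diagnostic sites carrying >= 1 donor
#' allele, tolerating up to `gapTolerance` intervening
#' zero-donor-allele sites; missing sites neither extend, break, nor
#' count toward the gap.
#'
#' @param sites data.frame from [diagnosticSites()].
#' @param x the [GenotypeExperiment-class] the sites were derived from.
#' @param recipients character vector of individual names and/or group
#'   labels.
#' @param gapTolerance allowed zero-donor sites inside a block
#'   (default 0).
#' @return list with `painting` (character matrix, sites x recipients)
#'   and `blocks` (`GRanges` in 1-based inclusive coordinates with
#'   metadata `label`, `nSites`, `donorFraction` = donor alleles /
#'   called alleles within the block).
#' @export
paintAndCallBlocks <- function(sites, x, recipients, gapTolerance = 0L) {
    gt <- genotypeCalls(x)
    sg <- sampleGroups(x)
    donorCount <- function(ind, idx) {
        g <- gt[idx, ind]
        ifelse(sites$donorAllele == "alt", g, 2L - g)
    }
    idx <- sites$siteIndex
    counts <- list()   # per recipient: site x member donor-allele counts
    painting <- matrix(NA_character_, nrow(sites), length(recipients),
                       dimnames = list(NULL, recipients))
    for (rec in recipients) {
        if (rec %in% colnames(gt)) {
            cm <- matrix(donorCount(rec, idx), ncol = 1L)
        } else if (rec %in% sg) {
            cm <- vapply(groupMembers(x, rec), donorCount,
                         numeric(nrow(sites)), idx = idx)
            cm <- matrix(cm, nrow = nrow(sites))
        } else stop("recipient '", rec, "' is neither an individual nor a group")
        counts[[rec]] <- cm
        if (ncol(cm) == 1L) {
            painting[, rec] <- .stateFromCount(cm[, 1L])
        } else {
            sm <- apply(cm, 2L, .stateFromCount)
            painting[, rec] <- .majorityState(matrix(sm, nrow = nrow(sites)))
        }
    }
    blocks <- GRanges()
    for (rec in recipients) {
        for (ch in unique(sites$chrom)) {
            ci <- which(sites$chrom == ch)
            st <- painting[ci, rec]
            carry <- st %in% c("het", "donorHom")
            zero <- st == "backgroundHom"
            runs <- .donorRuns(carry, zero, gapTolerance)
            for (r in runs) {
                span <- ci[r[1]:r[2]]
                cm <- counts[[rec]][span, , drop = FALSE]
                donor <- sum(cm, na.rm = TRUE)
                called <- 2L * sum(!is.na(cm))
                blocks <- c(blocks, GRanges(
                    ch, IRanges(sites$pos[ci[r[1]]], sites$pos[ci[r[2]]]),
                    label = rec, nSites = length(span),
                    donorFraction = if (called) donor / called else NA_real_))
            }
        }
    }
    list(painting = painting, blocks = blocks)
}

# maximal runs of carry==TRUE tolerating <= g zero sites between
# carriers; returns list of c(firstIdx, lastIdx) into the input vector
.donorRuns <- function(carry, zero, g) {
    runs <- list()
    start <- NA_integer_; last <- NA_integer_; gaps <- 0L
    for (i in seq_along(carry)) {
        if (carry[i]) {
            if (is.na(start)) start <- i
            last <- i; gaps <- 0L
        } else if (!is.na(start) && zero[i]) {
            gaps <- gaps + 1L
            if (gaps > g) {
                runs[[length(runs) + 1L]] <- c(start, last)
                start <- NA_integer_; last <- NA_integer_; gaps <- 0L
            }
        }
    }
    if (!is.na(start)) runs[[length(runs) + 1L]] <- c(start, last)
    runs
}

#' Shared core of haplotype blocks across species
#'
#' The coordinate intersection of all input blocks: the interval at
#' which every carrier retains donor ancestry (the analogue of a short
#' central stretch fixed in all recipient species).
#'
#' @param blocks `GRanges` of >= 2 blocks on one chromosome.
#' @return `GRanges` of length 1 (the intersection) or 0 (disjoint).
#' @export
sharedCore <- function(blocks) {
    stopifnot(is(blocks, "GRanges"), length(blocks) >= 2L)
    if (length(unique(as.character(seqnames(blocks)))) > 1L)
        stop("blocks lie on different chromosomes")
    s <- max(start(blocks)); e <- min(end(blocks))
    if (s > e) return(GRanges())
    GRanges(as.character(seqnames(blocks))[1], IRanges(s, e))
}
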