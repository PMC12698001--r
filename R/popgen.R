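#' Per-site derived-allele frequencies for a four-taxon test
#'
#' Computes derived-allele frequencies in P1, P2, P3 (putative donor) and
#' the outgroup.  The derived allele is polarized as the minor allele in
#' the outgroup, ties broken toward ALT; missing alleles are excluded
#' from denominators; sites where any of the four groups has zero called
#' alleles are excluded (count in `attr(, "nExcluded")`).
#'
#' @param x A [GenotypeExperiment-class].
#' @param p1g,p2g,p3g,og disjoint group labels: P1, P2 (recipient),
#'   P3 (donor), outgroup.
#' @return data.frame with columns `chrom`, `pos`, `p1`, `p2`, `p3`,
#'   `p4`, `derived` (`"ref"`/`"alt"`) and per-group called-allele counts
#'   `n1`..`n4`.
#' @export
derivedFrequencies <- function(x, p1g, p2g, p3g, og) {
    gl <- c(p1g, p2g, p3g, og)
    if (anyDuplicated(gl))
        stop("the four groups must be disjoint")
    sg <- sampleGroups(x)
    if (!all(gl %in% sg))
        stop("group(s) with no individuals: ",
             paste(setdiff(gl, sg), collapse = ", "))
    af <- groupAltFrequencies(x, gl)
    called <- af$nCalled > 0L
    keep <- rowSums(called) == 4L
    f <- af$freq[keep, , drop = FALSE]
    n <- af$nCalled[keep, , drop = FALSE]
    # polarize: derived = outgroup minor allele, tie -> ALT
    derivedIsAlt <- f[, 4L] <= 0.5
    p <- f
    p[!derivedIsAlt, ] <- 1 - p[!derivedIsAlt, ]
    out <- data.frame(chrom = siteChroms(x)[keep],
                      pos = sitePositions(x)[keep],
                      p1 = p[, 1L], p2 = p[, 2L], p3 = p[, 3L], p4 = p[, 4L],
                      derived = ifelse(derivedIsAlt, "alt", "ref"),
                      n1 = n[, 1L], n2 = n[, 2L], n3 = n[, 3L], n4 = n[, 4L])
    rownames(out) <- NULL
    attr(out, "nExcluded") <- sum(!keep)
    out
}

# frequency-weighted ABBA/BABA site weights
.patternWeights <- function(p1, p2, p3, p4) {
    list(abba = (1 - p1) * p2 * p3 * (1 - p4),
         baba = p1 * (1 - p2) * p3 * (1 - p4))
}

#' ABBA-BABA D statistic for population samples
#'
#' Frequency-weighted D over a table of per-site derived-allele
#' frequencies: with site weights
#' \eqn{C_{ABBA} = (1-p_1)p_2p_3(1-p_4)} and
#' \eqn{C_{BABA} = p_1(1-p_2)p_3(1-p_4)},
#' \eqn{D = \sum(C_{ABBA}-C_{BABA}) / \sum(C_{ABBA}+C_{BABA})}.
#' An excess of ABBA (D > 0) indicates gene flow between P2 and P3.
#'
#' @param freqs data.frame from [derivedFrequencies()] (columns
#'   `p1`..`p4`).
#' @return list with `D` (`NA` when every site weight is zero), and the
#'   accumulated `sumAbba`/`sumBaba` for reuse by the jackknife.
#' @export
dStatistic <- function(freqs) {
    w <- .patternWeights(freqs$p1, freqs$p2, freqs$p3, freqs$p4)
    sa <- sum(w$abba); sb <- sum(w$baba)
    D <- if (sa + sb > 0) (sa - sb) / (sa + sb) else NA_real_
    list(D = D, sumAbba = sa, sumBaba = sb)
}

#' The f_d introgression-fraction statistic
#'
#' The window-scaled extension of D for population samples: the
#' numerator is \eqn{\sum(C_{ABBA}-C_{BABA})}; the denominator replaces
#' both P2 and P3 by the donor-like population \eqn{P_D}, the one of
#' P2/P3 with the higher derived frequency at each site, giving the
#' maximal sharing attainable.  Reported as 0 when the numerator sum is
#' non-positive (no ABBA excess), and `NA` when the denominator is zero
#' with a positive numerator.
#'
#' @inheritParams dStatistic
#' @return list with `fd`, `numerator`, `denominator`.
#' @export
fdValue <- function(freqs) {
    w <- .patternWeights(freqs$p1, freqs$p2, freqs$p3, freqs$p4)
    num <- sum(w$abba) - sum(w$baba)
    pd <- pmax(freqs$p2, freqs$p3)
    wd <- .patternWeights(freqs$p1, pd, pd, freqs$p4)
    den <- sum(wd$abba) - sum(wd$baba)
    fd <- if (num <= 0) 0
          else if (den == 0) NA_real_
          else num / den
    list(fd = fd, numerator = num, denominator = den)
}

#' The f4 statistic
#'
#' \eqn{f_4(A,B;C,D) = \sum_s (p_A-p_B)(p_C-p_D)} over per-site derived
#' frequencies.  Building block of the f4-ratio.
#'
#' @param pA,pB,pC,pD numeric vectors of per-site derived-allele
#'   frequencies.
#' @return the f4 sum.
#' @export
f4Sum <- function(pA, pB, pC, pD) {
    sum((pA - pB) * (pC - pD))
}

# per-site f4-ratio components with a random split of P3's called
# alleles: p3a from one half polarizes the shared drift, p3b from the
# other half replaces P2 in the denominator (avoids shared sampling
# noise between numerator and denominator)
.f4RatioComponents <- function(freqs) {
    k3 <- round(freqs$p3 * freqs$n3)         # derived alleles in P3
    n3 <- freqs$n3
    na <- floor(n3 / 2)
    ka <- rhyper(length(k3), k3, n3 - k3, na)
    p3a <- ka / na
    p3b <- (k3 - ka) / (n3 - na)
    data.frame(num = (freqs$p1 - freqs$p2) * (p3a - freqs$p4),
               den = (freqs$p1 - p3b) * (p3a - freqs$p4))
}

#' f4-ratio estimate of the admixture proportion
#'
#' Estimates the fraction of the P2 genome derived from the P3 (donor)
#' lineage as \eqn{\hat\alpha = f_4(P1,P2;P3_a,O) / f_4(P1,P3_b;P3_a,O)}
#' where \eqn{f_4(A,B;C,D) = \sum_s (p_A-p_B)(p_C-p_D)} and
#' \eqn{P3_a, P3_b} are disjoint random halves of P3's called alleles,
#' re-drawn per site under `seed`.  Sites where P3 has fewer than two
#' called alleles are dropped.
#'
#' @inheritParams derivedFrequencies
#' @param seed integer seed for the per-site allele split.
#' @return list with `alpha` (`NA` when the denominator is within 1e-12
#'   of zero), `nSitesUsed`.
#' @export
f4Ratio <- function(x, p1g, p2g, p3g, og, seed = 1L) {
    freqs <- derivedFrequencies(x, p1g, p2g, p3g, og)
    freqs <- freqs[freqs$n3 >= 2L, , drop = FALSE]
    set.seed(as.integer(seed))
    comp <- .f4RatioComponents(freqs)
    den <- sum(comp$den)
    alpha <- if (abs(den) < 1e-12) NA_real_ else sum(comp$num) / den
    list(alpha = alpha, nSitesUsed = nrow(freqs))
}

# split n sites into nBlocks contiguous runs of near-equal size
.blockIndex <- function(n, nBlocks) {
    sizes <- rep(n %/% nBlocks, nBlocks)
    extra <- n %% nBlocks
    if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    rep(seq_len(nBlocks), sizes)
}

#' Block-jackknife test of D or the f4-ratio
#'
#' Splits the informative sites into `nBlocks` contiguous blocks of
#' equal site counts (the genome order respects linkage), recomputes the
#' statistic leaving each block out, and reports the delete-one
#' jackknife standard error
#' \eqn{SE = \sqrt{\frac{n-1}{n}\sum_i(\theta_{(i)}-\bar\theta)^2}}
#' and `Z = value / SE` (`NA` when SE is 0).
#'
#' @inheritParams derivedFrequencies
#' @param statistic `"D"` or `"f4ratio"`.
#' @param nBlocks number of jackknife blocks (default 200).
#' @param seed seed for the f4-ratio allele split.
#' @return list with `statistic`, `value`, `se`, `z`, `nBlocks`,
#'   `nSitesUsed`.
#' @export
blockJackknife <- function(x, p1g, p2g, p3g, og,
                           statistic = c("D", "f4ratio"),
                           nBlocks = 200L, seed = 1L) {
    statistic <- match.arg(statistic)
    freqs <- derivedFrequencies(x, p1g, p2g, p3g, og)
    if (statistic == "D") {
        w <- .patternWeights(freqs$p1, freqs$p2, freqs$p3, freqs$p4)
        inf <- which(w$abba + w$baba > 0)
        if (length(inf) < nBlocks)
            stop("only ", length(inf), " informative sites; ",
                 "choose nBlocks <= that")
        blk <- .blockIndex(length(inf), nBlocks)
        bn <- rowsum(w$abba[inf] - w$baba[inf], blk)
        bd <- rowsum(w$abba[inf] + w$baba[inf], blk)
        value <- sum(bn) / sum(bd)
        loo <- (sum(bn) - bn) / (sum(bd) - bd)
        nUsed <- length(inf)
    } else {
        freqs <- freqs[freqs$n3 >= 2L, , drop = FALSE]
        if (nrow(freqs) < nBlocks)
            stop("only ", nrow(freqs), " usable sites; ",
                 "choose nBlocks <= that")
        set.seed(as.integer(seed))
        comp <- .f4RatioComponents(freqs)
        blk <- .blockIndex(nrow(freqs), nBlocks)
        bn <- rowsum(comp$num, blk)
        bd <- rowsum(comp$den, blk)
        value <- sum(bn) / sum(bd)
        loo <- (sum(bn) - bn) / (sum(bd) - bd)
        nUsed <- nrow(freqs)
    }
    n <- nBlocks
    se <- sqrt((n - 1) / n * sum((loo - mean(loo))^2))
    z <- if (se > 0) value / se else NA_real_
    list(statistic = statistic, value = value, se = se, z = z,
         nBlocks = as.integer(nBlocks), nSitesUsed = nUsed)
}
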