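#' Introgression-event counts under serial-transfer scenarios
#'
#' Given a donor and an ordered set of recipient species, the number of
#' introgression events needed for the shared haplotype to reach each
#' recipient under three scenarios: `independent` (each recipient
#' received it directly from the donor: 1 event each), `hub` (the first
#' recipient received it from the donor and passed it to each of the
#' others: 1 then 2 each), and `chain` (serial transfer along the
#' ordered list: recipient k needed k events).
#'
#' @param kind `"independent"`, `"hub"` or `"chain"`.
#' @param recipients ordered character vector of recipient species
#'   (first = earliest recipient).
#' @param donor donor label (must not be a recipient).
#' @return named integer vector of per-recipient event counts.
#' @export
scenarioEventCounts <- function(kind = c("independent", "hub", "chain"),
                                recipients, donor = NULL) {
    kind <- match.arg(kind)
    if (!length(recipients)) stop("recipient list is empty")
    if (anyDuplicated(recipients)) stop("recipients must be distinct")
    if (!is.null(donor) && donor %in% recipients)
        stop("donor cannot be a recipient")
    k <- length(recipients)
    counts <- switch(kind,
        independent = rep(1L, k),
        hub = if (k == 1L) 1L else c(1L, rep(2L, k - 1L)),
        chain = seq_len(k))
    setNames(as.integer(counts), recipients)
}

#' Rank recipients by remaining haplotype size
#'
#' Heuristic ordering of serial-introgression recipients: each transfer
#' exposes the haplotype to new pulses of recombination, so under the
#' tract-decay model the earliest recipient is expected to retain the
#' largest block.  Recipients are ranked by block length descending;
#' ties share a rank and are reported as unordered groups.
#'
#' @param blocks a `GRanges` with a `label` metadata column (one block
#'   per recipient), or a named numeric vector of block lengths.
#' @param recipients optional recipient list to require (error if a
#'   listed recipient has no block).
#' @return data.frame with `recipient`, `length`, `rank` (min-rank for
#'   ties), ordered by decreasing length.  The ordering is a heuristic
#'   under the decay model, not a test.
#' @export
inferTransferOrder <- function(blocks, recipients = NULL) {
    if (is(blocks, "GRanges")) {
        len <- setNames(width(blocks), mcols(blocks)$label)
    } else len <- blocks
    if (length(len) < 2L) stop("need blocks for >= 2 recipients")
    if (!is.null(recipients) && !all(recipients %in% names(len)))
        stop("no block for recipient(s): ",
             paste(setdiff(recipients, names(len)), collapse = ", "))
    o <- order(len, decreasing = TRUE)
    out <- data.frame(recipient = names(len)[o],
                      length = as.numeric(len[o]),
                      rank = rank(-len, ties.method = "min")[o])
    rownames(out) <- NULL
    out
}

#' Simulate introgressed-tract decay under recombination
#'
#' The introgressed allele at `focalPos` is kept by selection; the
#' surrounding donor tract erodes as crossovers accumulate.  Per
#' replicate, breakpoints fall on `[0, L0]` as a homogeneous Poisson
#' process of intensity `r * t` per unit length (rate `r` per unit per
#' generation over `t` generations); the surviving tract is the
#' interval between the nearest breakpoints flanking `focalPos`.
#' `rounds > 1` chains independent decay rounds on the surviving tract,
#' modelling serial transfer into successive recipients.
#'
#' @param L0 initial tract length.
#' @param focalPos position of the selected site in `[0, L0]`.
#' @param r recombination rate per unit length per generation (>= 0).
#' @param t generations per round.
#' @param reps number of replicates.
#' @param seed integer seed.
#' @param rounds number of chained decay rounds (default 1).
#' @return list with `meanLength`, `lengths` (per replicate), `left`
#'   and `right` surviving flank lengths.
#' @export
simulateTractDecay <- function(L0, focalPos = L0 / 2, r, t, reps = 1000L,
                               seed = 1L, rounds = 1L) {
    if (r < 0) stop("recombination rate must be non-negative")
    stopifnot(L0 > 0, t > 0, reps >= 1, focalPos >= 0, focalPos <= L0)
    set.seed(as.integer(seed))
    leftAvail <- rep(focalPos, reps)
    rightAvail <- rep(L0 - focalPos, reps)
    for (rd in seq_len(rounds)) {
        lam <- r * t * (leftAvail + rightAvail)
        n <- rpois(reps, lam)
        id <- rep.int(seq_len(reps), n)
        u <- runif(sum(n)) * (leftAvail + rightAvail)[id] - leftAvail[id]
        # u is breakpoint offset from the focal site; nearest on each side
        left <- leftAvail
        right <- rightAvail
        if (length(u)) {
            neg <- u < 0
            if (any(neg)) {
                nearLeft <- tapply(-u[neg], id[neg], min)
                at <- as.integer(names(nearLeft))
                left[at] <- pmin(left[at], nearLeft)
            }
            if (any(!neg)) {
                nearRight <- tapply(u[!neg], id[!neg], min)
                at <- as.integer(names(nearRight))
                right[at] <- pmin(right[at], nearRight)
            }
        }
        leftAvail <- left
        rightAvail <- right
    }
    lengths <- leftAvail + rightAvail
    list(meanLength = mean(lengths), lengths = lengths,
         left = leftAvail, right = rightAvail)
}
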