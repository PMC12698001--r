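#' Parse and write Newick trees
#'
#' Thin validated wrappers around ape's Newick reader/writer.
#' `parseNewick()` rejects unbalanced parentheses and duplicate leaf
#' labels; an optional outgroup roots the tree.
#'
#' @param text a Newick string (or path when `isFile = TRUE`).
#' @param outgroup optional tip label to root on.
#' @param isFile treat `text` as a file path.
#' @return `parseNewick()`: an ape `phylo`; `writeNewick()`: a Newick
#'   string.
#' @export
parseNewick <- function(text, outgroup = NULL, isFile = FALSE) {
    if (isFile)
        text <- paste(readLines(text), collapse = "")
    chars <- strsplit(text, "")[[1]]
    depth <- cumsum((chars == "(") - (chars == ")"))
    if (any(depth < 0) || depth[length(depth)] != 0)
        stop("unbalanced parentheses in Newick text")
    tree <- read.tree(text = text)
    if (is.null(tree)) stop("could not parse Newick text")
    if (anyDuplicated(tree$tip.label))
        stop("duplicate leaf labels: ",
             paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                   collapse = ", "))
    if (!is.null(outgroup)) {
        if (!outgroup %in% tree$tip.label)
            stop("outgroup '", outgroup, "' not in tree")
        tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
    }
    tree
}

#' @rdname parseNewick
#' @param tree an ape `phylo`.
#' @export
writeNewick <- function(tree) {
    write.tree(tree)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Plumbing stand-in for external tree inference: standard
#' neighbor-joining with negative branch lengths clamped to 0.
#'
#' @param D symmetric zero-diagonal distance matrix.
#' @param labels optional taxon labels (default: `rownames(D)`).
#' @return unrooted ape `phylo`.
#' @export
njFromDistances <- function(D, labels = rownames(D)) {
    D <- as.matrix(D)
    if (!isSymmetric(unname(D), tol = 1e-8) || any(diag(D) != 0))
        stop("distance matrix must be symmetric with zero diagonal")
    if (!is.null(labels)) rownames(D) <- colnames(D) <- labels
    tr <- ape::nj(as.dist(D))
    tr$edge.length[tr$edge.length < 0] <- 0
    tr
}

# leaf sets of every node (tips and internal), as character vectors
.nodeLeafSets <- function(tree) {
    nTip <- length(tree$tip.label)
    sets <- vector("list", nTip + tree$Nnode)
    for (i in seq_len(nTip)) sets[[i]] <- tree$tip.label[i]
    # postorder: children before parents
    po <- ape::reorder.phylo(tree, "postorder")
    for (i in seq_len(nrow(po$edge))) {
        par <- po$edge[i, 1L]; child <- po$edge[i, 2L]
        sets[[par]] <- c(sets[[par]], sets[[child]])
    }
    lapply(sets, sort)
}

.isClade <- function(leafSets, leaves) {
    key <- paste(sort(leaves), collapse = "\r")
    key %in% vapply(leafSets, paste, character(1), collapse = "\r")
}

#' Taxa displaced onto a donor clade's branch
#'
#' Detects the gene-tree signature of introgression: taxa that fall on
#' the branch normally occupied by the donor clade `donorClade`.  Two
#' complementary signals are used, in order: (i) if the gene-tree span
#' of the donor clade (the subtree of its MRCA) contains non-member
#' leaves, those intruders are the displaced set; (ii) otherwise, walk
#' rootward from the donor clade's MRCA and return the extra leaves of
#' the first gene-tree clade whose leaf set is not a species-tree clade
#' (a grouping with the donor clade that the species tree does not
#' predict), stopping as soon as a species-tree-concordant ancestor is
#' reached.  Returns an empty set for a concordant gene tree.
#'
#' @param geneTree,speciesTree rooted ape `phylo` on the same leaf set
#'   (the species tree is pruned to the gene tree's leaves if larger).
#' @param donorClade character vector of donor-clade tips; must be
#'   monophyletic in the species tree.
#' @param outgroup optional tip to root both trees on first.
#' @return character vector of displaced (recipient) taxa; possibly
#'   empty.
#' @export
displacedTaxa <- function(geneTree, speciesTree, donorClade,
                          outgroup = NULL) {
    if (!is.null(outgroup)) {
        geneTree <- ape::root(geneTree, outgroup = outgroup,
                              resolve.root = TRUE)
        speciesTree <- ape::root(speciesTree, outgroup = outgroup,
                                 resolve.root = TRUE)
    }
    if (!all(donorClade %in% geneTree$tip.label))
        stop("donor clade taxa missing from gene tree")
    extra <- setdiff(speciesTree$tip.label, geneTree$tip.label)
    if (length(extra))
        speciesTree <- ape::drop.tip(speciesTree, extra)
    if (!all(geneTree$tip.label %in% speciesTree$tip.label))
        stop("gene tree contains taxa absent from species tree")
    if (!ape::is.monophyletic(speciesTree, donorClade))
        stop("donor clade is not monophyletic in the species tree")
    sSets <- .nodeLeafSets(speciesTree)
    gSets <- .nodeLeafSets(geneTree)
    nTipG <- length(geneTree$tip.label)
    mrca <- if (length(donorClade) > 1L)
        ape::getMRCA(geneTree, donorClade)
    else match(donorClade, geneTree$tip.label)
    span <- gSets[[mrca]]
    intruders <- setdiff(span, donorClade)
    if (length(intruders)) return(sort(intruders))
    # monophyletic in gene tree: look for an unexpected grouping above
    node <- mrca
    repeat {
        parent <- geneTree$edge[geneTree$edge[, 2L] == node, 1L]
        if (!length(parent)) return(character(0))   # reached the root
        K <- gSets[[parent]]
        if (!.isClade(sSets, K))
            return(sort(setdiff(K, donorClade)))
        if (length(setdiff(K, donorClade)))        # concordant ancestor
            return(character(0))
        node <- parent
    }
}

#' Crown-age scaling of node divergence times
#'
#' Converts relative node depths to absolute ages using one or more
#' external crown-age calibrations: the relative depth of a node is its
#' mean path length to descendant tips divided by the mean root-to-tip
#' path length, and its age under calibration `T` is relative depth
#' times `T`.  A monotonicity repair clamps each child's relative depth
#' to its parent's, so ages never increase tipward.  Reported per node:
#' (min, mean, max) over the calibration set.
#'
#' @param tree rooted ape `phylo` with branch lengths.
#' @param crownAges numeric vector of crown ages (e.g. Mya), one per
#'   calibration source.
#' @param focalClades optional named list of tip-label vectors; when
#'   given, only the MRCA of each is reported.
#' @return data.frame with `node`, `label` (focal-clade name or node
#'   number), `relDepth`, `minAge`, `meanAge`, `maxAge`.
#' @export
calibrateNodeAges <- function(tree, crownAges, focalClades = NULL) {
    stopifnot(all(crownAges > 0))
    nTip <- length(tree$tip.label)
    nNode <- nTip + tree$Nnode
    # mean depth to descendant tips, via postorder accumulation
    sumDepth <- numeric(nNode)
    nTips <- integer(nNode)
    nTips[seq_len(nTip)] <- 1L
    po <- ape::reorder.phylo(tree, "postorder")
    for (i in seq_len(nrow(po$edge))) {
        par <- po$edge[i, 1L]; child <- po$edge[i, 2L]
        bl <- po$edge.length[i]
        sumDepth[par] <- sumDepth[par] + sumDepth[child] + bl * nTips[child]
        nTips[par] <- nTips[par] + nTips[child]
    }
    meanDepth <- sumDepth / nTips
    rootNode <- nTip + 1L
    if (meanDepth[rootNode] <= 0)
        stop("degenerate tree: zero mean root-to-tip path length")
    rel <- meanDepth / meanDepth[rootNode]
    # clamp children to parents, preorder
    pre <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]
    for (i in seq_len(nrow(pre)))
        rel[pre[i, 2L]] <- min(rel[pre[i, 2L]], rel[pre[i, 1L]])
    nodes <- if (is.null(focalClades)) (nTip + 1L):nNode
        else vapply(focalClades, function(lv) {
            if (length(lv) < 2L) stop("focal clades need >= 2 leaves")
            as.integer(ape::getMRCA(tree, lv))
        }, integer(1))
    labels <- if (is.null(focalClades)) as.character(nodes)
        else names(focalClades)
    ages <- outer(rel[nodes], crownAges)
    data.frame(node = nodes, label = labels, relDepth = rel[nodes],
               minAge = apply(ages, 1L, min),
               meanAge = rowMeans(ages),
               maxAge = apply(ages, 1L, max),
               row.names = NULL)
}
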