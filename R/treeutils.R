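#' @importFrom ape read.tree write.tree is.rooted Ntip
NULL

#' Read a support-annotated Newick tree
#'
#' Parses Newick text (or a file) into an ape \code{phylo} object, with
#' bootstrap/support values carried as internal node labels (the common
#' tree-inference output dialect).  Duplicate leaf labels and unbalanced
#' parentheses are rejected with informative errors.
#'
#' @param x Newick string, or path to a file containing one.
#' @return a \code{phylo} object.
#' @export
readSupportTree <- function(x) {
    text <- if (length(x) == 1L && !grepl("(", x, fixed = TRUE) &&
                file.exists(x)) paste(readLines(x), collapse = "") else x
    opens <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
    closes <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
    if (opens != closes)
        stop(sprintf("unbalanced parentheses: %d '(' vs %d ')'",
                     opens, closes))
    tr <- read.tree(text = text)
    if (is.null(tr)) stop("Newick parse failure")
    dup <- tr$tip.label[duplicated(tr$tip.label)]
    if (length(dup))
        stop("duplicate leaf label(s): ", paste(unique(dup), collapse = ", "))
    tr
}

#' Write a tree as Newick with supports as internal labels
#'
#' @param tree a \code{phylo} object.
#' @param file optional output path; if omitted, the Newick string is
#'   returned.
#' @param digits significant digits for branch lengths (default 6).
#' @return the Newick string, invisibly when written to a file.
#' @export
writeSupportTree <- function(tree, file = NULL, digits = 6L) {
    txt <- write.tree(tree, digits = digits)
    if (!is.null(file)) {
        writeLines(txt, file)
        return(invisible(txt))
    }
    txt
}

# numeric support values from internal node labels (NA where absent)
.nodeSupport <- function(tree) {
    if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
    suppressWarnings(as.numeric(tree$node.label))
}

#' Midpoint-root a phylogeny
#'
#' Places the root halfway along the longest leaf-to-leaf path, so the two
#' farthest leaves are equidistant from the root.  Support labels are
#' preserved through the rerooting.
#'
#' @param tree a \code{phylo} with branch lengths.
#' @return a rooted \code{phylo}.
#' @export
midpointRoot <- function(tree) {
    if (is.null(tree$edge.length))
        stop("midpoint rooting requires branch lengths")
    if (Ntip(tree) < 2L) stop("need at least 2 leaves")
    phangorn::midpoint(tree, node.labels = "support")
}

#' Collapse internal edges with low support
#'
#' Contracts every internal edge whose support (the child node's label)
#' falls below the threshold, producing multifurcations; leaf edges and the
#' leaf set are untouched, and edges without a numeric support label are
#' kept.  The operation is idempotent: no surviving internal edge has
#' support below the threshold.
#'
#' @param tree a \code{phylo} with support values as internal node labels.
#' @param threshold minimum support retained (default 95; edges with
#'   support strictly below it are collapsed).
#' @return a \code{phylo}, possibly multifurcating.
#' @export
collapseLowSupport <- function(tree, threshold = 95) {
    repeat {
        nt <- Ntip(tree)
        sup <- .nodeSupport(tree)
        child <- tree$edge[, 2]
        isInt <- child > nt
        supChild <- rep(NA_real_, length(child))
        supChild[isInt] <- sup[child[isInt] - nt]
        bad <- which(isInt & !is.na(supChild) & supChild < threshold)
        if (!length(bad)) return(tree)
        e <- bad[1L]
        chi <- tree$edge[e, 2L]
        par <- tree$edge[e, 1L]
        tree$edge[tree$edge[, 1L] == chi, 1L] <- par
        keep <- seq_len(nrow(tree$edge)) != e
        tree$edge <- tree$edge[keep, , drop = FALSE]
        if (!is.null(tree$edge.length))
            tree$edge.length <- tree$edge.length[keep]
        tree$edge[tree$edge > chi] <- tree$edge[tree$edge > chi] - 1L
        if (!is.null(tree$node.label))
            tree$node.label <- tree$node.label[-(chi - nt)]
        tree$Nnode <- tree$Nnode - 1L
    }
}

# tip labels under an internal node
.cladeTips <- function(tree, node) {
    nt <- Ntip(tree)
    stack <- node
    tips <- integer()
    while (length(stack)) {
        nd <- stack[1L]; stack <- stack[-1L]
        kids <- tree$edge[tree$edge[, 1L] == nd, 2L]
        tips <- c(tips, kids[kids <= nt])
        stack <- c(stack, kids[kids > nt])
    }
    tree$tip.label[tips]
}

#' Automated phylogenetic support check for an HGT candidate
#'
#' Formalizes the manual inspection of candidate-gene phylogenies: after
#' midpoint rooting and support collapsing, a candidate is phylogenetically
#' supported as horizontally acquired when the smallest non-trivial clade
#' containing it (the clade at its parent node, excluding the root) holds
#' at least one leaf from a potential donor lineage ("other") and no leaf
#' from the recipient lineage; leaves from the self-containing skip lineage
#' are ignored.  This is one defensible formalization of a judgment call,
#' and reports should label it as such.
#'
#' @param tree a rooted, support-collapsed \code{phylo}.
#' @param query leaf label of the candidate gene.
#' @param classes named character vector mapping every other leaf to
#'   "recipient", "skip", or "other".
#' @return list with \code{supported} (logical), \code{clade} (leaf labels
#'   of the enclosing clade, or character(0) when only the root contains
#'   the query), and \code{reason}.
#' @export
hgtSupportCheck <- function(tree, query, classes) {
    nt <- Ntip(tree)
    qi <- match(query, tree$tip.label)
    if (is.na(qi)) stop("query leaf '", query, "' not in tree")
    other <- setdiff(tree$tip.label, query)
    unmapped <- setdiff(other, names(classes))
    if (length(unmapped))
        stop("leaves without a taxon class: ",
             paste(utils::head(unmapped, 5), collapse = ", "))
    root <- nt + 1L
    parent <- tree$edge[tree$edge[, 2L] == qi, 1L]
    if (length(parent) != 1L || parent == root)
        return(list(supported = FALSE, clade = character(0),
                    reason = "no non-trivial clade contains the query"))
    clade <- setdiff(.cladeTips(tree, parent), query)
    cls <- classes[clade]
    informative <- cls[cls != "skip"]
    supported <- any(informative == "other") &&
        !any(informative == "recipient")
    reason <- if (supported)
        "query nests within donor-lineage leaves with no recipient leaf"
    else if (any(informative == "recipient"))
        "recipient-lineage leaf inside the enclosing clade"
    else "no donor-lineage leaf in the enclosing clade"
    list(supported = supported, clade = clade, reason = reason)
}
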