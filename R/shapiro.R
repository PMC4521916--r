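# Coarse-grained (Shapiro) motif trees and the ordered tree edit distance.

#' Coarse-grained Shapiro tree of a secondary structure
#'
#' Decomposes a nested structure into its motif tree: a virtual root R whose
#' children are external single-strand regions (E) and outermost stems (S);
#' each stem encloses one loop node -- hairpin (H), bulge (B), interior loop
#' (I) or multibranch loop (M) -- whose children are the next stems.  Nodes
#' carry no size annotation: the tree encodes shape only, so it is invariant
#' under compensatory base-pair substitutions.  Construction is
#' deterministic and follows 5' to 3' order.
#'
#' @param x a \linkS4class{SecondaryStructure}.
#' @return a \linkS4class{ShapiroTree}.
#' @examples
#' shapiroString(shapiroTree(parseDotBracket("((...))")))  # "R(S(H))"
#' @export
setMethod("shapiroTree", "SecondaryStructure", function(x) {
    t <- .shapiro_tree_cpp(x@dotbracket)
    new("ShapiroTree", labels = SHAPIRO_LABELS[t$labels],
        parent = as.integer(t$parent),
        span = cbind(start = as.integer(t$lo), end = as.integer(t$hi)))
})

#' @describeIn shapiroTree compact parenthesised rendering, e.g.
#'   \code{"R(S(M(S(H),S(H))))"}.
#' @export
setMethod("shapiroString", "ShapiroTree", function(x) {
    n <- length(x@labels)
    children <- .tree_children(x)
    render <- function(i) {
        kids <- children[[i]]
        if (!length(kids)) return(x@labels[i])
        paste0(x@labels[i], "(",
               paste(vapply(kids, render, character(1)), collapse = ","),
               ")")
    }
    render(1L)
})

setMethod("show", "ShapiroTree", function(object) {
    cat(sprintf("ShapiroTree (%d nodes): %s\n", length(object@labels),
                shapiroString(object)))
})

.tree_children <- function(tree) {
    n <- length(tree@labels)
    children <- vector("list", n)
    if (n > 1L) for (i in 2L:n) {
        p <- tree@parent[i]
        children[[p]] <- c(children[[p]], i)
    }
    children
}

#' Parse a parenthesised Shapiro tree string
#'
#' Inverse of \code{shapiroString}, mainly useful for constructing small
#' trees by hand.  Spans are unknown for hand-built trees and set to zero.
#'
#' @param text tree string such as \code{"R(S(I(S(H))))"}.
#' @return a \linkS4class{ShapiroTree}.
#' @export
parseShapiro <- function(text) {
    txt <- gsub("[[:space:]]", "", text)
    chars <- .rna_chars(txt)
    pos <- 1L
    labels <- character(0); parent <- integer(0)
    parse_node <- function(par) {
        lab <- chars[pos]
        if (!lab %in% SHAPIRO_LABELS)
            stop("unexpected label '", lab, "' at position ", pos)
        pos <<- pos + 1L
        labels <<- c(labels, lab)
        parent <<- c(parent, par)
        me <- length(labels)
        if (pos <= length(chars) && chars[pos] == "(") {
            pos <<- pos + 1L
            repeat {
                parse_node(me)
                if (pos > length(chars))
                    stop("unterminated subtree list")
                if (chars[pos] == ",") { pos <<- pos + 1L; next }
                if (chars[pos] == ")") { pos <<- pos + 1L; break }
                stop("expected ',' or ')' at position ", pos)
            }
        }
        me
    }
    parse_node(0L)
    if (pos <= length(chars)) stop("trailing input after tree")
    n <- length(labels)
    new("ShapiroTree", labels = labels, parent = as.integer(parent),
        span = cbind(start = integer(n), end = integer(n)))
}

# postorder label codes and leftmost-leaf-descendant indices for Zhang-Shasha
.tree_postorder <- function(tree) {
    n <- length(tree@labels)
    children <- .tree_children(tree)
    post <- integer(0)
    visit <- function(i) {
        for (k in children[[i]]) visit(k)
        post <<- c(post, i)
    }
    visit(1L)
    postpos <- match(seq_len(n), post)
    lld <- integer(n)
    for (pi in seq_len(n)) {
        j <- post[pi]
        while (length(children[[j]])) j <- children[[j]][1L]
        lld[pi] <- postpos[j]
    }
    list(labels = match(tree@labels[post], SHAPIRO_LABELS), lld = lld)
}

#' Ordered tree edit distance between Shapiro trees
#'
#' Zhang-Shasha ordered labelled tree edit distance with unit insertion,
#' deletion and relabelling costs.  A metric: zero exactly for
#' label-isomorphic trees, symmetric, and satisfying the triangle
#' inequality.
#'
#' @param a,b \linkS4class{ShapiroTree} objects, or
#'   \linkS4class{SecondaryStructure} objects (converted via
#'   \code{shapiroTree} first).
#' @return integer edit distance.
#' @export
setMethod("treeEditDistance", signature("ShapiroTree", "ShapiroTree"),
    function(a, b) {
        pa <- .tree_postorder(a)
        pb <- .tree_postorder(b)
        .tree_edit_distance_cpp(pa$labels, pa$lld, pb$labels, pb$lld)
    })

#' @rdname treeEditDistance
#' @export
setMethod("treeEditDistance",
          signature("SecondaryStructure", "SecondaryStructure"),
    function(a, b) treeEditDistance(shapiroTree(a), shapiroTree(b)))
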