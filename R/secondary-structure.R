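# Stack-matching of a dot-bracket string.  Returns an integer matrix of
# 0-based (i, j) pairs ordered by i, or a character error message.
.pairs_from_dotbracket <- function(db) {
    res <- .dotbracket_pairs_cpp(db)
    if (!res$ok) {
        idx <- res$index
        ch <- substr(db, idx + 1L, idx + 1L)
        return(if (ch == "(") sprintf("unbalanced '(' at index %d", idx)
               else if (ch == ")") sprintf("unbalanced ')' at index %d", idx)
               else sprintf("illegal character '%s' at index %d", ch, idx))
    }
    m <- res$pairs
    colnames(m) <- c("i", "j")
    m
}

#' Parse dot-bracket notation into a secondary structure
#'
#' Computes the base-pair set by stack matching.  Only nested (pseudoknot
#' free) structures over \code{.}, \code{(}, \code{)} are accepted;
#' whitespace is stripped.
#'
#' @param text dot-bracket string.
#' @return a \linkS4class{SecondaryStructure}.
#' @examples
#' s <- parseDotBracket("((...))")
#' basePairs(s)  # rows (0,6) and (1,5)
#' @export
parseDotBracket <- function(text) {
    db <- gsub("[[:space:]]", "", text)
    p <- .pairs_from_dotbracket(db)
    if (is.character(p)) stop("dot-bracket parse error: ", p)
    new("SecondaryStructure", dotbracket = db, pairs = p)
}

#' @describeIn parseDotBracket dot-bracket string accessor.
#' @param x a SecondaryStructure.
#' @export
setMethod("dotbracket", "SecondaryStructure", function(x) x@dotbracket)

#' @describeIn parseDotBracket base-pair matrix accessor (0-based, i < j).
#' @export
setMethod("basePairs", "SecondaryStructure", function(x) x@pairs)

#' @export
setMethod("length", "SecondaryStructure",
          function(x) nchar(x@dotbracket))

setMethod("show", "SecondaryStructure", function(object) {
    cat(sprintf("SecondaryStructure (%d nt, %d base pairs)\n",
                nchar(object@dotbracket), nrow(object@pairs)))
    cat(" ", object@dotbracket, "\n")
})

#' Base-pair distance between two structures
#'
#' The cardinality of the symmetric difference of the two base-pair sets: a
#' metric that is zero exactly when the pair sets are identical.  The two
#' structures must have the same length (the search compares equal-length
#' windows).
#'
#' @param a,b \linkS4class{SecondaryStructure} objects of equal length.
#' @return integer distance.
#' @export
setMethod("basePairDistance",
          signature("SecondaryStructure", "SecondaryStructure"),
    function(a, b) {
        if (nchar(a@dotbracket) != nchar(b@dotbracket))
            stop("basePairDistance requires equal-length structures (",
                 nchar(a@dotbracket), " vs ", nchar(b@dotbracket), ")")
        ka <- paste(a@pairs[, 1L], a@pairs[, 2L])
        kb <- paste(b@pairs[, 1L], b@pairs[, 2L])
        length(setdiff(ka, kb)) + length(setdiff(kb, ka))
    })

#' Read a Vienna-style structure file
#'
#' Expects an optional \code{>header} line, a sequence line and a dot-bracket
#' line; a trailing \code{(dG)} suffix on the structure line is ignored.
#'
#' @param path file path.
#' @return list with elements \code{sequence} (\linkS4class{RNASequence}),
#'   \code{structure} (\linkS4class{SecondaryStructure}) and \code{dG}
#'   (numeric, NA when absent).
#' @export
readViennaStructure <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    id <- ""
    if (length(lines) && startsWith(lines[1L], ">")) {
        id <- sub("^>\\s*", "", lines[1L])
        lines <- lines[-1L]
    }
    if (length(lines) < 2L)
        stop("Vienna structure file needs a sequence line and a structure line")
    seq <- RNASequence(trimws(lines[1L]), id = id)
    sline <- trimws(lines[2L])
    dG <- NA_real_
    m <- regmatches(sline, regexec("^([.()]+)\\s*\\(\\s*(-?[0-9.]+)\\s*\\)$",
                                   sline))[[1]]
    if (length(m) == 3L) {
        sline <- m[2L]
        dG <- as.numeric(m[3L])
    }
    structure <- parseDotBracket(sline)
    if (length(structure) != length(seq))
        stop("sequence and structure lengths differ in ", path)
    list(sequence = seq, structure = structure, dG = dG)
}

#' Write a Vienna-style structure file
#'
#' @param sequence an \linkS4class{RNASequence}.
#' @param structure its \linkS4class{SecondaryStructure}.
#' @param path output path.
#' @param dG optional free energy appended as \code{(dG)}.
#' @return invisibly, \code{path}.
#' @export
writeViennaStructure <- function(sequence, structure, path, dG = NA_real_) {
    sline <- structure@dotbracket
    if (!is.na(dG)) sline <- sprintf("%s (%.2f)", sline, dG)
    writeLines(c(paste0(">", sequence@id), sequence@residues, sline), path)
    invisible(path)
}
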