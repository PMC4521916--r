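#' Construct an RNA sequence
#'
#' Builds an \linkS4class{RNASequence}, normalising DNA letters (T) and
#' lowercase input to the uppercase RNA alphabet.
#'
#' @param residues nucleotide string over A, C, G, U (T and lowercase
#'   accepted and normalised).
#' @param id sequence identifier.
#' @param description optional free-text description.
#' @return an \linkS4class{RNASequence}.
#' @examples
#' rna <- RNASequence("gattaca", id = "toy")
#' residues(rna)  # "GAUUACA"
#' @export
RNASequence <- function(residues, id = "", description = "") {
    new("RNASequence", id = as.character(id),
        description = as.character(description),
        residues = .to_rna(residues))
}

#' @describeIn RNASequence residue string accessor.
#' @param x an RNASequence.
#' @export
setMethod("residues", "RNASequence", function(x) x@residues)

#' @describeIn RNASequence identifier accessor.
#' @export
setMethod("seqID", "RNASequence", function(x) x@id)

#' @describeIn RNASequence description accessor.
#' @export
setMethod("seqDescription", "RNASequence", function(x) x@description)

setMethod("show", "RNASequence", function(object) {
    cat("RNASequence", if (nzchar(object@id)) object@id else "<unnamed>",
        sprintf("(%d nt)\n", nchar(object@residues)))
    r <- object@residues
    if (nchar(r) > 60) r <- paste0(substr(r, 1, 57), "...")
    cat(" ", r, "\n")
})

#' Number of residues
#' @param x an RNASequence or SecondaryStructure.
#' @return integer length.
#' @export
setMethod("length", "RNASequence", function(x) nchar(x@residues))

#' Hamming distance between equal-length sequences
#'
#' Counts positions whose residues differ after alphabet normalisation.
#'
#' @param a,b \linkS4class{RNASequence} objects (or plain strings) of equal
#'   length.
#' @return integer count of differing positions.
#' @export
setMethod("hammingDistance", signature("RNASequence", "RNASequence"),
    function(a, b) {
        ra <- a@residues; rb <- b@residues
        if (nchar(ra) != nchar(rb))
            stop("hammingDistance requires equal-length sequences (",
                 nchar(ra), " vs ", nchar(rb), ")")
        sum(.rna_chars(ra) != .rna_chars(rb))
    })

#' @rdname hammingDistance
#' @export
setMethod("hammingDistance", signature("character", "character"),
    function(a, b) hammingDistance(RNASequence(a), RNASequence(b)))

#' Read a multi-record FASTA file as RNA sequences
#'
#' DNA letters are converted to RNA on ingest.  Wrapped and unwrapped
#' records are both accepted.
#'
#' @param path FASTA file path.
#' @return list of \linkS4class{RNASequence} objects.
#' @export
readRNAFasta <- function(path) {
    set <- Biostrings::readBStringSet(path)
    nm <- names(set)
    lapply(seq_along(set), function(i) {
        words <- strsplit(nm[i], "[ \t]+")[[1]]
        RNASequence(as.character(set[[i]]), id = words[1L],
                    description = trimws(sub("^\\S+\\s*", "", nm[i])))
    })
}

#' Write RNA sequences to a FASTA file
#'
#' @param seqs an \linkS4class{RNASequence} or list thereof.
#' @param path output file path.
#' @param width line wrap width.
#' @return invisibly, \code{path}.
#' @export
writeRNAFasta <- function(seqs, path, width = 60L) {
    if (is(seqs, "RNASequence")) seqs <- list(seqs)
    nm <- vapply(seqs, function(s) {
        if (nzchar(s@description)) paste(s@id, s@description) else s@id
    }, character(1))
    set <- Biostrings::BStringSet(vapply(seqs, slot, character(1), "residues"))
    names(set) <- nm
    Biostrings::writeXStringSet(set, path, width = width)
    invisible(path)
}

#' The Bacillus subtilis xpt guanine-binding aptamer domain
#'
#' The 69-nt wild-type purine riboswitch aptamer used as the worked query
#' throughout the package, together with the covariant escape and restored
#' borderline sequences derived from it.
#'
#' @return \code{xptAptamer()}: the aptamer as an \linkS4class{RNASequence}.
#' @export
xptAptamer <- function() {
    RNASequence(paste0("CACUCAUAUAAUCGCGUGGAUAUGGCACGCAAGUUUCUACC",
                       "GGGCACCGUAAAUGUCCGACUAUGGGUG"),
                id = "xpt_Bsubtilis",
                description = "guanine-binding purine riboswitch aptamer")
}

#' @rdname xptAptamer
#' @return \code{xptEscapeSequences()}: named list with the covariant escape
#'   sequence (\code{escaped}) and the partially restored borderline sequence
#'   (\code{restored}).
#' @export
xptEscapeSequences <- function() {
    list(
        escaped = RNASequence(
            paste0("UGAAUGUAUAAUUCGACCUGGCAACGGUCGAAGUUUCUACC",
                   "AAAAAAUAACCGUUUUUGACUACAUUCA"),
            id = "xpt_covariant_escape"),
        restored = RNASequence(
            paste0("UGAAUGUAUAAUUCGACCUGGCAACGGUCGAAGUUUCUACC",
                   "GGGCACCGUAAAUGUCCGACUACAUUCA"),
            id = "xpt_borderline_restored"))
}

#' The Bacillus subtilis queC preQ1 aptamer and its mutational series
#'
#' The wild-type queC riboswitch aptamer plus the three mutated sequences of
#' the structure-preservation case study: a 17-mutation covariant escape that
#' retains the wild-type fold, the same sequence after one further covariant
#' base-pair change (C-G to A-U in the 5' stem) whose fold is disrupted by
#' energy considerations, and an alternative escape that preserves the fold.
#'
#' @return named list of \linkS4class{RNASequence}: \code{wildtype},
#'   \code{escape17}, \code{collapsed}, \code{alternative}.
#' @export
preq1Sequences <- function() {
    list(
        wildtype = RNASequence(
            "CCGTGCGATATGCGGGAGAGGTTCTAGCTACACCCTCTATAAAAAACTAAGGA",
            id = "queC_Bsubtilis", description = "preQ1 riboswitch aptamer"),
        escape17 = RNASequence(
            "ACGTGCGATATGCGTGGGCCGTTCTAGCTACACCGGCCATTTTTTTCATTGGA",
            id = "queC_escape17"),
        collapsed = RNASequence(
            "ATGTGCGATATGCATGGGCCGTTCTAGCTACACCGGCCATTTTTTTCATTGGA",
            id = "queC_escape19_collapsed"),
        alternative = RNASequence(
            "AAGTGCGATATGCTTGGGCCGTTCTAGCTACACCGGCCATAAAAAAGAAAGGA",
            id = "queC_alt_escape"))
}
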