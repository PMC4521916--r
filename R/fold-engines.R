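# Minimum free energy folding behind a pluggable engine contract.

#' Built-in deterministic fold engine
#'
#' A Nussinov-style dynamic program over pair scores GC -3, AU -2, GU -1
#' (arbitrary energy units reported as dG), with a minimum hairpin loop of 3
#' unpaired nucleotides.  The traceback is fully deterministic, preferring
#' the 5'-most pairing at ties, so the engine is oracle-verifiable by
#' exhaustive enumeration.  Intended for testing and for fully reproducible
#' pipeline runs; prefer \code{viennaEngine()} for thermodynamic realism.
#'
#' @param min_hairpin minimum unpaired nucleotides in a hairpin loop.
#' @return a \linkS4class{FoldEngine}.
#' @export
nussinovEngine <- function(min_hairpin = 3L) {
    min_hairpin <- as.integer(min_hairpin)
    new("FoldEngine", name = "builtin",
        fold = function(res) .nussinov_fold_cpp(res, min_hairpin))
}

#' ViennaRNA thermodynamic fold engine
#'
#' Adapter around the \command{RNAfold} executable (nearest-neighbour Turner
#' parameters, default temperature and ionic conditions).  Deterministic for
#' a fixed sequence and RNAfold version; predictions can shift between
#' energy-parameter revisions.
#'
#' @param rnafold path to the RNAfold executable.
#' @return a \linkS4class{FoldEngine}.
#' @export
viennaEngine <- function(rnafold = "RNAfold") {
    if (Sys.which(rnafold) == "")
        stop("RNAfold executable not found; install ViennaRNA or use ",
             "nussinovEngine()")
    new("FoldEngine", name = "vienna",
        fold = function(res) {
            out <- system2(rnafold, c("--noPS"), input = res, stdout = TRUE)
            sline <- out[length(out)]
            m <- regmatches(sline,
                regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\s*\\)", sline))[[1]]
            if (length(m) != 3L)
                stop("could not parse RNAfold output: ", sline)
            list(dotbracket = m[2L], dG = as.numeric(m[3L]))
        })
}

#' Select a fold engine by name
#'
#' @param name "builtin" or "vienna".
#' @return a \linkS4class{FoldEngine}.
#' @export
foldEngine <- function(name = c("builtin", "vienna")) {
    switch(match.arg(name), builtin = nussinovEngine(), vienna = viennaEngine())
}

setMethod("show", "FoldEngine", function(object) {
    cat("FoldEngine:", object@name, "\n")
})

#' Predict the minimum free energy structure of a sequence
#'
#' Sequences too short to form any admissible pair fold to the open chain
#' (dG 0), not an error.
#'
#' @param seq an \linkS4class{RNASequence} (or residue string).
#' @param engine a \linkS4class{FoldEngine}.
#' @return list with elements \code{structure}
#'   (\linkS4class{SecondaryStructure}) and \code{dG} (numeric).
#' @examples
#' foldMFE(RNASequence("GGGAAACCC"), nussinovEngine())$structure
#' @export
foldMFE <- function(seq, engine = nussinovEngine()) {
    if (is.character(seq)) seq <- RNASequence(seq)
    out <- engine@fold(seq@residues)
    structure <- parseDotBracket(out$dotbracket)
    if (length(structure) != length(seq))
        stop("engine '", engine@name,
             "' returned a structure of the wrong length")
    list(structure = structure, dG = out$dG)
}

#' Does a sequence still fold into a reference structure?
#'
#' Folds the sequence and compares to the reference by base-pair distance.
#'
#' @param seq an \linkS4class{RNASequence}, same length as the reference.
#' @param reference the reference \linkS4class{SecondaryStructure}.
#' @param engine a \linkS4class{FoldEngine}.
#' @param tol_bp maximum tolerated base-pair distance.
#' @return TRUE iff the predicted fold is within \code{tol_bp} of the
#'   reference.
#' @export
structurePreserved <- function(seq, reference, engine = nussinovEngine(),
                               tol_bp = 0L) {
    if (is.character(seq)) seq <- RNASequence(seq)
    if (length(seq) != length(reference))
        stop("sequence and reference structure must have equal length")
    fold <- foldMFE(seq, engine)
    basePairDistance(fold$structure, reference) <= tol_bp
}
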