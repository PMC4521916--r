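#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' @export
setGeneric("seqID", function(x) standardGeneric("seqID"))

#' @export
setGeneric("seqDescription", function(x) standardGeneric("seqDescription"))

#' @export
setGeneric("dotbracket", function(x) standardGeneric("dotbracket"))

#' @export
setGeneric("basePairs", function(x) standardGeneric("basePairs"))

#' @export
setGeneric("hammingDistance",
           function(a, b) standardGeneric("hammingDistance"))

#' @export
setGeneric("basePairDistance",
           function(a, b) standardGeneric("basePairDistance"))

#' @export
setGeneric("treeEditDistance",
           function(a, b) standardGeneric("treeEditDistance"))

#' @export
setGeneric("shapiroTree", function(x) standardGeneric("shapiroTree"))

#' @export
setGeneric("shapiroString", function(x) standardGeneric("shapiroString"))

#' @export
setGeneric("objectiveTotal", function(x) standardGeneric("objectiveTotal"))

#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))
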