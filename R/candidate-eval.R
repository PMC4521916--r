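# Turn similarity hits on designed sequences into vetted riboswitch
# candidates: extract aptamer-sized windows, fold, compare to the query
# structure, report Table-style metrics.

#' Extract an aptamer-sized window around a similarity hit
#'
#' The window has exactly \code{aptamer_len} nucleotides, anchored by the
#' hit's query offset: the alignment's query start dictates how much is
#' added upstream of the subject interval, the remainder goes downstream.
#' Windows clipped at a record edge are shifted toward the interior to
#' preserve the length.  Minus-strand hits are extracted from the reverse
#' complement.
#'
#' @param record_sequence the full record (forward-strand DNA/RNA string).
#' @param hit one row of a \code{\link{searchHits}} data.frame.
#' @param aptamer_len the query aptamer length.
#' @return list with \code{window} (\linkS4class{RNASequence}),
#'   \code{location} (integer(2), 1-based inclusive forward-strand
#'   interval) and \code{strand}.
#' @export
extractWindow <- function(record_sequence, hit, aptamer_len) {
    rec <- .to_dna(record_sequence)
    Ls <- nchar(rec)
    if (Ls < aptamer_len)
        stop("record shorter than the aptamer length")
    minus <- hit$strand == "-"
    subj <- if (minus) .revcomp_dna(rec) else rec
    # subject interval in strand space
    ss <- if (minus) Ls - hit$send else hit$sstart
    start <- ss - hit$qstart
    end <- start + aptamer_len
    if (start < 0L) { start <- 0L; end <- aptamer_len }
    if (end > Ls) { end <- Ls; start <- Ls - aptamer_len }
    window <- substr(subj, start + 1L, end)
    fwd <- if (minus) c(Ls - end, Ls - start) else c(start, end)
    list(window = RNASequence(window,
                              id = paste0(hit$record_id, "_window")),
         location = c(fwd[1L] + 1L, fwd[2L]),
         strand = if (minus) "-" else "+")
}

#' Structurally assess a candidate window against the query aptamer
#'
#' Folds the window, computes base-pair and Shapiro distances to the query
#' structure and marks positions identical to the query sequence.  The
#' verdict keys on the coarse-grained shape: accepted iff the Shapiro
#' distance is at most \code{max_shapiro} and, when a motif constraint is
#' supplied, the coarse label sequence over the constraint region matches
#' the query's (the multibranch core must be present).  The raw base-pair
#' distance is reported but deliberately does not gate acceptance: genuine
#' homologs show large base-pair distances from minor shifts between
#' coarse-grained motifs.
#'
#' @param window the extracted \linkS4class{RNASequence} (query length).
#' @param query the query \linkS4class{RNASequence}.
#' @param query_structure the query \linkS4class{SecondaryStructure}.
#' @param engine a \linkS4class{FoldEngine}.
#' @param constraint optional \linkS4class{MotifConstraint} marking the
#'   ligand-binding core.
#' @param max_shapiro acceptance threshold on the Shapiro distance.
#' @param record_id,location,strand,e_value provenance carried into the
#'   report.
#' @return a \linkS4class{CandidateReport}.
#' @export
assessCandidate <- function(window, query, query_structure,
                            engine = nussinovEngine(), constraint = NULL,
                            max_shapiro = 2L, record_id = "",
                            location = c(NA_integer_, NA_integer_),
                            strand = "+", e_value = NA_real_) {
    if (is.character(window)) window <- RNASequence(window)
    if (length(window) != length(query))
        stop("window and query must have equal length")
    fold <- foldMFE(window, engine)$structure
    bp <- basePairDistance(fold, query_structure)
    shap <- treeEditDistance(fold, query_structure)
    preserved <- which(.rna_chars(window@residues) ==
                       .rna_chars(query@residues)) - 1L
    motif_ok <- TRUE
    if (!is.null(constraint)) {
        motif_ok <- identical(
            .region_labels(fold, constraint@region),
            .region_labels(query_structure, constraint@region))
    }
    new("CandidateReport", record_id = as.character(record_id),
        location = as.integer(location), strand = strand, window = window,
        structure = fold, bp_distance = as.integer(bp),
        shapiro_distance = as.integer(shap),
        preserved_positions = as.integer(preserved),
        e_value = as.numeric(e_value),
        verdict = shap <= max_shapiro && motif_ok)
}

# preorder label string of the Shapiro nodes whose span intersects a
# 0-based half-open region -- the coarse description of that fragment
.region_labels <- function(structure, region) {
    tree <- shapiroTree(structure)
    hit <- tree@span[, 1L] < region[2L] & tree@span[, 2L] > region[1L]
    paste(tree@labels[hit], collapse = "")
}

#' @describeIn assessCandidate acceptance verdict accessor.
#' @param x a CandidateReport.
#' @export
setMethod("verdict", "CandidateReport", function(x) x@verdict)

setMethod("show", "CandidateReport", function(object) {
    cat(sprintf("CandidateReport %s:%d-%d(%s) %s | bp %d, shapiro %d, %d preserved\n",
                object@record_id, object@location[1L], object@location[2L],
                object@strand,
                if (object@verdict) "ACCEPTED" else "rejected",
                object@bp_distance, object@shapiro_distance,
                length(object@preserved_positions)))
})

#' Rank candidate reports
#'
#' Accepted candidates first, then ascending Shapiro distance, base-pair
#' distance and E-value; the sort is stable, so ties keep input order.
#'
#' @param reports list of \linkS4class{CandidateReport} objects.
#' @return the reordered list.
#' @export
rankCandidates <- function(reports) {
    if (!length(reports)) return(reports)
    acc <- vapply(reports, function(r) !r@verdict, logical(1))
    shap <- vapply(reports, slot, integer(1), "shapiro_distance")
    bp <- vapply(reports, slot, integer(1), "bp_distance")
    ev <- vapply(reports, slot, numeric(1), "e_value")
    ev[is.na(ev)] <- Inf
    reports[order(acc, shap, bp, ev)]
}

#' Tabulate candidate reports
#'
#' One row per report, locations printed 1-based inclusive; suitable for
#' TSV export.
#'
#' @param reports list of \linkS4class{CandidateReport} objects.
#' @return data.frame.
#' @export
candidateTable <- function(reports) {
    if (!length(reports))
        return(data.frame(record_id = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          verdict = logical(0), bp_distance = integer(0),
                          shapiro_distance = integer(0),
                          n_preserved = integer(0), e_value = numeric(0),
                          sequence = character(0), structure = character(0),
                          stringsAsFactors = FALSE))
    do.call(rbind, lapply(reports, function(r) {
        data.frame(record_id = r@record_id, start = r@location[1L],
                   end = r@location[2L], strand = r@strand,
                   verdict = r@verdict, bp_distance = r@bp_distance,
                   shapiro_distance = r@shapiro_distance,
                   n_preserved = length(r@preserved_positions),
                   e_value = r@e_value, sequence = r@window@residues,
                   structure = r@structure@dotbracket,
                   stringsAsFactors = FALSE)
    }))
}
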