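# The five-term design objective, its weights and sub-scores.

#' Construct the design objective weights
#'
#' The weights are fixed at the published values; only the term switches are
#' tunable.  The motif term dominates (1000) because the protected fragment
#' must be reproduced without compromise; the Shapiro term (100) drives
#' shape preservation; the tiny base-pair term (0.01) keeps solutions from
#' being over-dominated by shape alone.  The neutrality (100) and dG (1)
#' terms are available but disabled by default, because candidate
#' riboswitches with different nucleotide composition may legitimately
#' differ in robustness and stability.
#'
#' @param enable_neutrality enable the mutational-robustness term.
#' @param enable_dG enable the thermodynamic-stability term.
#' @return an \linkS4class{ObjectiveWeights}.
#' @export
ObjectiveWeights <- function(enable_neutrality = FALSE, enable_dG = FALSE) {
    new("ObjectiveWeights", w_neutrality = 100, w_dG = 1, w_motif = 1000,
        w_shapiro = 100, w_bp = 0.01,
        enable_neutrality = isTRUE(enable_neutrality),
        enable_dG = isTRUE(enable_dG))
}

#' Construct a motif constraint
#'
#' @param region integer(2): 0-based half-open interval on the target
#'   structure (use \code{regionFromStructure} helpers or 1-based input via
#'   \code{one_based = TRUE}).
#' @param substructure required dot-bracket over the region.
#' @param fixed_positions 0-based positions of fixed nucleotides.
#' @param fixed_nucleotides required residues, parallel to
#'   \code{fixed_positions}.
#' @param one_based interpret \code{region} (inclusive) and
#'   \code{fixed_positions} as 1-based.
#' @return a \linkS4class{MotifConstraint}.
#' @export
MotifConstraint <- function(region, substructure, fixed_positions = integer(0),
                            fixed_nucleotides = character(0),
                            one_based = FALSE) {
    region <- as.integer(region)
    fixed_positions <- as.integer(fixed_positions)
    if (one_based) {
        region <- c(region[1L] - 1L, region[2L])
        fixed_positions <- fixed_positions - 1L
    }
    new("MotifConstraint", region = region,
        substructure = as.character(substructure),
        fixed_positions = fixed_positions,
        fixed_nucleotides = .to_rna(as.character(fixed_nucleotides)))
}

#' Read a constraint file
#'
#' Plain-text format: a line \code{motif START END} (1-based inclusive)
#' followed by a dot-bracket line giving the required substructure, and any
#' number of \code{fix POS NT} lines (1-based).  Bare \code{START END} and
#' \code{POS NT} lines are also accepted; \code{#} starts a comment.
#'
#' @param path constraint file path.
#' @return a \linkS4class{MotifConstraint}.
#' @export
readConstraintFile <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    region <- NULL; substructure <- NULL
    fpos <- integer(0); fnt <- character(0)
    expect_db <- FALSE
    for (ln in lines) {
        if (expect_db) {
            if (!grepl("^[.()]+$", ln))
                stop("expected a dot-bracket line after the motif region in ",
                     path)
            substructure <- ln
            expect_db <- FALSE
            next
        }
        tok <- strsplit(ln, "[ \t]+")[[1]]
        if (tok[1L] == "motif") tok <- tok[-1L]
        else if (tok[1L] == "fix") tok <- tok[-1L]
        if (length(tok) == 2L && !is.na(suppressWarnings(as.integer(tok[2L])))) {
            region <- as.integer(tok)
            expect_db <- TRUE
        } else if (length(tok) == 2L) {
            fpos <- c(fpos, as.integer(tok[1L]))
            fnt <- c(fnt, tok[2L])
        } else stop("unparseable constraint line: ", ln)
    }
    if (is.null(region) || is.null(substructure))
        stop("constraint file must define a motif region and substructure")
    MotifConstraint(region, substructure, fpos, fnt, one_based = TRUE)
}

#' @rdname readConstraintFile
#' @param constraint a \linkS4class{MotifConstraint} to write.
#' @return \code{writeConstraintFile}: invisibly, \code{path}.
#' @export
writeConstraintFile <- function(constraint, path) {
    lines <- c(sprintf("motif %d %d", constraint@region[1L] + 1L,
                       constraint@region[2L]),
               constraint@substructure,
               sprintf("fix %d %s", constraint@fixed_positions + 1L,
                       constraint@fixed_nucleotides))
    writeLines(lines, path)
    invisible(path)
}

#' Derive the motif constraint for a structure region
#'
#' Convenience: takes the region's required substructure directly from the
#' target structure (the usual case -- protect the fragment as it is).
#'
#' @param structure the target \linkS4class{SecondaryStructure}.
#' @param region 0-based half-open interval.
#' @param fixed_positions,fixed_nucleotides optional fixed residues.
#' @return a \linkS4class{MotifConstraint}.
#' @export
motifConstraintFromStructure <- function(structure, region,
                                         fixed_positions = integer(0),
                                         fixed_nucleotides = character(0)) {
    region <- as.integer(region)
    if (region[1L] < 0L || region[2L] > length(structure))
        stop("region outside structure")
    MotifConstraint(region,
                    substr(structure@dotbracket, region[1L] + 1L, region[2L]),
                    fixed_positions, fixed_nucleotides)
}

#' Mutational-robustness (neutrality) score
#'
#' Mean over all 3L single-point mutants m of
#' \eqn{1 - d_{bp}(fold(m), fold(s)) / L}, clipped to [0, 1].  High values
#' mean the predicted structure is robust to point mutation.
#'
#' @param seq an \linkS4class{RNASequence}.
#' @param engine a \linkS4class{FoldEngine}.
#' @return numeric in [0, 1].
#' @export
neutrality <- function(seq, engine = nussinovEngine()) {
    if (is.character(seq)) seq <- RNASequence(seq)
    chars <- .rna_chars(seq@residues)
    L <- length(chars)
    ref <- foldMFE(seq, engine)$structure
    post <- .shapiro_post_cpp(ref@dotbracket)
    total <- 0
    for (p in seq_len(L)) {
        for (nt in setdiff(RNA_ALPHABET, chars[p])) {
            mut <- chars
            mut[p] <- nt
            f <- engine@fold(paste(mut, collapse = ""))
            d <- .structure_scores_cpp(f$dotbracket, ref@pairs,
                                       post$labels, post$lld)[1L]
            total <- total + (1 - d / L)
        }
    }
    min(1, max(0, total / (3 * L)))
}

#' Motif-absence indicator
#'
#' Returns 0 when the candidate structure reproduces the required
#' substructure exactly over the constraint region, 1 otherwise.  A missing
#' constraint is vacuously satisfied (0).  Interpreted as a penalty
#' indicator: the protected fragment is a hard constraint to be fulfilled
#' without compromise, so its violation is what the objective charges for.
#'
#' @param candidate a \linkS4class{SecondaryStructure}.
#' @param constraint a \linkS4class{MotifConstraint} or NULL.
#' @return integer 0 or 1.
#' @export
motifMissing <- function(candidate, constraint = NULL) {
    if (is.null(constraint)) return(0L)
    r <- constraint@region
    if (r[2L] > length(candidate))
        stop("constraint region outside candidate structure")
    got <- substr(candidate@dotbracket, r[1L] + 1L, r[2L])
    if (identical(got, constraint@substructure)) 0L else 1L
}

#' Combine measured quantities into the objective breakdown
#'
#' Pure arithmetic of the five-term objective
#' \deqn{f = 100 |\Delta neutrality| + |\Delta dG| + 1000 \cdot motif +
#'   100 \cdot d_{Shapiro} + 0.01 \cdot d_{bp}}
#' with disabled terms contributing zero.
#'
#' @param dneutrality absolute neutrality difference.
#' @param ddG absolute dG difference (kcal/mol or engine units).
#' @param motif_missing 0/1 motif-absence indicator.
#' @param shapiro_dist Shapiro tree edit distance.
#' @param bp_dist base-pair distance.
#' @param weights an \linkS4class{ObjectiveWeights}.
#' @return an \linkS4class{ObjectiveBreakdown}.
#' @examples
#' w <- ObjectiveWeights()
#' objectiveTotal(objectiveBreakdown(0, 0, 0, 2, 14, w))  # 200.14
#' @export
objectiveBreakdown <- function(dneutrality, ddG, motif_missing, shapiro_dist,
                               bp_dist, weights = ObjectiveWeights()) {
    nt <- if (weights@enable_neutrality)
        weights@w_neutrality * abs(dneutrality) else 0
    gt <- if (weights@enable_dG) weights@w_dG * abs(ddG) else 0
    mt <- weights@w_motif * motif_missing
    st <- weights@w_shapiro * shapiro_dist
    bt <- weights@w_bp * bp_dist
    new("ObjectiveBreakdown", neutrality_term = nt, dG_term = gt,
        motif_term = mt, shapiro_term = st, bp_term = bt,
        total = nt + gt + mt + st + bt)
}

#' @describeIn objectiveBreakdown total objective value accessor.
#' @param x an ObjectiveBreakdown.
#' @export
setMethod("objectiveTotal", "ObjectiveBreakdown", function(x) x@total)

setMethod("show", "ObjectiveBreakdown", function(object) {
    cat(sprintf(paste0("ObjectiveBreakdown: total %.4f (neutrality %.3f, ",
                       "dG %.3f, motif %.0f, shapiro %.0f, bp %.4f)\n"),
                object@total, object@neutrality_term, object@dG_term,
                object@motif_term, object@shapiro_term, object@bp_term))
})

# normalise a candidate/target argument to list(seq, structure, dG)
.as_folded <- function(x, engine) {
    if (is(x, "RNASequence")) {
        f <- foldMFE(x, engine)
        return(list(seq = x, structure = f$structure, dG = f$dG))
    }
    if (is.list(x)) {
        seq <- x$seq %||% x$sequence
        if (is.character(seq)) seq <- RNASequence(seq)
        structure <- x$structure
        dG <- x$dG
        if (is.null(structure)) {
            f <- foldMFE(seq, engine)
            structure <- f$structure
            if (is.null(dG)) dG <- f$dG
        }
        if (is.null(dG)) dG <- NA_real_
        return(list(seq = seq, structure = structure, dG = dG))
    }
    stop("expected an RNASequence or list(seq, structure, dG)")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate the design objective for a candidate against the target
#'
#' Folds are taken as supplied (the candidate structure must be the engine's
#' fold of the candidate sequence) or computed with \code{engine} when
#' absent.  With the default weights the objective depends on the candidate
#' sequence only through its predicted structure, and is zero exactly when
#' the candidate reproduces the target structure with the motif present.
#'
#' @param candidate,target an \linkS4class{RNASequence} or a
#'   \code{list(seq=, structure=, dG=)} triple.
#' @param constraint optional \linkS4class{MotifConstraint}.
#' @param weights an \linkS4class{ObjectiveWeights}.
#' @param engine a \linkS4class{FoldEngine}, used to fold missing structures
#'   and to compute neutrality when that term is enabled.
#' @return an \linkS4class{ObjectiveBreakdown}.
#' @export
evaluateObjective <- function(candidate, target, constraint = NULL,
                              weights = ObjectiveWeights(),
                              engine = nussinovEngine()) {
    cand <- .as_folded(candidate, engine)
    targ <- .as_folded(target, engine)
    if (length(cand$structure) != length(targ$structure))
        stop("candidate and target must have equal length")
    dneut <- if (weights@enable_neutrality)
        abs(neutrality(targ$seq, engine) - neutrality(cand$seq, engine)) else 0
    ddG <- if (weights@enable_dG) abs(targ$dG - cand$dG) else 0
    objectiveBreakdown(
        dneutrality = dneut, ddG = ddG,
        motif_missing = motifMissing(cand$structure, constraint),
        shapiro_dist = treeEditDistance(targ$structure, cand$structure),
        bp_dist = basePairDistance(targ$structure, cand$structure),
        weights = weights)
}
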