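# Escape-the-well mutation operators: random escape and the
# structure-preserving covariant special case.

setMethod("show", "EscapeTrace", function(object) {
    cat(sprintf("EscapeTrace: %d mutation(s), final hit count %d\n",
                nrow(object@mutation_path),
                if (length(object@hits_at_each_step))
                    object@hits_at_each_step[length(object@hits_at_each_step)]
                else NA_integer_))
})

.apply_mutation <- function(chars, pos1, nt) {
    chars[pos1] <- nt
    chars
}

#' Escape the similarity well by successive random point mutations
#'
#' Performs successive single-point random mutations (uniform position,
#' uniform different nucleotide) until the mutated sequence has no database
#' hits at the configured E-value cutoff, re-querying after every mutation.
#' A query that already has no hits returns a zero-length trace.
#'
#' @param seq the starting \linkS4class{RNASequence}.
#' @param db a \linkS4class{SearchDatabase}.
#' @param params a \linkS4class{SearchParams}.
#' @param max_mutations mutation budget; default 3 x sequence length.  If
#'   hits remain when it is exhausted an error of class
#'   \code{riboseekEscapeBudgetError} carrying the partial trace (field
#'   \code{trace}) is signalled.
#' @param rng_seed optional seed making the walk replayable.
#' @return an \linkS4class{EscapeTrace} whose end sequence has zero hits.
#' @export
randomEscape <- function(seq, db, params = SearchParams(),
                         max_mutations = 3L * length(seq), rng_seed = NULL) {
    if (is.character(seq)) seq <- RNASequence(seq)
    L <- length(seq)
    n_hits <- nrow(searchHits(seq, db, params))
    if (n_hits == 0L)
        return(new("EscapeTrace", start = seq, end = seq,
                   mutation_path = data.frame(position = integer(0),
                                              from = character(0),
                                              to = character(0)),
                   hits_at_each_step = integer(0)))
    .with_seed(rng_seed, {
        chars <- .rna_chars(seq@residues)
        path_pos <- integer(0); path_from <- character(0)
        path_to <- character(0); hits <- integer(0)
        repeat {
            if (length(path_pos) >= max_mutations) {
                partial <- new("EscapeTrace", start = seq,
                    end = RNASequence(paste(chars, collapse = ""),
                                      id = paste0(seq@id, "_escape_partial")),
                    mutation_path = data.frame(position = path_pos,
                                               from = path_from,
                                               to = path_to),
                    hits_at_each_step = hits)
                stop(errorCondition(
                    sprintf("escape budget of %d mutations exhausted with %d hit(s) remaining",
                            max_mutations,
                            if (length(hits)) hits[length(hits)] else n_hits),
                    trace = partial,
                    class = c("riboseekEscapeBudgetError", "error",
                              "condition")))
            }
            p <- sample.int(L, 1L)
            nt <- setdiff(RNA_ALPHABET, chars[p])[sample.int(3L, 1L)]
            path_pos <- c(path_pos, p - 1L)
            path_from <- c(path_from, chars[p])
            path_to <- c(path_to, nt)
            chars[p] <- nt
            h <- nrow(searchHits(paste(chars, collapse = ""), db, params))
            hits <- c(hits, h)
            if (h == 0L) break
        }
        new("EscapeTrace", start = seq,
            end = RNASequence(paste(chars, collapse = ""),
                              id = paste0(seq@id, "_escape")),
            mutation_path = data.frame(position = path_pos, from = path_from,
                                       to = path_to),
            hits_at_each_step = hits)
    })
}

#' One structure-preserving (covariant) mutation
#'
#' Either replaces one base pair of the reference structure by a different
#' pair drawn from AU, UA, GC, CG, GU, UG (wobble pairs admitted because
#' riboswitch stems contain them; disable with \code{allow_wobble = FALSE}),
#' or point-mutates one unpaired position.  The mutant is refolded with the
#' engine and returned only if its predicted structure has base-pair
#' distance 0 to the reference; otherwise the move is re-drawn up to
#' \code{max_retries} times.
#'
#' @param seq the \linkS4class{RNASequence} to mutate.
#' @param structure the reference \linkS4class{SecondaryStructure} (the fold
#'   of \code{seq}, or a declared reference).
#' @param engine a \linkS4class{FoldEngine}.
#' @param frozen 0-based positions excluded from mutation (e.g. a conserved
#'   ligand-binding core).
#' @param allow_wobble admit GU/UG replacement pairs.
#' @param max_retries retry budget before giving up with an error.
#' @param rng_seed optional seed.
#' @return the mutated \linkS4class{RNASequence}, guaranteed to refold to
#'   \code{structure}.
#' @export
covariantMutate <- function(seq, structure, engine = nussinovEngine(),
                            frozen = integer(0), allow_wobble = TRUE,
                            max_retries = 50L, rng_seed = NULL) {
    if (is.character(seq)) seq <- RNASequence(seq)
    L <- length(seq)
    if (L != length(structure))
        stop("sequence and structure must have equal length")
    pairs <- structure@pairs
    frozen1 <- frozen + 1L
    pset <- if (allow_wobble) PAIR_SET else PAIR_SET[1:4]
    keep <- if (nrow(pairs))
        !(pairs[, 1L] + 1L) %in% frozen1 & !(pairs[, 2L] + 1L) %in% frozen1
        else logical(0)
    pairs <- pairs[keep, , drop = FALSE]
    paired_pos <- if (nrow(structure@pairs))
        c(structure@pairs[, 1L], structure@pairs[, 2L]) + 1L else integer(0)
    unpaired <- setdiff(setdiff(seq_len(L), paired_pos), frozen1)
    n_sites <- nrow(pairs) + length(unpaired)
    if (n_sites == 0L) stop("no mutable site outside the frozen set")

    .with_seed(rng_seed, {
        chars0 <- .rna_chars(seq@residues)
        for (try in seq_len(max_retries)) {
            chars <- chars0
            s <- sample.int(n_sites, 1L)
            if (s <= nrow(pairs)) {
                i <- pairs[s, 1L] + 1L; j <- pairs[s, 2L] + 1L
                alt <- setdiff(pset, paste0(chars[i], chars[j]))
                np <- alt[sample.int(length(alt), 1L)]
                chars[i] <- substr(np, 1, 1)
                chars[j] <- substr(np, 2, 2)
            } else {
                p <- unpaired[s - nrow(pairs)]
                alt <- setdiff(RNA_ALPHABET, chars[p])
                chars[p] <- alt[sample.int(3L, 1L)]
            }
            mut <- paste(chars, collapse = "")
            fold <- foldMFE(mut, engine)$structure
            if (basePairDistance(fold, structure) == 0L)
                return(RNASequence(mut, id = seq@id,
                                   description = seq@description))
        }
        stop("no structure-preserving mutation found in ", max_retries,
             " retries")
    })
}

#' Escape the similarity well with covariant mutations only
#'
#' The special-case escape: successive structure-preserving mutations until
#' the sequence has no database hits.  Every intermediate folds exactly to
#' the reference structure, so the whole walk doubles as a set of designed
#' sequences.
#'
#' @inheritParams randomEscape
#' @param structure reference \linkS4class{SecondaryStructure} preserved by
#'   every step.
#' @param engine a \linkS4class{FoldEngine}.
#' @param frozen 0-based positions excluded from mutation.
#' @return list with \code{trace} (an \linkS4class{EscapeTrace}) and
#'   \code{intermediates} (list of \linkS4class{RNASequence}, one per step).
#' @export
covariantEscape <- function(seq, structure, db, params = SearchParams(),
                            engine = nussinovEngine(), frozen = integer(0),
                            max_mutations = 3L * length(seq),
                            rng_seed = NULL) {
    if (is.character(seq)) seq <- RNASequence(seq)
    n_hits <- nrow(searchHits(seq, db, params))
    empty <- list(trace = new("EscapeTrace", start = seq, end = seq,
                              mutation_path = data.frame(position = integer(0),
                                                         from = character(0),
                                                         to = character(0)),
                              hits_at_each_step = integer(0)),
                  intermediates = list())
    if (n_hits == 0L) return(empty)
    .with_seed(rng_seed, {
        cur <- seq
        inter <- list()
        path_pos <- integer(0); path_from <- character(0)
        path_to <- character(0); hits <- integer(0)
        repeat {
            if (length(hits) >= max_mutations)
                stop(errorCondition(
                    sprintf("covariant escape budget of %d mutations exhausted with hits remaining",
                            max_mutations),
                    class = c("riboseekEscapeBudgetError", "error",
                              "condition")))
            nxt <- covariantMutate(cur, structure, engine, frozen = frozen)
            diff <- which(.rna_chars(cur@residues) != .rna_chars(nxt@residues))
            for (p in diff) {
                path_pos <- c(path_pos, p - 1L)
                path_from <- c(path_from,
                               substr(cur@residues, p, p))
                path_to <- c(path_to, substr(nxt@residues, p, p))
            }
            cur <- nxt
            inter[[length(inter) + 1L]] <- cur
            h <- nrow(searchHits(cur, db, params))
            hits <- c(hits, rep(h, length(diff)))
            if (h == 0L) break
        }
        list(trace = new("EscapeTrace", start = seq,
                         end = RNASequence(cur@residues,
                                           id = paste0(seq@id, "_covescape")),
                         mutation_path = data.frame(position = path_pos,
                                                    from = path_from,
                                                    to = path_to),
                         hits_at_each_step = hits),
             intermediates = inter)
    })
}

#' Restore a region of a mutated sequence toward the original
#'
#' The output equals \code{mutated} outside \code{region} and \code{original}
#' inside it -- the move used to bring an escaped sequence back to the
#' borderline of the similarity well.
#'
#' @param mutated,original equal-length \linkS4class{RNASequence} objects.
#' @param region integer(2), 0-based half-open interval.
#' @return the spliced \linkS4class{RNASequence}.
#' @export
restoreRegion <- function(mutated, original, region) {
    if (is.character(mutated)) mutated <- RNASequence(mutated)
    if (is.character(original)) original <- RNASequence(original)
    if (length(mutated) != length(original))
        stop("sequences must have equal length")
    region <- as.integer(region)
    L <- length(mutated)
    if (region[1L] < 0L || region[2L] > L || region[2L] < region[1L])
        stop("invalid region")
    if (region[2L] == region[1L]) return(mutated)
    chars <- .rna_chars(mutated@residues)
    orig <- .rna_chars(original@residues)
    idx <- (region[1L] + 1L):region[2L]
    chars[idx] <- orig[idx]
    RNASequence(paste(chars, collapse = ""),
                id = paste0(mutated@id, "_restored"))
}
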