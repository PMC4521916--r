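# Flexible inverse folding: simulated annealing over sequence space.

PAIR_SET <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Construct a simulated annealing schedule
#'
#' Defaults: initial temperature 10, geometric cooling by 0.95 every 50
#' iterations, at most 10000 objective evaluations, look-ahead width 4
#' (proposals bundle up to four jointly mutated positions).
#'
#' @param initial_temperature starting temperature.
#' @param cooling_factor geometric cooling factor in (0, 1).
#' @param steps_per_temperature iterations between cooling steps.
#' @param max_iterations budget on objective evaluations.
#' @param lookahead_width maximum positions mutated per proposal.
#' @param rng_seed integer seed.
#' @return an \linkS4class{AnnealSchedule}.
#' @export
AnnealSchedule <- function(initial_temperature = 10, cooling_factor = 0.95,
                           steps_per_temperature = 50L,
                           max_iterations = 10000L, lookahead_width = 4L,
                           rng_seed = 1L) {
    new("AnnealSchedule", initial_temperature = initial_temperature,
        cooling_factor = cooling_factor,
        steps_per_temperature = as.integer(steps_per_temperature),
        max_iterations = as.integer(max_iterations),
        lookahead_width = as.integer(lookahead_width),
        rng_seed = as.integer(rng_seed))
}

setMethod("show", "DesignResult", function(object) {
    cat(sprintf("DesignResult from seed '%s' (%s, objective %.4f, %d evals%s)\n",
                object@seed_sequence_id,
                if (object@converged) "converged" else "budget exhausted",
                object@breakdown@total, object@iterations_used,
                if (object@multiplicity > 1L)
                    sprintf(", x%d", object@multiplicity) else ""))
    cat(" ", object@sequence@residues, "\n")
    cat(" ", object@structure@dotbracket, "\n")
})

# Target-side precomputation shared by all evaluations of one run.
.design_context <- function(target_structure, constraint, weights, engine,
                            target_seq = NULL) {
    post <- .shapiro_post_cpp(target_structure@dotbracket)
    ctx <- list(
        structure = target_structure,
        post = post,
        pairs = target_structure@pairs,
        constraint = constraint, weights = weights, engine = engine,
        t_neut = NA_real_, t_dG = NA_real_)
    if (weights@enable_neutrality || weights@enable_dG) {
        if (is.null(target_seq))
            stop("target sequence required when neutrality or dG terms are ",
                 "enabled")
        if (weights@enable_neutrality)
            ctx$t_neut <- neutrality(target_seq, engine)
        if (weights@enable_dG)
            ctx$t_dG <- foldMFE(target_seq, engine)$dG
    }
    ctx
}

# Evaluate one candidate residue vector against the context; returns the
# measured quantities plus the raw fold, cheap enough for the annealing
# loop (structure S4 objects are only built for the returned best).
.design_eval <- function(chars, ctx) {
    res <- paste(chars, collapse = "")
    fold <- ctx$engine@fold(res)
    sc <- .structure_scores_cpp(fold$dotbracket, ctx$pairs,
                                ctx$post$labels, ctx$post$lld)
    bp <- sc[1L]; shap <- sc[2L]
    motif <- 0L
    if (!is.null(ctx$constraint)) {
        r <- ctx$constraint@region
        got <- substr(fold$dotbracket, r[1L] + 1L, r[2L])
        motif <- if (identical(got, ctx$constraint@substructure)) 0L else 1L
    }
    w <- ctx$weights
    dneut <- if (w@enable_neutrality)
        abs(ctx$t_neut - neutrality(res, ctx$engine)) else 0
    ddG <- if (w@enable_dG) abs(ctx$t_dG - fold$dG) else 0
    total <- (if (w@enable_neutrality) w@w_neutrality * dneut else 0) +
             (if (w@enable_dG) w@w_dG * ddG else 0) +
             w@w_motif * motif + w@w_shapiro * shap + w@w_bp * bp
    list(total = total, fold = fold, dneut = dneut, ddG = ddG,
         motif = motif, shap = shap, bp = bp)
}

#' Design a sequence folding into a target structure
#'
#' Simulated annealing over sequence space minimising the five-term design
#' objective.  Moves are shape-preserving by construction bias: positions
#' paired in the target mutate as compensatory pair substitutions (drawn
#' from AU, UA, GC, CG, GU, UG), unpaired positions mutate singly; each
#' proposal bundles up to \code{lookahead_width} jointly mutated positions
#' and is accepted by the Metropolis rule on the objective change at the
#' current temperature.  Fixed nucleotide positions are never mutated.  The
#' best sequence visited is returned; the run is deterministic given
#' \code{schedule@rng_seed} and exits early when the objective reaches 0.
#'
#' @param target the target \linkS4class{SecondaryStructure}, or a list
#'   \code{list(structure=, seq=)} when the neutrality/dG terms need the
#'   target sequence.
#' @param seed the starting \linkS4class{RNASequence} (same length as the
#'   target structure).
#' @param constraint optional \linkS4class{MotifConstraint}; fixed
#'   nucleotides are imposed on the seed before the first iteration.
#' @param schedule an \linkS4class{AnnealSchedule}.
#' @param engine a \linkS4class{FoldEngine}.
#' @param weights an \linkS4class{ObjectiveWeights}.
#' @return a \linkS4class{DesignResult}.
#' @export
inverseFold <- function(target, seed, constraint = NULL,
                        schedule = AnnealSchedule(),
                        engine = nussinovEngine(),
                        weights = ObjectiveWeights()) {
    if (is(target, "SecondaryStructure"))
        target <- list(structure = target, seq = NULL)
    tstruct <- target$structure
    if (is.character(seed)) seed <- RNASequence(seed)
    L <- length(seed)
    if (L != length(tstruct))
        stop("seed length must equal the target structure length")

    chars <- .rna_chars(seed@residues)
    fixed <- rep(FALSE, L)
    if (!is.null(constraint)) {
        validObject(constraint)
        fp <- constraint@fixed_positions
        if (length(fp) && (any(fp < 0L) || any(fp >= L)))
            stop("fixed position outside the sequence")
        if (length(fp)) {
            chars[fp + 1L] <- constraint@fixed_nucleotides
            fixed[fp + 1L] <- TRUE
        }
    }

    ctx <- .design_context(tstruct, constraint, weights, engine, target$seq)

    # move sites: target pairs (compensatory) and target-unpaired positions
    tp <- tstruct@pairs
    pair_sites <- list()
    if (nrow(tp)) for (r in seq_len(nrow(tp))) {
        i <- tp[r, 1L] + 1L; j <- tp[r, 2L] + 1L
        allowed <- PAIR_SET
        if (fixed[i]) allowed <- allowed[substr(allowed, 1, 1) == chars[i]]
        if (fixed[j]) allowed <- allowed[substr(allowed, 2, 2) == chars[j]]
        if (length(allowed) >= 2L)
            pair_sites[[length(pair_sites) + 1L]] <-
                list(i = i, j = j, allowed = allowed)
    }
    paired_pos <- if (nrow(tp)) c(tp[, 1L], tp[, 2L]) + 1L else integer(0)
    unpaired_sites <- setdiff(which(!fixed), paired_pos)
    n_sites <- length(pair_sites) + length(unpaired_sites)

    .with_seed(schedule@rng_seed, {
        ev <- .design_eval(chars, ctx)
        iter <- 1L
        cur <- chars; cur_total <- ev$total
        best <- ev; best_chars <- chars; best_iter <- iter
        Temp <- schedule@initial_temperature

        while (best$total > 0 && iter < schedule@max_iterations && n_sites > 0) {
            k <- sample.int(schedule@lookahead_width, 1L)
            prop <- cur
            for (t in seq_len(k)) {
                s <- sample.int(n_sites, 1L)
                if (s <= length(pair_sites)) {
                    site <- pair_sites[[s]]
                    curpair <- paste0(prop[site$i], prop[site$j])
                    alt <- setdiff(site$allowed, curpair)
                    if (!length(alt)) next
                    np <- alt[sample.int(length(alt), 1L)]
                    prop[site$i] <- substr(np, 1, 1)
                    prop[site$j] <- substr(np, 2, 2)
                } else {
                    p <- unpaired_sites[s - length(pair_sites)]
                    alt <- setdiff(RNA_ALPHABET, prop[p])
                    prop[p] <- alt[sample.int(3L, 1L)]
                }
            }
            pev <- .design_eval(prop, ctx)
            iter <- iter + 1L
            d <- pev$total - cur_total
            if (d <= 0 || stats::runif(1) < exp(-d / Temp)) {
                cur <- prop; cur_total <- pev$total
            }
            if (pev$total < best$total) {
                best <- pev; best_chars <- prop; best_iter <- iter
            }
            if (iter %% schedule@steps_per_temperature == 0L)
                Temp <- Temp * schedule@cooling_factor
        }

        breakdown <- objectiveBreakdown(best$dneut, best$ddG, best$motif,
                                        best$shap, best$bp, weights)
        new("DesignResult",
            sequence = RNASequence(paste(best_chars, collapse = ""),
                                   id = paste0(seed@id, "_design")),
            structure = parseDotBracket(best$fold$dotbracket),
            dG = best$fold$dG,
            breakdown = breakdown, iterations_used = iter,
            seed_sequence_id = seed@id, converged = best$total == 0,
            multiplicity = 1L)
    })
}

#' Run the inverse-folding solver over a batch of seeds
#'
#' Each seed is sent to the solver \code{runs_per_seed} times, each run
#' independently seeded by a deterministic function of the schedule seed,
#' the seed index and the run index.  Designs identical in sequence are
#' collapsed, with multiplicity recorded.
#'
#' @param target as in \code{\link{inverseFold}}.
#' @param seeds non-empty list of \linkS4class{RNASequence} seeds.
#' @param runs_per_seed solver runs per seed (>= 1).
#' @param constraint,schedule,engine,weights as in \code{\link{inverseFold}}.
#' @return list of unique \linkS4class{DesignResult} objects; multiplicities
#'   sum to \code{length(seeds) * runs_per_seed}.
#' @export
designBatch <- function(target, seeds, runs_per_seed = 20L, constraint = NULL,
                        schedule = AnnealSchedule(),
                        engine = nussinovEngine(),
                        weights = ObjectiveWeights()) {
    if (!length(seeds)) stop("empty seed list")
    runs_per_seed <- as.integer(runs_per_seed)
    if (runs_per_seed < 1L) stop("runs_per_seed must be >= 1")
    out <- list()
    index <- new.env(parent = emptyenv())
    for (i in seq_along(seeds)) {
        for (j in seq_len(runs_per_seed)) {
            sched <- schedule
            sched@rng_seed <- .derive_seed(schedule@rng_seed, i, j)
            res <- inverseFold(target, seeds[[i]], constraint, sched, engine,
                               weights)
            key <- res@sequence@residues
            if (is.null(index[[key]])) {
                out[[length(out) + 1L]] <- res
                index[[key]] <- length(out)
            } else {
                k <- index[[key]]
                out[[k]]@multiplicity <- out[[k]]@multiplicity + 1L
            }
        }
    }
    out
}
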