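# Orchestration of the full search flow: escape -> restore/design ->
# screen -> assess, in general and covariant modes, deterministically
# seeded per stage.

#' Construct a pipeline configuration
#'
#' Study-scale defaults are 500 escape traces with 20 solver runs each; a
#' small-profile run (e.g. \code{n_escape = 10, runs_per_seed = 2}) is
#' appropriate for continuous testing.
#'
#' @param query the known aptamer \linkS4class{RNASequence}.
#' @param reference its reference \linkS4class{SecondaryStructure}; default
#'   is the engine's fold of the query.
#' @param db the target \linkS4class{SearchDatabase}.
#' @param constraint optional \linkS4class{MotifConstraint}.
#' @param mode "general" or "covariant".
#' @param n_escape escape traces to generate.
#' @param runs_per_seed inverse-folding runs per escaped seed.
#' @param search_params a \linkS4class{SearchParams}.
#' @param schedule an \linkS4class{AnnealSchedule}.
#' @param engine a \linkS4class{FoldEngine}.
#' @param rng_seed master seed.
#' @param max_mutations escape budget per trace.
#' @param output_dir optional directory persisting every stage's outputs.
#' @return a \linkS4class{PipelineConfig}.
#' @export
PipelineConfig <- function(query, db, reference = NULL, constraint = NULL,
                           mode = c("general", "covariant"),
                           n_escape = 500L, runs_per_seed = 20L,
                           search_params = SearchParams(),
                           schedule = AnnealSchedule(),
                           engine = nussinovEngine(), rng_seed = 1L,
                           max_mutations = NULL, output_dir = NA_character_) {
    if (is.character(query)) query <- RNASequence(query)
    if (is.null(reference)) reference <- foldMFE(query, engine)$structure
    if (is.null(max_mutations)) max_mutations <- 3L * length(query)
    new("PipelineConfig", query = query, reference = reference,
        constraint = constraint, db = db, mode = match.arg(mode),
        n_escape = as.integer(n_escape),
        runs_per_seed = as.integer(runs_per_seed),
        search_params = search_params, schedule = schedule, engine = engine,
        rng_seed = as.integer(rng_seed),
        max_mutations = as.integer(max_mutations),
        output_dir = as.character(output_dir))
}

setMethod("show", "PipelineConfig", function(object) {
    cat(sprintf(paste0("PipelineConfig: %s mode, query %s (%d nt), ",
                       "%d record(s), %d x %d runs, engine %s, seed %d\n"),
                object@mode, object@query@id, length(object@query),
                length(object@db@ids), object@n_escape,
                object@runs_per_seed, object@engine@name, object@rng_seed))
})

#' Sanity checks before a search run
#'
#' Recomputes the query's fold with the configured engine and compares it
#' to the supplied reference (base-pair and Shapiro distances), and counts
#' the query's own database hits.  Warns -- without aborting -- when the
#' fold disagrees with the reference beyond the candidate threshold or when
#' the query has no hits.
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @param max_shapiro warning threshold on the fold/reference Shapiro
#'   distance.
#' @return list with \code{bp_distance}, \code{shapiro_distance},
#'   \code{dG}, \code{n_hits} and \code{warnings} (character vector).
#' @export
preflight <- function(config, max_shapiro = 2L) {
    fold <- foldMFE(config@query, config@engine)
    bp <- basePairDistance(fold$structure, config@reference)
    shap <- treeEditDistance(fold$structure, config@reference)
    n_hits <- nrow(searchHits(config@query, config@db,
                              config@search_params))
    warnings <- character(0)
    if (shap > max_shapiro)
        warnings <- c(warnings, sprintf(
            "query fold disagrees with the reference structure (Shapiro distance %d)",
            shap))
    if (n_hits == 0L)
        warnings <- c(warnings,
                      "query has no database hits; nothing to escape from")
    for (w in warnings) warning(w, call. = FALSE)
    list(bp_distance = bp, shapiro_distance = shap, dG = fold$dG,
         n_hits = n_hits, warnings = warnings)
}

# screen designed sequences and assess every non-self hit window
.screen_designs <- function(designs, config) {
    query <- config@query
    L <- length(query)
    reports <- list()
    known <- list()
    seen_windows <- new.env(parent = emptyenv())
    all_hits <- .empty_hits()
    for (d in designs) {
        dseq <- if (is(d, "DesignResult")) d@sequence else d
        hits <- searchHits(dseq, config@db, config@search_params)
        if (nrow(hits)) all_hits <- rbind(all_hits, hits)
        for (h in seq_len(nrow(hits))) {
            hit <- hits[h, ]
            rec <- config@db@sequences[match(hit$record_id, config@db@ids)]
            win <- extractWindow(rec, hit, L)
            key <- paste(hit$record_id, win$location[1L], win$strand)
            if (!is.null(seen_windows[[key]])) next
            seen_windows[[key]] <- TRUE
            if (win$window@residues == query@residues) {
                known[[length(known) + 1L]] <- data.frame(
                    record_id = hit$record_id, start = win$location[1L],
                    end = win$location[2L], strand = win$strand,
                    e_value = hit$e_value, stringsAsFactors = FALSE)
                next
            }
            reports[[length(reports) + 1L]] <- assessCandidate(
                win$window, query, config@reference, config@engine,
                constraint = config@constraint,
                record_id = hit$record_id, location = win$location,
                strand = win$strand, e_value = hit$e_value)
        }
    }
    list(reports = rankCandidates(reports),
         known = if (length(known)) do.call(rbind, known) else NULL,
         hits = all_hits)
}

.persist_run <- function(config, designs, screened) {
    dir <- config@output_dir
    if (is.na(dir) || !nzchar(dir)) return(invisible(NULL))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    seqs <- lapply(designs, function(d)
        if (is(d, "DesignResult")) d@sequence else d)
    if (length(seqs)) {
        for (i in seq_along(seqs))
            if (!nzchar(seqs[[i]]@id)) seqs[[i]]@id <- sprintf("design_%04d", i)
        writeRNAFasta(seqs, file.path(dir, "designs.fasta"))
    }
    writeHitsTable(screened$hits, file.path(dir, "hits.tsv"))
    utils::write.table(candidateTable(screened$reports),
                       file.path(dir, "candidates.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(screened$known))
        utils::write.table(screened$known, file.path(dir, "known.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(sprintf("mode=%s seed=%d n_escape=%d runs_per_seed=%d engine=%s",
                       config@mode, config@rng_seed, config@n_escape,
                       config@runs_per_seed, config@engine@name),
               file.path(dir, "run.log"))
    invisible(NULL)
}

#' Run the general (inverse-folding) search pipeline
#'
#' Executes the full flow: \code{n_escape} random escape traces from the
#' query, inverse-folding restoration of each escaped sequence
#' (\code{runs_per_seed} runs each), screening of every unique design
#' against the database, and structural assessment of every hit window that
#' is not an exact copy of the query (exact copies are reported separately
#' as known sites).  Fully reproducible from the master seed; designs with
#' zero hits are simply uninformative, not errors.
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @return ranked list of \linkS4class{CandidateReport} objects, with the
#'   known-site table in \code{attr(, "known")} and the design list in
#'   \code{attr(, "designs")}.
#' @export
runGeneral <- function(config) {
    stopifnot(config@mode == "general")
    base <- config@rng_seed
    seeds <- lapply(seq_len(config@n_escape), function(i) {
        tr <- randomEscape(config@query, config@db, config@search_params,
                           max_mutations = config@max_mutations,
                           rng_seed = .derive_seed(base, 1L, i))
        end <- tr@end
        end@id <- sprintf("escape_%03d", i)
        end
    })
    sched <- config@schedule
    sched@rng_seed <- .derive_seed(base, 2L)
    designs <- designBatch(list(structure = config@reference,
                                seq = config@query),
                           seeds, config@runs_per_seed,
                           constraint = config@constraint, schedule = sched,
                           engine = config@engine)
    screened <- .screen_designs(designs, config)
    .persist_run(config, designs, screened)
    out <- screened$reports
    attr(out, "known") <- screened$known
    attr(out, "designs") <- designs
    out
}

#' Run the covariant special-case pipeline
#'
#' As \code{\link{runGeneral}}, but both the escape and the way back use
#' only structure-preserving covariant mutations, so every designed
#' sequence folds exactly to the query's reference structure and no
#' inverse-folding solver is needed.  The designed set is the union of all
#' intermediate sequences along each escape walk.
#'
#' @param config a \linkS4class{PipelineConfig} with
#'   \code{mode = "covariant"}.
#' @return as \code{\link{runGeneral}}.
#' @export
runCovariant <- function(config) {
    stopifnot(config@mode == "covariant")
    base <- config@rng_seed
    designs <- list()
    index <- new.env(parent = emptyenv())
    for (i in seq_len(config@n_escape)) {
        esc <- covariantEscape(config@query, config@reference, config@db,
                               config@search_params, config@engine,
                               max_mutations = config@max_mutations,
                               rng_seed = .derive_seed(base, 1L, i))
        for (s in esc$intermediates) {
            if (is.null(index[[s@residues]])) {
                index[[s@residues]] <- TRUE
                s@id <- sprintf("covdesign_%04d", length(designs) + 1L)
                designs[[length(designs) + 1L]] <- s
            }
        }
    }
    screened <- .screen_designs(designs, config)
    .persist_run(config, designs, screened)
    out <- screened$reports
    attr(out, "known") <- screened$known
    attr(out, "designs") <- designs
    out
}

#' Run the configured pipeline mode
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @return as \code{\link{runGeneral}}.
#' @export
runPipeline <- function(config) {
    if (config@mode == "general") runGeneral(config) else runCovariant(config)
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys: \code{query} (FASTA), \code{structure} (Vienna file, optional),
#' \code{database} (FASTA), \code{constraint} (constraint file, optional),
#' \code{mode}, \code{n_escape}, \code{runs_per_seed}, \code{engine}
#' (builtin|vienna), \code{rng_seed}, \code{word_size}, \code{e_cutoff},
#' \code{max_iterations}, \code{output_dir}.  Relative paths resolve
#' against the YAML file's directory.
#'
#' @param path YAML configuration path.
#' @return a \linkS4class{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    root <- dirname(normalizePath(path))
    resolve <- function(p) {
        if (is.null(p)) return(NULL)
        if (file.exists(p)) p else file.path(root, p)
    }
    query <- readRNAFasta(resolve(cfg$query))[[1L]]
    engine <- foldEngine(cfg$engine %||% "builtin")
    reference <- if (!is.null(cfg$structure))
        readViennaStructure(resolve(cfg$structure))$structure else NULL
    constraint <- if (!is.null(cfg$constraint))
        readConstraintFile(resolve(cfg$constraint)) else NULL
    params <- SearchParams(word_size = cfg$word_size %||% 7L,
                           e_cutoff = cfg$e_cutoff %||% 10,
                           search_space = cfg$search_space %||% NA_real_)
    db <- buildDatabase(resolve(cfg$database), word_size = params@word_size)
    schedule <- AnnealSchedule(
        max_iterations = cfg$max_iterations %||% 10000L,
        rng_seed = cfg$rng_seed %||% 1L)
    PipelineConfig(query, db, reference = reference, constraint = constraint,
                   mode = cfg$mode %||% "general",
                   n_escape = cfg$n_escape %||% 500L,
                   runs_per_seed = cfg$runs_per_seed %||% 20L,
                   search_params = params, schedule = schedule,
                   engine = engine, rng_seed = cfg$rng_seed %||% 1L,
                   output_dir = cfg$output_dir %||% NA_character_)
}
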