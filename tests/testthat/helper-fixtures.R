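# Shared study fixture: a small synthetic aptamer whose built-in-engine
# fold is a clean two-hairpin multibranch, plus the search parameters used
# for fixture databases (search space pinned to a genome-scale value so
# E-value significance matches a large database despite the small fixture).

synth_aptamer <- function() {
    RNASequence("AGACACCAUUCUAGUUGGUGCGAUUAGACCGGGAAGUUCGGGUUAUGGUGGGA",
                id = "synth_apt",
                description = "synthetic multibranch test aptamer")
}

# conserved ligand-binding core emulation: 0-based half-open
synth_core <- function() c(12L, 32L)

synth_reference <- function(engine = nussinovEngine()) {
    foldMFE(synth_aptamer(), engine)$structure
}

synth_constraint <- function(engine = nussinovEngine()) {
    apt <- synth_aptamer()
    core <- synth_core()
    motifConstraintFromStructure(
        synth_reference(engine), c(12L, 41L),
        fixed_positions = core[1L]:(core[2L] - 1L),
        fixed_nucleotides = strsplit(substr(residues(apt), core[1L] + 1L,
                                            core[2L]), "")[[1]])
}

fixture_params <- function() SearchParams(search_space = 1e10)

# one fixture database with planted diverged homologs; returns db + truth
make_fixture_db <- function(rng_seed, n_records = 4L, record_length = 600L,
                            n_planted = 2L, divergence_steps = 15L,
                            scrambled = FALSE, engine = nussinovEngine()) {
    fx <- generateFixture(synth_aptamer(), synth_reference(engine),
                          n_records = n_records,
                          record_length = record_length,
                          n_planted = n_planted,
                          divergence_steps = divergence_steps,
                          conserved_region = synth_core(),
                          scrambled = scrambled, engine = engine,
                          rng_seed = rng_seed)
    list(db = buildDatabase(fx$sequences), truth = fx$truth,
         sequences = fx$sequences)
}

# does any accepted report overlap a truth interval by > half the aptamer?
planted_recovered <- function(reports, truth, min_overlap = 27L) {
    tab <- candidateTable(reports)
    if (!nrow(tab)) return(FALSE)
    any(apply(truth, 1L, function(tr) any(
        tab$record_id == tr[["record_id"]] & tab$verdict &
        pmin(tab$end, as.integer(tr[["end"]])) -
            pmax(tab$start, as.integer(tr[["start"]])) >= min_overlap)))
}

ci_pipeline_config <- function(db, mode, rng_seed,
                               engine = nussinovEngine()) {
    PipelineConfig(synth_aptamer(), db,
                   reference = synth_reference(engine),
                   constraint = synth_constraint(engine), mode = mode,
                   n_escape = 10L, runs_per_seed = 2L,
                   search_params = fixture_params(),
                   schedule = AnnealSchedule(max_iterations = 800L),
                   engine = engine, rng_seed = rng_seed)
}
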