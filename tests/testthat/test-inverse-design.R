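test_that("a seed already at the optimum is returned unchanged", {
    target <- parseDotBracket("(((...)))")
    seed <- RNASequence("GGGAAACCC", id = "perfect")
    r <- inverseFold(target, seed)
    expect_true(r@converged)
    expect_identical(residues(r@sequence), "GGGAAACCC")
    expect_identical(r@iterations_used, 1L)
    expect_identical(objectiveTotal(r@breakdown), 0)
})

test_that("the annealer restores a 9-nt hairpin from a homopolymer seed", {
    target <- parseDotBracket("(((...)))")
    r <- inverseFold(target, RNASequence("AAAAAAAAA", id = "toy"),
                     schedule = AnnealSchedule(rng_seed = 7))
    expect_identical(
        treeEditDistance(shapiroTree(r@structure), shapiroTree(target)), 0L)
    # the returned structure is the engine's fold of the returned sequence
    expect_identical(dotbracket(foldMFE(r@sequence)$structure),
                     dotbracket(r@structure))
})

test_that("identical inputs and seed give byte-identical designs", {
    target <- synth_reference()
    seed <- RNASequence(strrep("A", length(target)), id = "s")
    sch <- AnnealSchedule(rng_seed = 99, max_iterations = 300L)
    r1 <- inverseFold(target, seed, schedule = sch)
    r2 <- inverseFold(target, seed, schedule = sch)
    expect_identical(residues(r1@sequence), residues(r2@sequence))
    expect_identical(r1@iterations_used, r2@iterations_used)
    expect_identical(objectiveTotal(r1@breakdown),
                     objectiveTotal(r2@breakdown))
})

test_that("fixed positions are never mutated and the motif is honoured", {
    target <- synth_reference()
    con <- synth_constraint()
    set.seed(31)
    seed <- RNASequence(random_rna(length(target)), id = "rnd")
    r <- inverseFold(target, seed, constraint = con,
                     schedule = AnnealSchedule(rng_seed = 13,
                                               max_iterations = 1500L))
    chars <- strsplit(residues(r@sequence), "")[[1]]
    expect_identical(chars[con@fixed_positions + 1L], con@fixed_nucleotides)
    # constraint safety: below the motif weight, the motif region of the
    # fold must equal the required substructure exactly
    if (objectiveTotal(r@breakdown) < 1000) {
        got <- substr(dotbracket(r@structure), con@region[1L] + 1L,
                      con@region[2L])
        expect_identical(got, con@substructure)
    }
})

test_that("design batches conserve run counts and deduplicate by sequence", {
    target <- parseDotBracket("(((...)))")
    seeds <- list(RNASequence("GGGAAACCC", id = "a"),
                  RNASequence("AAAAAAAAA", id = "b"))
    res <- designBatch(target, seeds, runs_per_seed = 3L,
                       schedule = AnnealSchedule(rng_seed = 5))
    mult <- vapply(res, slot, integer(1), "multiplicity")
    expect_identical(sum(mult), 6L)
    expect_lte(length(res), 6L)
    expect_false(anyDuplicated(vapply(res, function(r)
        residues(r@sequence), character(1))) > 0)

    one <- designBatch(target, seeds[1], runs_per_seed = 1L)
    expect_identical(length(one), 1L)
    expect_error(designBatch(target, list(), 2L), "empty seed list")

    res2 <- designBatch(target, seeds, runs_per_seed = 3L,
                        schedule = AnnealSchedule(rng_seed = 5))
    expect_identical(vapply(res, function(r) residues(r@sequence), ""),
                     vapply(res2, function(r) residues(r@sequence), ""))
})

test_that("schedule invariants are enforced", {
    expect_error(AnnealSchedule(initial_temperature = 0), "initial_temperature")
    expect_error(AnnealSchedule(cooling_factor = 1), "cooling_factor")
    expect_error(AnnealSchedule(lookahead_width = 0L), "lookahead")
    expect_error(inverseFold(parseDotBracket("(((...)))"),
                             RNASequence("ACGU")), "length")
})
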