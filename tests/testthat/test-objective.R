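test_that("neutrality is the mean structural robustness of single mutants", {
    # every 4-nt mutant folds open (no admissible hairpin): neutrality 1
    expect_identical(neutrality("AAAA"), 1)
    set.seed(5)
    for (i in 1:3) {
        v <- neutrality(random_rna(12))
        expect_gte(v, 0)
        expect_lte(v, 1)
    }
    # a strong short hairpin loses pairs under some mutations
    expect_lt(neutrality("GGGGAAAACCCC"), 1)
})

test_that("motif-absence indicator compares the constraint region exactly", {
    target <- parseDotBracket("..((..((...))..((...))..))..")
    con <- motifConstraintFromStructure(target, c(4L, 24L))
    expect_identical(motifMissing(target, con), 0L)
    # same length, region folded differently
    other <- parseDotBracket("..((((((.....))..((...))))))")
    expect_identical(motifMissing(other, con), 1L)
    expect_identical(motifMissing(other, NULL), 0L)
    expect_error(motifMissing(parseDotBracket("..."), con), "region")
})

test_that("objective arithmetic reproduces hand-computed totals", {
    w_all <- ObjectiveWeights(enable_neutrality = TRUE, enable_dG = TRUE)
    b <- objectiveBreakdown(0.1, 2.0, 1, 3, 10, w_all)
    expect_equal(objectiveTotal(b), 1312.1)
    expect_equal(b@neutrality_term, 10)
    expect_equal(b@dG_term, 2)
    expect_equal(b@motif_term, 1000)
    expect_equal(b@shapiro_term, 300)
    expect_equal(b@bp_term, 0.1)

    # default flags: neutrality and dG contribute nothing
    b2 <- objectiveBreakdown(0.5, 7, 0, 2, 14, ObjectiveWeights())
    expect_equal(objectiveTotal(b2), 200.14)

    expect_equal(objectiveTotal(objectiveBreakdown(0, 0, 0, 0, 0)), 0)
})

test_that("objective is zero exactly on structure-identical motif-satisfying candidates", {
    apt <- synth_aptamer()
    con <- synth_constraint()
    b <- evaluateObjective(apt, apt, constraint = con)
    expect_identical(objectiveTotal(b), 0)

    # a shuffled candidate of the same length scores positive
    set.seed(2)
    shuf <- RNASequence(paste(sample(strsplit(residues(apt), "")[[1]]),
                              collapse = ""))
    expect_gt(objectiveTotal(evaluateObjective(shuf, apt, constraint = con)),
              0)
    expect_error(evaluateObjective(RNASequence("ACGU"), apt), "equal length")
})

test_that("objective is monotone in each distance term", {
    w <- ObjectiveWeights(enable_neutrality = TRUE, enable_dG = TRUE)
    base <- objectiveTotal(objectiveBreakdown(0.2, 1, 0, 2, 10, w))
    expect_gte(objectiveTotal(objectiveBreakdown(0.3, 1, 0, 2, 10, w)), base)
    expect_gte(objectiveTotal(objectiveBreakdown(0.2, 2, 0, 2, 10, w)), base)
    expect_gte(objectiveTotal(objectiveBreakdown(0.2, 1, 1, 2, 10, w)), base)
    expect_gte(objectiveTotal(objectiveBreakdown(0.2, 1, 0, 3, 10, w)), base)
    expect_gte(objectiveTotal(objectiveBreakdown(0.2, 1, 0, 2, 11, w)), base)
})

test_that("constraint files round-trip with 1-based coordinates", {
    con <- MotifConstraint(c(10L, 30L), strrep(".", 20),
                           fixed_positions = c(12L, 15L),
                           fixed_nucleotides = c("G", "U"))
    path <- tempfile(fileext = ".txt")
    writeConstraintFile(con, path)
    back <- readConstraintFile(path)
    expect_identical(back@region, con@region)
    expect_identical(back@substructure, con@substructure)
    expect_identical(back@fixed_positions, con@fixed_positions)
    expect_identical(back@fixed_nucleotides, con@fixed_nucleotides)

    expect_error(MotifConstraint(c(0L, 4L), "....",
                                 fixed_positions = c(1L, 1L),
                                 fixed_nucleotides = c("A", "G")),
                 "conflicting")
})
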