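test_that("dot-bracket parsing computes pairs by stack matching and round-trips", {
    s <- parseDotBracket("((...))")
    expect_identical(unname(basePairs(s)), cbind(c(0L, 1L), c(6L, 5L)))
    expect_identical(dotbracket(s), "((...))")

    expect_identical(nrow(basePairs(parseDotBracket("......."))), 0L)

    expect_error(parseDotBracket("((...)"), "unbalanced '\\(' at index 0")
    expect_error(parseDotBracket("(..))"), "unbalanced '\\)'")
    expect_error(parseDotBracket("((.x.))"), "illegal character")
    # whitespace stripped
    expect_identical(dotbracket(parseDotBracket(" ((...)) \n")), "((...))")
})

test_that("base-pair distance is the symmetric difference of pair sets", {
    a <- parseDotBracket("((...))")
    b <- parseDotBracket(".(...).")
    open <- parseDotBracket(".......")
    expect_identical(basePairDistance(a, a), 0L)
    expect_identical(basePairDistance(a, b), 1L)
    expect_identical(basePairDistance(a, open), 2L)
    expect_identical(basePairDistance(b, a), basePairDistance(a, b))
    expect_error(basePairDistance(a, parseDotBracket("....")),
                 "equal-length")
})

test_that("Shapiro trees decompose structures into the coarse motif tree", {
    expect_identical(shapiroString(shapiroTree(parseDotBracket("((...))"))),
                     "R(S(H))")
    expect_identical(shapiroString(shapiroTree(parseDotBracket("......."))),
                     "R(E)")
    expect_identical(
        shapiroString(shapiroTree(parseDotBracket("((..((...))..((...))..))"))),
        "R(S(M(S(H),S(H))))")
    # bulge and interior loop labels
    expect_identical(
        shapiroString(shapiroTree(parseDotBracket("((.((...))))"))),
        "R(S(B(S(H))))")
    expect_identical(
        shapiroString(shapiroTree(parseDotBracket("((.((...)).))"))),
        "R(S(I(S(H))))")
    # external strands flank stems in 5'->3' order
    expect_identical(
        shapiroString(shapiroTree(parseDotBracket("..((...))..((...))"))),
        "R(E,S(H),E,S(H))")
})

test_that("Shapiro tree is invariant under covariant base-pair substitution", {
    st <- synth_reference()
    apt <- synth_aptamer()
    set.seed(11)
    mut <- covariantMutate(apt, st)
    expect_identical(
        shapiroString(shapiroTree(foldMFE(mut)$structure)),
        shapiroString(shapiroTree(st)))
})

test_that("tree edit distance matches the recursive forest-distance oracle", {
    expect_identical(treeEditDistance(parseShapiro("R(S(H))"),
                                      parseShapiro("R(S(I(S(H))))")), 2L)
    expect_identical(treeEditDistance(parseShapiro("R(E)"),
                                      parseShapiro("R(S(H))")), 2L)

    # systematic small-tree family (all <= 6 nodes) plus random structures
    small <- c("R", "R(E)", "R(S(H))", "R(E,S(H))", "R(S(H),E)",
               "R(S(B(S(H))))", "R(S(I(S(H))))", "R(E,S(H),E)",
               "R(S(M(S(H),S(H))))", "R(S(H),S(H))", "R(E,E)",
               "R(S(B(S(H))),E)")
    trees <- lapply(small, parseShapiro)
    for (i in seq_along(trees)) {
        for (j in seq_along(trees)) {
            expect_identical(treeEditDistance(trees[[i]], trees[[j]]),
                             as.integer(oracle_tree_dist(trees[[i]],
                                                         trees[[j]])),
                             info = paste(small[i], "vs", small[j]))
        }
    }
})

test_that("both structural distances behave as metrics on random structures", {
    set.seed(42)
    structs <- lapply(1:8, function(i) randomNestedStructure(24L))
    trees <- lapply(structs, shapiroTree)
    for (i in 1:8) {
        expect_identical(basePairDistance(structs[[i]], structs[[i]]), 0L)
        expect_identical(treeEditDistance(trees[[i]], trees[[i]]), 0L)
    }
    for (i in 1:7) for (j in (i + 1):8) {
        dbp_ij <- basePairDistance(structs[[i]], structs[[j]])
        expect_identical(dbp_ij, basePairDistance(structs[[j]], structs[[i]]))
        dt_ij <- treeEditDistance(trees[[i]], trees[[j]])
        expect_identical(dt_ij, treeEditDistance(trees[[j]], trees[[i]]))
        for (k in seq_len(8)) {
            expect_lte(dbp_ij, basePairDistance(structs[[i]], structs[[k]]) +
                               basePairDistance(structs[[k]], structs[[j]]))
            expect_lte(dt_ij, treeEditDistance(trees[[i]], trees[[k]]) +
                              treeEditDistance(trees[[k]], trees[[j]]))
        }
    }
})

test_that("Hamming distance reproduces the preQ1 mutational series", {
    pq <- preq1Sequences()
    expect_identical(hammingDistance(pq$wildtype, pq$escape17), 17L)
    expect_identical(hammingDistance(pq$escape17, pq$collapsed), 2L)
    expect_identical(hammingDistance(pq$wildtype, pq$wildtype), 0L)
    expect_error(hammingDistance(RNASequence("ACGU"), RNASequence("ACG")),
                 "equal-length")
})

test_that("sequence construction normalises the alphabet and validates", {
    expect_identical(residues(RNASequence("gattaca")), "GAUUACA")
    expect_identical(length(RNASequence("ACGU")), 4L)
    expect_error(RNASequence("ACGX"), "illegal residue")
    expect_error(RNASequence(""), "non-empty")
})

test_that("FASTA and Vienna structure files round-trip", {
    seqs <- list(RNASequence("GGGAAACCC", id = "a", description = "toy"),
                 RNASequence(strrep("ACGU", 40), id = "b"))
    fa <- tempfile(fileext = ".fasta")
    writeRNAFasta(seqs, fa, width = 50L)
    back <- readRNAFasta(fa)
    expect_identical(vapply(back, residues, ""), c("GGGAAACCC",
                                                   strrep("ACGU", 40)))
    expect_identical(vapply(back, seqID, ""), c("a", "b"))
    expect_identical(back[[1]]@description, "toy")

    vf <- tempfile(fileext = ".vienna")
    st <- parseDotBracket("(((...)))")
    writeViennaStructure(seqs[[1]], st, vf, dG = -9)
    v <- readViennaStructure(vf)
    expect_identical(residues(v$sequence), "GGGAAACCC")
    expect_identical(dotbracket(v$structure), "(((...)))")
    expect_equal(v$dG, -9)
})
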