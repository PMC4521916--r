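test_that("covariant mutation always preserves the predicted structure", {
    apt <- synth_aptamer()
    ref <- synth_reference()
    set.seed(8)
    cur <- apt
    for (i in 1:20) {
        cur <- covariantMutate(cur, ref)
        expect_identical(
            basePairDistance(foldMFE(cur)$structure, ref), 0L)
    }
    expect_gt(hammingDistance(cur, apt), 0L)
})

test_that("covariant pair replacement keeps complementarity at the pair", {
    apt <- synth_aptamer()
    ref <- synth_reference()
    pairs <- basePairs(ref)
    legal <- c("AU", "UA", "GC", "CG", "GU", "UG")
    set.seed(21)
    for (i in 1:10) {
        mut <- covariantMutate(apt, ref)
        ch <- strsplit(residues(mut), "")[[1]]
        for (r in seq_len(nrow(pairs))) {
            expect_true(paste0(ch[pairs[r, 1] + 1], ch[pairs[r, 2] + 1])
                        %in% legal)
        }
    }
    # strict Watson-Crick mode never introduces wobble at mutated pairs
    set.seed(22)
    for (i in 1:10) {
        mut <- covariantMutate(apt, ref, allow_wobble = FALSE)
        ch <- strsplit(residues(mut), "")[[1]]
        ch0 <- strsplit(residues(apt), "")[[1]]
        for (r in seq_len(nrow(pairs))) {
            p <- paste0(ch[pairs[r, 1] + 1], ch[pairs[r, 2] + 1])
            if (p != paste0(ch0[pairs[r, 1] + 1], ch0[pairs[r, 2] + 1]))
                expect_true(p %in% c("AU", "UA", "GC", "CG"))
        }
    }
})

test_that("frozen positions are never touched by covariant mutation", {
    apt <- synth_aptamer()
    ref <- synth_reference()
    core <- synth_core()
    frozen <- core[1]:(core[2] - 1L)
    set.seed(4)
    cur <- apt
    for (i in 1:15) cur <- covariantMutate(cur, ref, frozen = frozen)
    expect_identical(substr(residues(cur), core[1] + 1L, core[2]),
                     substr(residues(apt), core[1] + 1L, core[2]))
})

test_that("random escape reaches zero hits and records a replayable trace", {
    fx <- make_fixture_db(rng_seed = 301)
    params <- fixture_params()
    apt <- synth_aptamer()
    expect_true(hasHits(apt, fx$db, params))

    tr <- randomEscape(apt, fx$db, params, rng_seed = 17)
    expect_s4_class(tr, "EscapeTrace")
    n <- length(tr@hits_at_each_step)
    expect_gt(n, 0L)
    expect_identical(tr@hits_at_each_step[n], 0L)
    expect_false(hasHits(tr@end, fx$db, params))
    # the trace is replayable (validity already checks path application)
    tr2 <- randomEscape(apt, fx$db, params, rng_seed = 17)
    expect_identical(residues(tr2@end), residues(tr@end))

    # a query with no hits returns an empty trace
    set.seed(1)
    far <- RNASequence(random_rna(length(apt)))
    if (!hasHits(far, fx$db, params)) {
        tr0 <- randomEscape(far, fx$db, params)
        expect_identical(nrow(tr0@mutation_path), 0L)
    }

    # exhausted budget signals a typed error carrying the partial trace
    err <- tryCatch(randomEscape(apt, fx$db, params, max_mutations = 0L),
                    error = function(e) e)
    expect_s3_class(err, "riboseekEscapeBudgetError")
    expect_s4_class(err$trace, "EscapeTrace")
})

test_that("covariant escape intermediates all fold to the reference", {
    fx <- make_fixture_db(rng_seed = 302)
    params <- fixture_params()
    apt <- synth_aptamer()
    ref <- synth_reference()
    esc <- covariantEscape(apt, ref, fx$db, params, rng_seed = 23)
    expect_gt(length(esc$intermediates), 0L)
    for (s in esc$intermediates)
        expect_identical(basePairDistance(foldMFE(s)$structure, ref), 0L)
    expect_false(hasHits(esc$trace@end, fx$db, params))
})

test_that("region restoration splices exactly and reproduces the printed borderline sequence", {
    a <- RNASequence("AAAAAAAA", id = "a")
    b <- RNASequence("CCCCCCCC", id = "b")
    expect_identical(residues(restoreRegion(a, b, c(0L, 8L))), residues(b))
    expect_identical(residues(restoreRegion(a, b, c(3L, 3L))), residues(a))
    expect_identical(residues(restoreRegion(a, b, c(2L, 5L))), "AACCCAAA")

    # the purine worked example: restoring the right segment of the
    # covariant escape sequence toward the aptamer yields the printed
    # borderline sequence
    xpt <- xptAptamer()
    esc <- xptEscapeSequences()
    diff <- which(strsplit(residues(esc$escaped), "")[[1]] !=
                  strsplit(residues(esc$restored), "")[[1]])
    region <- c(min(diff) - 1L, max(diff))
    back <- restoreRegion(esc$escaped, xpt, region)
    expect_identical(residues(back), residues(esc$restored))
    # inside the region the restored sequence equals the aptamer
    expect_identical(substr(residues(back), region[1] + 1L, region[2]),
                     substr(residues(xpt), region[1] + 1L, region[2]))
})
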