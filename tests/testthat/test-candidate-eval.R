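make_hit <- function(record_id = "r", qstart = 0L, qend = 10L,
                     sstart = 0L, send = 10L, strand = "+",
                     e_value = 1e-10) {
    data.frame(record_id = record_id, qstart = qstart, qend = qend,
               sstart = sstart, send = send, strand = strand,
               e_value = e_value, stringsAsFactors = FALSE)
}

test_that("window extraction anchors on the hit's query offset", {
    rec <- paste0(strrep("A", 50), strrep("C", 69), strrep("G", 50))

    # full-length exact hit: window == subject interval
    w <- extractWindow(rec, make_hit(qstart = 0L, qend = 69L, sstart = 50L,
                                     send = 119L), 69L)
    expect_identical(w$location, c(51L, 119L))
    expect_identical(residues(w$window), strrep("C", 69))

    # hit covering query positions 10..40: extend 10 upstream, 29 down
    w2 <- extractWindow(rec, make_hit(qstart = 10L, qend = 40L,
                                      sstart = 60L, send = 90L), 69L)
    expect_identical(w2$location, c(51L, 119L))

    # clipped at the record start: shifted into the interior
    w3 <- extractWindow(rec, make_hit(qstart = 10L, qend = 40L, sstart = 3L,
                                      send = 33L), 69L)
    expect_identical(w3$location[1L], 1L)
    expect_identical(w3$location[2L] - w3$location[1L] + 1L, 69L)

    expect_error(extractWindow("ACGT", make_hit(), 69L), "shorter")
})

test_that("minus-strand windows are extracted from the reverse complement", {
    core <- gsub("U", "T", residues(synth_aptamer()))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(core)))
    rec <- paste0(strrep("A", 30), rc, strrep("G", 30))
    L <- nchar(core)
    hit <- make_hit(qstart = 0L, qend = L, sstart = 30L, send = 30L + L,
                    strand = "-")
    w <- extractWindow(rec, hit, L)
    expect_identical(residues(w$window), residues(synth_aptamer()))
    expect_identical(w$location, c(31L, 30L + L))
    expect_identical(w$strand, "-")
})

test_that("assessment accepts shape-preserved windows and rejects collapsed ones", {
    apt <- synth_aptamer()
    ref <- synth_reference()
    con <- synth_constraint()

    # the query itself: distances zero, accepted
    r <- assessCandidate(apt, apt, ref, constraint = con)
    expect_true(verdict(r))
    expect_identical(r@bp_distance, 0L)
    expect_identical(r@shapiro_distance, 0L)
    expect_identical(length(r@preserved_positions), length(apt))

    # an open-chain window is structurally distant: rejected
    poly <- RNASequence(strrep("A", length(apt)))
    r2 <- assessCandidate(poly, apt, ref, constraint = con)
    expect_false(verdict(r2))

    # a covariant homolog keeps the shape: accepted with both distances 0
    set.seed(14)
    hom <- apt
    for (i in 1:15) hom <- covariantMutate(hom, ref)
    r3 <- assessCandidate(hom, apt, ref, constraint = con)
    expect_true(verdict(r3))
    expect_identical(r3@bp_distance, 0L)
    expect_identical(r3@shapiro_distance, 0L)
    expect_identical(length(r3@preserved_positions),
                     length(apt) - hammingDistance(hom, apt))

    expect_error(assessCandidate(RNASequence("ACGU"), apt, ref), "length")
})

test_that("verdict depends on the window only through its predicted structure", {
    apt <- synth_aptamer()
    ref <- synth_reference()
    con <- synth_constraint()
    set.seed(15)
    w1 <- apt
    for (i in 1:8) w1 <- covariantMutate(w1, ref)
    # a synonymous-structure substitute of w1 must keep the verdict
    w2 <- covariantMutate(w1, ref)
    r1 <- assessCandidate(w1, apt, ref, constraint = con)
    r2 <- assessCandidate(w2, apt, ref, constraint = con)
    expect_identical(verdict(r1), verdict(r2))
})

test_that("large bp distance with small Shapiro distance does not reject", {
    apt <- synth_aptamer()
    ref <- synth_reference()
    # manufacture a report with Table-style distances: shape identical,
    # many shifted base pairs
    rep1 <- new("CandidateReport", record_id = "x", location = c(1L, 53L),
                strand = "+", window = apt, structure = ref,
                bp_distance = 39L, shapiro_distance = 2L,
                preserved_positions = 0:9, e_value = 1e-5, verdict = TRUE)
    expect_true(verdict(rep1))
})

test_that("ranking puts accepted candidates first, then sorts by distances", {
    mk <- function(id, verdict, shap, bp, ev) {
        new("CandidateReport", record_id = id, location = c(1L, 10L),
            strand = "+", window = RNASequence("ACGUACGUAC"),
            structure = parseDotBracket(".........."),
            bp_distance = as.integer(bp),
            shapiro_distance = as.integer(shap),
            preserved_positions = integer(0), e_value = ev,
            verdict = verdict)
    }
    a <- mk("rej_close", FALSE, 0, 0, 1e-30)
    b <- mk("acc_far", TRUE, 2, 30, 1)
    c2 <- mk("acc_near", TRUE, 0, 2, 1)
    d <- mk("acc_tie", TRUE, 0, 2, 1)
    ranked <- rankCandidates(list(a, b, c2, d))
    ids <- vapply(ranked, slot, character(1), "record_id")
    expect_identical(ids, c("acc_near", "acc_tie", "acc_far", "rej_close"))
    expect_identical(rankCandidates(list(a))[[1]]@record_id, "rej_close")

    tab <- candidateTable(ranked)
    expect_identical(nrow(tab), 4L)
    expect_true(all(tab$verdict[1:3]))
})
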