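test_that("database construction indexes both strands and validates input", {
    db <- buildDatabase(c(rec = strrep("ACGT", 10)), word_size = 7L)
    # forward postings count L - w + 1
    fwd <- 0L
    for (w in ls(db@index)) {
        m <- db@index[[w]]
        fwd <- fwd + sum(m[, "strand"] == 1L)
    }
    expect_identical(fwd, 40L - 7L + 1L)

    # record shorter than the word size is retained with no postings
    db2 <- buildDatabase(c(long = strrep("ACGT", 10), tiny = "ACGTA"),
                         word_size = 7L)
    expect_identical(length(db2@ids), 2L)

    expect_error(buildDatabase(c(a = "ACGT", a = "ACGT")), "duplicate")
    expect_error(buildDatabase(character(0)), "empty")
    expect_error(buildDatabase(c(bad = "ACGTNNN")), "bad")
    # U is normalised to T on ingest
    db3 <- buildDatabase(c(r = "ACGUACGUACGU"))
    expect_identical(db3@sequences, "ACGTACGTACGT")
})

test_that("a verbatim planted query is found as a full-length perfect hit", {
    set.seed(9)
    bg <- random_dna(400)
    q <- synth_aptamer()
    L <- length(q)
    rec <- paste0(substr(bg, 1, 150), gsub("U", "T", residues(q)),
                  substr(bg, 151, 400))
    db <- buildDatabase(c(r1 = rec, r2 = random_dna(400)))
    hits <- searchHits(q, db)
    expect_gt(nrow(hits), 0L)
    top <- hits[1L, ]
    expect_identical(top$record_id, "r1")
    expect_identical(c(top$sstart, top$send), c(150L, 150L + L))
    expect_identical(c(top$qstart, top$qend), c(0L, L))
    expect_identical(top$identities, top$alignment_length)
    expect_identical(top$strand, "+")

    # hits are sorted by ascending E-value
    expect_true(!is.unsorted(hits$e_value))
})

test_that("search is strand symmetric", {
    set.seed(10)
    bg <- random_dna(300)
    q <- synth_aptamer()
    rec <- paste0(substr(bg, 1, 100), gsub("U", "T", residues(q)),
                  substr(bg, 101, 300))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rec)))
    h_fwd <- searchHits(q, buildDatabase(c(r = rec)))
    h_rev <- searchHits(q, buildDatabase(c(r = rc)))
    expect_identical(nrow(h_fwd), nrow(h_rev))
    expect_identical(h_fwd$raw_score, h_rev$raw_score)
    top_f <- h_fwd[1L, ]; top_r <- h_rev[1L, ]
    expect_identical(top_f$strand, "+")
    expect_identical(top_r$strand, "-")
    # the minus-strand interval mirrors the plus-strand one
    Ls <- nchar(rec)
    expect_identical(c(top_r$sstart, top_r$send),
                     c(Ls - top_f$send, Ls - top_f$sstart))
})

test_that("hit verdicts agree with a full Smith-Waterman scan", {
    set.seed(12)
    apt <- synth_aptamer()
    # the study's significance regime (genome-scale search space)
    params <- fixture_params()
    fx <- make_fixture_db(rng_seed = 77, n_records = 3L,
                          record_length = 400L, n_planted = 2L,
                          divergence_steps = 12L)
    db <- fx$db
    thresh <- log(params@karlin_K * params@search_space /
                  params@e_cutoff) / params@karlin_lambda

    queries <- c(list(residues(apt)),
                 lapply(1:12, function(i) random_rna(69)),
                 lapply(fx$truth$planted_residues, identity))
    agree <- 0L
    for (qs in queries) {
        q <- RNASequence(qs)
        mine <- hasHits(q, db, params)
        oracle_score <- oracle_best_local_score(gsub("U", "T", qs),
                                                db@sequences)
        oracle_verdict <- oracle_score > thresh
        if (identical(mine, oracle_verdict)) agree <- agree + 1L
        # when both find it, the reported best score cannot exceed the
        # true local-alignment optimum
        if (mine && oracle_verdict) {
            top <- searchHits(q, db, params)[1L, ]
            expect_lte(top$raw_score, oracle_score)
        }
    }
    expect_gte(agree / length(queries), 0.95)

    # documented miss class: under the permissive default cutoff every
    # disagreement is a seed-and-extend miss of a weak chance alignment
    # (no exact word seed), never a spurious extra hit
    defaults <- SearchParams()
    d_thresh <- log(defaults@karlin_K * 69 * 2 * db@total_length /
                    defaults@e_cutoff) / defaults@karlin_lambda
    for (i in 1:8) {
        qs <- random_rna(69)
        mine <- hasHits(RNASequence(qs), db, defaults)
        oracle <- oracle_best_local_score(gsub("U", "T", qs),
                                          db@sequences) > d_thresh
        if (!identical(mine, oracle)) expect_true(oracle && !mine)
    }
})

test_that("raising the E-value cutoff never removes hits", {
    fx <- make_fixture_db(rng_seed = 55, n_records = 2L,
                          record_length = 400L)
    q <- synth_aptamer()
    strict <- searchHits(q, fx$db, SearchParams(e_cutoff = 0.01))
    loose <- searchHits(q, fx$db, SearchParams(e_cutoff = 100))
    key <- function(h) paste(h$record_id, h$sstart, h$send, h$strand)
    expect_true(all(key(strict) %in% key(loose)))
    expect_gte(nrow(loose), nrow(strict))
})

test_that("word size must match the index and short queries error", {
    db <- buildDatabase(c(r = random_dna(100)), word_size = 7L)
    expect_error(searchHits("ACGUACGUACGU", db, SearchParams(word_size = 11L)),
                 "word_size")
    expect_error(searchHits("ACGU", db), "shorter than the word size")
})

test_that("tabular hit output round-trips, including minus-strand coordinates", {
    set.seed(30)
    bg <- random_dna(200)
    q <- synth_aptamer()
    ins <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(gsub("U", "T", residues(q)))))
    rec <- paste0(substr(bg, 1, 80), ins, substr(bg, 81, 200))
    db <- buildDatabase(c(rev_rec = rec))
    hits <- searchHits(q, db)
    expect_identical(hits$strand[1L], "-")
    path <- tempfile(fileext = ".tsv")
    writeHitsTable(hits, path)
    back <- readHitsTable(path)
    expect_identical(back$record_id, hits$record_id)
    expect_identical(back$sstart, hits$sstart)
    expect_identical(back$send, hits$send)
    expect_identical(back$strand, hits$strand)
    expect_identical(back$qstart, hits$qstart)
    expect_identical(back$alignment_length, hits$alignment_length)
    expect_equal(back$raw_score, hits$raw_score, tolerance = 0.05)
})
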