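# Independent oracles used to validate the implementation:
#  - exhaustive enumeration of nested structures (fold oracle)
#  - recursive forest edit distance from first principles (tree oracle)
#  - Biostrings Smith-Waterman (alignment oracle)

# All nested bracketings of length n with >= 3 unpaired inside every
# hairpin, as dot-bracket strings.
enumerate_structures <- function(n) {
    memo <- new.env(parent = emptyenv())
    gen <- function(i, j) {
        if (j < i) return("")
        key <- paste(i, j)
        if (!is.null(memo[[key]])) return(memo[[key]])
        res <- paste0(".", gen(i + 1L, j))
        if (j >= i + 4L) for (k in (i + 4L):j) {
            inner <- gen(i + 1L, k - 1L)
            rest <- gen(k + 1L, j)
            res <- c(res, as.vector(outer(inner, rest,
                function(a, b) paste0("(", a, ")", b))))
        }
        memo[[key]] <- res
        res
    }
    gen(1L, n)
}

# pair scores of the built-in engine; NA when not pairable
oracle_pair_score <- function(a, b) {
    key <- paste0(a, b)
    switch(key, GC = -3, CG = -3, AU = -2, UA = -2, GU = -1, UG = -1,
           NA_real_)
}

# score a dot-bracket against a sequence; NA when any pair is not pairable
oracle_structure_score <- function(db, seq_chars) {
    p <- basePairs(parseDotBracket(db))
    if (!nrow(p)) return(0)
    s <- 0
    for (r in seq_len(nrow(p))) {
        v <- oracle_pair_score(seq_chars[p[r, 1L] + 1L],
                               seq_chars[p[r, 2L] + 1L])
        if (is.na(v)) return(NA_real_)
        s <- s + v
    }
    s
}

# optimal (minimum) score over all nested structures, by brute force
oracle_fold_dG <- function(residues) {
    chars <- strsplit(residues, "")[[1]]
    scores <- vapply(enumerate_structures(length(chars)),
                     oracle_structure_score, numeric(1),
                     seq_chars = chars)
    min(c(0, scores), na.rm = TRUE)
}

# --- tree edit distance oracle: plain recursive forest edit distance ----

# convert a ShapiroTree into a nested list forest
tree_to_nested <- function(tree) {
    n <- length(tree@labels)
    children <- vector("list", n)
    if (n > 1L) for (i in 2L:n) {
        p <- tree@parent[i]
        children[[p]] <- c(children[[p]], i)
    }
    build <- function(i) {
        list(label = tree@labels[i],
             children = lapply(children[[i]], build))
    }
    list(build(1L))
}

forest_size <- function(f) {
    if (!length(f)) return(0L)
    sum(vapply(f, function(t) 1L + forest_size(t$children), integer(1)))
}

forest_key <- function(f) {
    paste(vapply(f, function(t)
        paste0(t$label, "(", forest_key(t$children), ")"), character(1)),
        collapse = ",")
}

# minimal number of node insertions/deletions/relabelings between ordered
# forests -- the defining recurrence, memoised, independent of Zhang-Shasha
oracle_forest_dist <- function(f1, f2, memo = new.env(parent = emptyenv())) {
    if (!length(f1)) return(forest_size(f2))
    if (!length(f2)) return(forest_size(f1))
    key <- paste(forest_key(f1), "|", forest_key(f2))
    if (!is.null(memo[[key]])) return(memo[[key]])
    t1 <- f1[[length(f1)]]; r1 <- f1[-length(f1)]
    t2 <- f2[[length(f2)]]; r2 <- f2[-length(f2)]
    del <- oracle_forest_dist(c(r1, t1$children), f2, memo) + 1L
    ins <- oracle_forest_dist(f1, c(r2, t2$children), memo) + 1L
    match <- oracle_forest_dist(r1, r2, memo) +
        oracle_forest_dist(t1$children, t2$children, memo) +
        (t1$label != t2$label)
    v <- min(del, ins, match)
    memo[[key]] <- v
    v
}

oracle_tree_dist <- function(a, b) {
    oracle_forest_dist(tree_to_nested(a), tree_to_nested(b))
}

# --- Smith-Waterman oracle (Biostrings) -------------------------------

# best local alignment score of q (DNA string) against each strand of each
# record; returns the max over the database
oracle_best_local_score <- function(qdna, sequences) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
        mismatch = -3, baseOnly = TRUE)
    best <- 0
    for (s in sequences) {
        for (subj in c(s, as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(s))))) {
            pa <- Biostrings::pairwiseAlignment(qdna, subj, type = "local",
                substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
            best <- max(best, Biostrings::score(pa))
        }
    }
    best
}

random_rna <- function(n) {
    paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
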