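# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  seed = NULL runs in the ambient RNG.
.with_seed <- function(seed, code) {
    if (is.null(seed)) return(force(code))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

# Deterministic sub-seed derivation; result always in [1, 2^31 - 2].
.derive_seed <- function(base, ...) {
    v <- as.numeric(base) %% 2147483647
    for (x in c(...)) v <- (v * 1009 + as.numeric(x) + 1) %% 2147483647
    as.integer(v + 1)
}

.rna_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

.to_rna <- function(x) chartr("T", "U", toupper(x))

.to_dna <- function(x) chartr("U", "T", toupper(x))

.revcomp_dna <- function(x) {
    paste(rev(.rna_chars(chartr("ACGT", "TGCA", x))), collapse = "")
}
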