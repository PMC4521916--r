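# Synthetic genome fixtures: random backgrounds with planted,
# structure-preserved aptamer homologs at known coordinates.

#' Sample a random nested secondary structure
#'
#' Draws a valid pseudoknot-free structure of exactly \code{n} nucleotides
#' with realistic motif dimensions (stems of \code{min_stem} to
#' \code{max_stem} pairs, loops of at least \code{min_loop} unpaired
#' nucleotides), used for design-convergence studies.
#'
#' @param n structure length.
#' @param min_stem,max_stem stem length bounds (base pairs).
#' @param min_loop minimum unpaired nucleotides inside a hairpin.
#' @param rng_seed optional seed.
#' @return a \linkS4class{SecondaryStructure}.
#' @export
randomNestedStructure <- function(n, min_stem = 3L, max_stem = 6L,
                                  min_loop = 3L, rng_seed = NULL) {
    gen_forest <- function(len) {
        # sequence of dots and helices filling exactly len positions
        out <- ""
        rem <- len
        while (rem > 0L) {
            min_hairpin_len <- 2L * min_stem + min_loop
            if (rem >= min_hairpin_len && stats::runif(1) < 0.6) {
                s <- sample(min_stem:min(max_stem,
                                         (rem - min_loop) %/% 2L), 1L)
                inner <- rem - 2L * s
                # keep some room after the helix sometimes
                tail_len <- if (inner > min_loop + 2L && stats::runif(1) < 0.5)
                    sample.int(inner - min_loop, 1L) else 0L
                inner <- inner - tail_len
                body <- if (inner >= min_hairpin_len && stats::runif(1) < 0.5)
                    gen_forest(inner) else strrep(".", inner)
                if (nchar(gsub("[^.]", "", body)) < min_loop &&
                    !grepl("\\(", body))
                    body <- strrep(".", inner)
                out <- paste0(out, strrep("(", s), body, strrep(")", s))
                rem <- tail_len
            } else {
                out <- paste0(out, ".")
                rem <- rem - 1L
            }
        }
        out
    }
    .with_seed(rng_seed, {
        repeat {
            db <- gen_forest(as.integer(n))
            s <- try(parseDotBracket(db), silent = TRUE)
            if (!inherits(s, "try-error") && nchar(db) == n) return(s)
        }
    })
}

#' Generate a synthetic genome fixture with planted aptamer homologs
#'
#' Builds random-background records and plants diverged copies of a
#' supplied aptamer at recorded coordinates and strands.  Each planted copy
#' is produced by \code{divergence_steps} covariant mutations, so it is
#' sequence-diverged but refolds exactly to the aptamer structure
#' (verified by construction).  Positions in \code{conserved_region} are
#' never mutated, emulating the sequence conservation of essential
#' ligand-binding nucleotides.  With \code{scrambled = TRUE} the planted
#' copies instead have all positions outside the conserved region randomly
#' permuted (same composition, structure destroyed) -- the negative
#' control for specificity studies.
#'
#' @param aptamer the \linkS4class{RNASequence} to plant.
#' @param structure its reference \linkS4class{SecondaryStructure}; default
#'   is the engine's fold of the aptamer.
#' @param n_records number of background records.
#' @param record_length length of each background record (must be at least
#'   the aptamer length).
#' @param n_planted number of planted copies.
#' @param divergence_steps covariant mutations applied to each copy.
#' @param conserved_region 0-based half-open interval protected from
#'   divergence (NULL for none).
#' @param scrambled plant shuffled (structure-destroyed) copies instead.
#' @param engine a \linkS4class{FoldEngine} used to verify structure
#'   preservation.
#' @param rng_seed integer seed.
#' @return list with \code{sequences} (named character, DNA) and
#'   \code{truth} (data.frame: record_id, start, end 1-based inclusive,
#'   strand, planted_residues, hamming).
#' @export
generateFixture <- function(aptamer, structure = NULL, n_records = 5L,
                            record_length = 2000L, n_planted = 2L,
                            divergence_steps = 15L, conserved_region = NULL,
                            scrambled = FALSE, engine = nussinovEngine(),
                            rng_seed = 1L) {
    if (is.character(aptamer)) aptamer <- RNASequence(aptamer)
    L <- length(aptamer)
    if (record_length < L)
        stop("background records shorter than the aptamer")
    if (divergence_steps < 0L) stop("divergence_steps must be >= 0")
    if (is.null(structure)) structure <- foldMFE(aptamer, engine)$structure
    frozen <- if (is.null(conserved_region)) integer(0)
              else seq(conserved_region[1L], conserved_region[2L] - 1L)

    .with_seed(rng_seed, {
        seqs <- vapply(seq_len(n_records), function(i) {
            paste(sample(c("A", "C", "G", "T"), record_length,
                         replace = TRUE), collapse = "")
        }, character(1))
        names(seqs) <- sprintf("record_%02d", seq_len(n_records))

        occupied <- vector("list", n_records)
        truth <- list()
        for (p in seq_len(n_planted)) {
            planted <- aptamer
            if (scrambled) {
                chars <- .rna_chars(aptamer@residues)
                outside <- setdiff(seq_len(L), frozen + 1L)
                chars[outside] <- chars[sample(outside)]
                planted <- RNASequence(paste(chars, collapse = ""))
            } else if (divergence_steps > 0L) {
                for (s in seq_len(divergence_steps))
                    planted <- covariantMutate(planted, structure, engine,
                                               frozen = frozen)
            }
            rec <- ((p - 1L) %% n_records) + 1L
            # non-overlapping placement within the record
            for (try in 1:100) {
                off <- sample.int(record_length - L + 1L, 1L)
                iv <- c(off, off + L - 1L)
                clash <- any(vapply(occupied[[rec]], function(o)
                    iv[1L] <= o[2L] && o[1L] <= iv[2L], logical(1)))
                if (!clash) break
                if (try == 100L) stop("could not place plant without overlap")
            }
            occupied[[rec]] <- c(occupied[[rec]], list(iv))
            strand <- sample(c("+", "-"), 1L)
            insert <- .to_dna(planted@residues)
            if (strand == "-") insert <- .revcomp_dna(insert)
            seqs[rec] <- paste0(substr(seqs[rec], 1L, off - 1L), insert,
                                substr(seqs[rec], off + L, record_length))
            truth[[p]] <- data.frame(
                record_id = names(seqs)[rec], start = iv[1L], end = iv[2L],
                strand = strand, planted_residues = planted@residues,
                hamming = hammingDistance(planted, aptamer),
                stringsAsFactors = FALSE)
        }
        list(sequences = seqs, truth = do.call(rbind, truth))
    })
}
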