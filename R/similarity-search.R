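# Self-contained seed-and-extend nucleotide similarity search: a local
# stand-in for blastn ("somewhat similar sequences" defaults), so the
# escape and screening steps run with no network or external binary.
# Real blastn tabular output can be ingested through readHitsTable().

#' Construct similarity search parameters
#'
#' @param word_size exact word seed length.
#' @param match,mismatch,gap_open,gap_extend alignment scores (a gap of
#'   length k costs \code{|gap_open| + k |gap_extend|}).
#' @param x_drop score drop-off ending ungapped extension.
#' @param gap_trigger ungapped score above which a gapped extension runs.
#' @param e_cutoff maximum reported E-value.
#' @param karlin_lambda,karlin_K Karlin-Altschul calibration constants
#'   (published ungapped values for +2/-3).
#' @param search_space effective search space for E-values (NA: query
#'   length times both database strands; set to e.g. 1e10 to emulate
#'   genome-scale significance on a small fixture database).
#' @return a \linkS4class{SearchParams}.
#' @export
SearchParams <- function(word_size = 7L, match = 2, mismatch = -3,
                         gap_open = -5, gap_extend = -2, x_drop = 20,
                         gap_trigger = 22, e_cutoff = 10,
                         karlin_lambda = 0.625, karlin_K = 0.41,
                         search_space = NA_real_) {
    new("SearchParams", word_size = as.integer(word_size), match = match,
        mismatch = mismatch, gap_open = gap_open, gap_extend = gap_extend,
        x_drop = x_drop, gap_trigger = gap_trigger, e_cutoff = e_cutoff,
        karlin_lambda = karlin_lambda, karlin_K = karlin_K,
        search_space = as.numeric(search_space))
}

setMethod("show", "SearchDatabase", function(object) {
    cat(sprintf("SearchDatabase: %d record(s), %.0f nt, word size %d\n",
                length(object@ids), object@total_length, object@word_size))
})

#' Build a k-mer indexed search database
#'
#' Sequences are normalised to uppercase DNA (U to T) and every k-mer
#' occurrence of every record, on both strands, enters the word index.
#' Records shorter than the word size are retained but contribute no
#' postings.
#'
#' @param x multi-FASTA path, a named character vector of sequences, or a
#'   \code{Biostrings::XStringSet}.
#' @param word_size word length for the index.
#' @return a \linkS4class{SearchDatabase}.
#' @export
buildDatabase <- function(x, word_size = 7L) {
    word_size <- as.integer(word_size)
    if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
        file.exists(x)) {
        set <- Biostrings::readBStringSet(x)
        seqs <- as.character(set)
        names(seqs) <- sub("\\s.*$", "", names(set))
    } else if (is(x, "XStringSet")) {
        seqs <- as.character(x)
    } else {
        seqs <- x
    }
    if (!length(seqs)) stop("empty database")
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
        stop("all database records need identifiers")
    if (anyDuplicated(names(seqs)))
        stop("duplicate record ids: ",
             paste(unique(names(seqs)[duplicated(names(seqs))]),
                   collapse = ", "))
    seqs <- vapply(seqs, .to_dna, character(1))
    for (i in seq_along(seqs)) {
        bad <- setdiff(unique(.rna_chars(seqs[[i]])), c("A", "C", "G", "T"))
        if (length(bad))
            stop("non-nucleotide character(s) ", paste(bad, collapse = ", "),
                 " in record ", names(seqs)[i])
    }

    rc <- vapply(seqs, .revcomp_dna, character(1))
    index <- new.env(parent = emptyenv(), hash = TRUE)
    rec_all <- integer(0); off_all <- integer(0)
    strand_all <- integer(0); words_all <- character(0)
    for (i in seq_along(seqs)) {
        for (strand in 1:2) {
            subj <- if (strand == 1L) seqs[[i]] else rc[[i]]
            L <- nchar(subj)
            if (L < word_size) next
            starts <- seq_len(L - word_size + 1L)
            words_all <- c(words_all,
                           substring(subj, starts, starts + word_size - 1L))
            rec_all <- c(rec_all, rep(i, length(starts)))
            off_all <- c(off_all, starts - 1L)
            strand_all <- c(strand_all, rep(strand, length(starts)))
        }
    }
    if (length(words_all)) {
        groups <- split(seq_along(words_all), words_all)
        for (w in names(groups)) {
            g <- groups[[w]]
            index[[w]] <- cbind(rec = rec_all[g], off = off_all[g],
                                strand = strand_all[g])
        }
    }
    new("SearchDatabase", ids = names(seqs), sequences = unname(seqs),
        revcomp = unname(rc), index = index, word_size = word_size,
        total_length = sum(nchar(seqs)))
}

.empty_hits <- function() {
    data.frame(query_id = character(0), record_id = character(0),
               qstart = integer(0), qend = integer(0), sstart = integer(0),
               send = integer(0), strand = character(0),
               raw_score = numeric(0), bit_score = numeric(0),
               e_value = numeric(0), identities = integer(0),
               alignment_length = integer(0), mismatches = integer(0),
               gap_openings = integer(0), stringsAsFactors = FALSE)
}

#' Search a database for local similarities to a query
#'
#' Seed-and-extend: exact word seeds from the index are extended without
#' gaps under an x-drop rule; seeds whose ungapped score exceeds the gapped
#' trigger are re-extended with affine gaps (Smith-Waterman on a window
#' around the seed).  Hits are scored with the Karlin-Altschul E-value
#' \eqn{E = K m n e^{-\lambda S}} (n counts both strands), filtered at the
#' E-value cutoff, deduplicated by subject overlap and sorted by ascending
#' E-value.  Subject intervals are reported 0-based half-open on the
#' forward strand.
#'
#' @param query an \linkS4class{RNASequence} (or string); length must reach
#'   the word size.
#' @param db a \linkS4class{SearchDatabase}.
#' @param params a \linkS4class{SearchParams} (its word size must match the
#'   database index).
#' @return data.frame of hits (possibly zero rows) with columns query_id,
#'   record_id, qstart, qend, sstart, send, strand, raw_score, bit_score,
#'   e_value, identities, alignment_length, mismatches, gap_openings.
#' @export
searchHits <- function(query, db, params = SearchParams()) {
    if (is.character(query)) query <- RNASequence(query)
    q <- .to_dna(query@residues)
    w <- db@word_size
    if (params@word_size != w)
        stop("params word_size (", params@word_size,
             ") does not match the database index (", w, ")")
    if (nchar(q) < w)
        stop("query shorter than the word size")
    m <- nchar(q)
    space <- if (is.na(params@search_space)) m * 2 * db@total_length
             else params@search_space

    starts <- seq_len(m - w + 1L)
    words <- substring(q, starts, starts + w - 1L)
    seen <- new.env(parent = emptyenv(), hash = TRUE)
    rows <- list()
    for (qi in seq_along(words)) {
        postings <- db@index[[words[qi]]]
        if (is.null(postings)) next
        for (r in seq_len(nrow(postings))) {
            rec <- postings[r, 1L]; off <- postings[r, 2L]
            strand <- postings[r, 3L]
            diag_key <- paste(rec, strand, off - (qi - 1L))
            if (!is.null(seen[[diag_key]])) next
            seen[[diag_key]] <- TRUE
            subj <- if (strand == 1L) db@sequences[rec] else db@revcomp[rec]
            ext <- .xdrop_extend_cpp(q, subj, qi - 1L, off, w,
                                     as.integer(params@match),
                                     as.integer(params@mismatch),
                                     as.integer(params@x_drop))
            score <- ext[5L]
            if (score >= params@gap_trigger) {
                Ls <- nchar(subj)
                win0 <- max(0L, ext[3L] - m - 15L)
                win1 <- min(Ls, ext[4L] + m + 15L)
                sw <- .smith_waterman_cpp(q,
                          substr(subj, win0 + 1L, win1),
                          as.integer(params@match),
                          as.integer(params@mismatch),
                          as.integer(-params@gap_open),
                          as.integer(-params@gap_extend))
                hit <- list(qs = sw[2L], qe = sw[3L], ss = win0 + sw[4L],
                            se = win0 + sw[5L], score = sw[1L],
                            ident = sw[6L], alen = sw[7L], gaps = sw[8L])
            } else {
                hit <- list(qs = ext[1L], qe = ext[2L], ss = ext[3L],
                            se = ext[4L], score = score, ident = ext[6L],
                            alen = ext[2L] - ext[1L],
                            gaps = 0L)
            }
            if (hit$score <= 0) next
            e <- params@karlin_K * space *
                exp(-params@karlin_lambda * hit$score)
            if (e > params@e_cutoff) next
            Ls <- nchar(db@sequences[rec])
            if (strand == 1L) {
                ss <- hit$ss; se <- hit$se
            } else {
                ss <- Ls - hit$se; se <- Ls - hit$ss
            }
            rows[[length(rows) + 1L]] <- data.frame(
                query_id = query@id, record_id = db@ids[rec],
                qstart = hit$qs, qend = hit$qe, sstart = ss, send = se,
                strand = if (strand == 1L) "+" else "-",
                raw_score = hit$score,
                bit_score = (params@karlin_lambda * hit$score -
                             log(params@karlin_K)) / log(2),
                e_value = e, identities = hit$ident,
                alignment_length = hit$alen,
                mismatches = hit$alen - hit$ident - hit$gaps,
                gap_openings = hit$gaps, stringsAsFactors = FALSE)
        }
    }
    if (!length(rows)) return(.empty_hits())
    hits <- do.call(rbind, rows)

    # dedupe: keep the best-scoring hit among subject-overlapping ones
    hits <- hits[order(-hits$raw_score, hits$e_value), , drop = FALSE]
    keep <- rep(TRUE, nrow(hits))
    for (i in seq_len(nrow(hits))[-1L]) {
        for (j in seq_len(i - 1L)) {
            if (!keep[j]) next
            if (hits$record_id[i] != hits$record_id[j] ||
                hits$strand[i] != hits$strand[j]) next
            ov <- min(hits$send[i], hits$send[j]) -
                  max(hits$sstart[i], hits$sstart[j])
            span <- min(hits$send[i] - hits$sstart[i],
                        hits$send[j] - hits$sstart[j])
            if (ov > 0.5 * span) { keep[i] <- FALSE; break }
        }
    }
    hits <- hits[keep, , drop = FALSE]
    hits <- hits[order(hits$e_value, -hits$raw_score, hits$record_id,
                       hits$sstart), , drop = FALSE]
    rownames(hits) <- NULL
    hits
}

#' Does the query have any database hit?
#'
#' @inheritParams searchHits
#' @return TRUE iff \code{searchHits} returns at least one hit at the
#'   E-value cutoff.
#' @export
hasHits <- function(query, db, params = SearchParams()) {
    nrow(searchHits(query, db, params)) > 0L
}

#' Write hits as tabular (outfmt-6 style) TSV
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore, with 1-based inclusive coordinates and subject
#' coordinates swapped on minus-strand hits.
#'
#' @param hits a hit data.frame from \code{\link{searchHits}}.
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
writeHitsTable <- function(hits, path) {
    out <- data.frame(
        qseqid = hits$query_id, sseqid = hits$record_id,
        pident = round(100 * hits$identities /
                       pmax(1L, hits$alignment_length), 2),
        length = hits$alignment_length, mismatch = hits$mismatches,
        gapopen = hits$gap_openings,
        qstart = hits$qstart + 1L, qend = hits$qend,
        sstart = ifelse(hits$strand == "+", hits$sstart + 1L, hits$send),
        send = ifelse(hits$strand == "+", hits$send, hits$sstart + 1L),
        evalue = signif(hits$e_value, 3),
        bitscore = round(hits$bit_score, 1))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read tabular (outfmt-6 style) hits
#'
#' Adapter ingesting standard 12-column tabular alignment output -- from
#' this package or from real blastn -- into the internal hit data.frame, so
#' downstream vetting is search-tool agnostic.  Raw scores are
#' back-computed from bit scores with the configured Karlin-Altschul
#' constants.
#'
#' @param path TSV path (no header, 12 columns).
#' @param params a \linkS4class{SearchParams} for score back-conversion.
#' @return hit data.frame as returned by \code{\link{searchHits}}.
#' @export
readHitsTable <- function(path, params = SearchParams()) {
    raw <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(raw) != 12L) stop("expected 12 tab-separated columns")
    names(raw) <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                    "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                    "bitscore")
    minus <- raw$sstart > raw$send
    ss <- ifelse(minus, raw$send, raw$sstart) - 1L
    se <- ifelse(minus, raw$sstart, raw$send)
    data.frame(
        query_id = raw$qseqid, record_id = raw$sseqid,
        qstart = raw$qstart - 1L, qend = raw$qend,
        sstart = ss, send = se,
        strand = ifelse(minus, "-", "+"),
        raw_score = (raw$bitscore * log(2) + log(params@karlin_K)) /
            params@karlin_lambda,
        bit_score = raw$bitscore, e_value = raw$evalue,
        identities = as.integer(round(raw$pident * raw$length / 100)),
        alignment_length = raw$length, mismatches = raw$mismatch,
        gap_openings = raw$gapopen, stringsAsFactors = FALSE)
}
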