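#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib RiboSeek, .registration = TRUE
NULL

RNA_ALPHABET <- c("A", "C", "G", "U")
SHAPIRO_LABELS <- c("R", "E", "S", "H", "I", "B", "M")

#' RNASequence: an RNA sequence with identifier
#'
#' Nucleotide string over \{A,C,G,U\}.  Input letters T and lowercase are
#' normalised to U/uppercase on construction.
#'
#' @slot id character identifier.
#' @slot description free-text description.
#' @slot residues the normalised residue string.
#' @exportClass RNASequence
setClass("RNASequence",
    representation(id = "character", description = "character",
                   residues = "character"),
    validity = function(object) {
        if (length(object@residues) != 1L || nchar(object@residues) < 1L)
            return("residues must be a single non-empty string")
        bad <- setdiff(unique(strsplit(object@residues, "")[[1]]), RNA_ALPHABET)
        if (length(bad))
            return(paste0("illegal residue(s): ", paste(bad, collapse = ", ")))
        TRUE
    })

#' SecondaryStructure: a nested RNA secondary structure
#'
#' Dot-bracket string paired with its base-pair set (0-based index pairs,
#' i < j).  Pseudoknots are not representable.
#'
#' @slot dotbracket the dot-bracket string over \{., (, )\}.
#' @slot pairs integer matrix with columns i, j (0-based, i < j), one row per
#'   base pair, ordered by i.
#' @exportClass SecondaryStructure
setClass("SecondaryStructure",
    representation(dotbracket = "character", pairs = "matrix"),
    validity = function(object) {
        db <- object@dotbracket
        if (length(db) != 1L) return("dotbracket must be a single string")
        if (grepl("[^.()]", db)) return("dotbracket may contain only . ( )")
        p <- .pairs_from_dotbracket(db)
        if (is.character(p)) return(p)
        if (!identical(unname(object@pairs), unname(p)))
            return("pairs slot does not match dotbracket")
        TRUE
    })

#' ShapiroTree: coarse-grained structural motif tree
#'
#' Ordered labelled tree over the motif alphabet R (virtual root), E
#' (external single strand), S (stem), H (hairpin loop), I (interior loop),
#' B (bulge), M (multibranch loop).  Nodes are stored in preorder.
#'
#' @slot labels character vector of node labels, preorder.
#' @slot parent integer vector; parent[i] is the preorder index of node i's
#'   parent, 0 for the root.
#' @slot span integer matrix (n x 2) of 0-based half-open sequence spans.
#' @exportClass ShapiroTree
setClass("ShapiroTree",
    representation(labels = "character", parent = "integer", span = "matrix"),
    validity = function(object) {
        n <- length(object@labels)
        if (n < 1L) return("tree must have at least the root node")
        if (!all(object@labels %in% SHAPIRO_LABELS))
            return("labels must be in {R,E,S,H,I,B,M}")
        if (sum(object@labels == "R") != 1L || object@labels[1L] != "R")
            return("exactly one R node, at the root")
        if (object@parent[1L] != 0L) return("root must have parent 0")
        if (n > 1L && any(object@parent[-1L] >= seq_len(n)[-1L] |
                          object@parent[-1L] < 1L))
            return("parent indices must precede children (preorder)")
        hairpins <- which(object@labels == "H")
        if (any(hairpins %in% object@parent))
            return("H nodes must be leaves")
        TRUE
    })

#' MotifConstraint: protected fragment and fixed nucleotides
#'
#' Marks a region of the target structure whose dot-bracket must be
#' reproduced exactly by a design (e.g. the ligand-binding multibranch loop)
#' plus individual nucleotide positions fixed to required residues.
#'
#' @slot region integer(2), 0-based half-open interval on the target.
#' @slot substructure required dot-bracket over the region.
#' @slot fixed_positions integer vector of 0-based positions.
#' @slot fixed_nucleotides character vector of required residues, parallel to
#'   \code{fixed_positions}.
#' @exportClass MotifConstraint
setClass("MotifConstraint",
    representation(region = "integer", substructure = "character",
                   fixed_positions = "integer",
                   fixed_nucleotides = "character"),
    validity = function(object) {
        if (length(object@region) != 2L || object@region[1L] < 0L ||
            object@region[2L] < object@region[1L])
            return("region must be a valid 0-based half-open interval")
        if (nchar(object@substructure) !=
            object@region[2L] - object@region[1L])
            return("substructure length must equal the region width")
        if (length(object@fixed_positions) !=
            length(object@fixed_nucleotides))
            return("fixed_positions and fixed_nucleotides must be parallel")
        if (anyDuplicated(object@fixed_positions)) {
            dup <- object@fixed_positions[duplicated(object@fixed_positions)]
            keys <- paste(object@fixed_positions, object@fixed_nucleotides)
            if (anyDuplicated(object@fixed_positions[!duplicated(keys)]))
                return("conflicting nucleotides fixed at the same position")
        }
        if (length(object@fixed_nucleotides) &&
            !all(object@fixed_nucleotides %in% RNA_ALPHABET))
            return("fixed nucleotides must be A, C, G or U")
        TRUE
    })

#' FoldEngine: pluggable minimum free energy folding backend
#'
#' @slot name engine name ("builtin" or "vienna").
#' @slot fold function(residues) returning list(dotbracket, dG); must be
#'   deterministic for a fixed sequence.
#' @exportClass FoldEngine
setClass("FoldEngine",
    representation(name = "character", fold = "function"))

#' ObjectiveWeights: fixed weights of the five-term design objective
#'
#' The weights are the published constants of the flexible inverse folding
#' objective: 100 (neutrality), 1 (dG), 1000 (motif), 100 (Shapiro tree
#' distance), 0.01 (base-pair distance).  The neutrality and dG terms are
#' disabled by default.
#'
#' @slot w_neutrality,w_dG,w_motif,w_shapiro,w_bp numeric weights.
#' @slot enable_neutrality,enable_dG logical term switches.
#' @exportClass ObjectiveWeights
setClass("ObjectiveWeights",
    representation(w_neutrality = "numeric", w_dG = "numeric",
                   w_motif = "numeric", w_shapiro = "numeric",
                   w_bp = "numeric", enable_neutrality = "logical",
                   enable_dG = "logical"))

#' ObjectiveBreakdown: per-term value of the design objective
#'
#' @slot neutrality_term,dG_term,motif_term,shapiro_term,bp_term weighted,
#'   non-negative term values.
#' @slot total their sum.
#' @exportClass ObjectiveBreakdown
setClass("ObjectiveBreakdown",
    representation(neutrality_term = "numeric", dG_term = "numeric",
                   motif_term = "numeric", shapiro_term = "numeric",
                   bp_term = "numeric", total = "numeric"),
    validity = function(object) {
        terms <- c(object@neutrality_term, object@dG_term, object@motif_term,
                   object@shapiro_term, object@bp_term)
        if (any(terms < 0)) return("all terms must be non-negative")
        if (abs(object@total - sum(terms)) > 1e-9)
            return("total must equal the sum of the five terms")
        TRUE
    })

#' AnnealSchedule: simulated annealing schedule for inverse folding
#'
#' @slot initial_temperature starting temperature (> 0).
#' @slot cooling_factor geometric cooling factor in (0, 1).
#' @slot steps_per_temperature iterations between cooling steps.
#' @slot max_iterations budget on objective evaluations.
#' @slot lookahead_width maximum number of positions mutated jointly per
#'   proposal (the four-nucleotide look-ahead).
#' @slot rng_seed integer seed driving the run.
#' @exportClass AnnealSchedule
setClass("AnnealSchedule",
    representation(initial_temperature = "numeric",
                   cooling_factor = "numeric",
                   steps_per_temperature = "integer",
                   max_iterations = "integer",
                   lookahead_width = "integer",
                   rng_seed = "integer"),
    validity = function(object) {
        if (object@initial_temperature <= 0)
            return("initial_temperature must be > 0")
        if (object@cooling_factor <= 0 || object@cooling_factor >= 1)
            return("cooling_factor must be in (0, 1)")
        if (object@steps_per_temperature < 1L)
            return("steps_per_temperature must be >= 1")
        if (object@max_iterations < 1L)
            return("max_iterations must be >= 1")
        if (object@lookahead_width < 1L)
            return("lookahead_width must be >= 1")
        TRUE
    })

#' DesignResult: an inverse-folding design with its objective breakdown
#'
#' @slot sequence the designed \linkS4class{RNASequence}.
#' @slot structure the engine's fold of the sequence.
#' @slot dG predicted folding energy of the design.
#' @slot breakdown \linkS4class{ObjectiveBreakdown} against the target.
#' @slot iterations_used objective evaluations spent.
#' @slot seed_sequence_id id of the seed the run started from.
#' @slot converged TRUE when the objective reached 0 within budget.
#' @slot multiplicity how many batch runs produced this exact sequence.
#' @exportClass DesignResult
setClass("DesignResult",
    representation(sequence = "RNASequence", structure = "SecondaryStructure",
                   dG = "numeric", breakdown = "ObjectiveBreakdown",
                   iterations_used = "integer", seed_sequence_id = "character",
                   converged = "logical", multiplicity = "integer"))

#' EscapeTrace: record of a mutational escape from the similarity well
#'
#' @slot start,end the initial and final \linkS4class{RNASequence}.
#' @slot mutation_path data.frame with columns position (0-based), from, to.
#' @slot hits_at_each_step database hit count after each mutation.
#' @exportClass EscapeTrace
setClass("EscapeTrace",
    representation(start = "RNASequence", end = "RNASequence",
                   mutation_path = "data.frame",
                   hits_at_each_step = "integer"),
    validity = function(object) {
        n <- nrow(object@mutation_path)
        if (length(object@hits_at_each_step) != n)
            return("one hit count per mutation step is required")
        cur <- strsplit(object@start@residues, "")[[1]]
        if (n > 0) {
            for (r in seq_len(n)) {
                p <- object@mutation_path$position[r] + 1L
                if (cur[p] != object@mutation_path$from[r])
                    return("mutation path does not apply to start sequence")
                cur[p] <- object@mutation_path$to[r]
            }
        }
        if (paste(cur, collapse = "") != object@end@residues)
            return("applying the mutation path to start must yield end")
        TRUE
    })

#' SearchParams: scoring and filtering for the local similarity search
#'
#' Defaults mimic the "somewhat similar sequences" blastn task: word size 7,
#' match +2, mismatch -3, gap open -5, gap extend -2, E-value cutoff 10.
#' The Karlin-Altschul constants are the published ungapped values for the
#' +2/-3 scheme (lambda 0.625, K 0.41).
#'
#' @slot word_size exact-match seed length (>= 4).
#' @slot match,mismatch,gap_open,gap_extend alignment scores.
#' @slot x_drop score drop-off terminating ungapped extension.
#' @slot gap_trigger raw ungapped score above which a gapped extension runs.
#' @slot e_cutoff maximum reported E-value.
#' @slot karlin_lambda,karlin_K E-value calibration constants.
#' @slot search_space effective search space for the E-value; NA (default)
#'   uses query length times both strands of the database.  Pin to a large
#'   value (e.g. 1e10) to reproduce the significance regime of a
#'   genome-scale database on a small fixture, as blastn's -searchsp does.
#' @exportClass SearchParams
setClass("SearchParams",
    representation(word_size = "integer", match = "numeric",
                   mismatch = "numeric", gap_open = "numeric",
                   gap_extend = "numeric", x_drop = "numeric",
                   gap_trigger = "numeric", e_cutoff = "numeric",
                   karlin_lambda = "numeric", karlin_K = "numeric",
                   search_space = "numeric"),
    validity = function(object) {
        if (object@word_size < 4L) return("word_size must be >= 4")
        if (!(object@match > 0 && object@mismatch < 0))
            return("match must be > 0 and mismatch < 0")
        TRUE
    })

#' SearchDatabase: k-mer indexed nucleotide database
#'
#' Sequences are stored on the forward strand as DNA; the word index covers
#' both strands and is rebuilt deterministically from the input.
#'
#' @slot ids record identifiers.
#' @slot sequences forward-strand DNA strings, parallel to ids.
#' @slot index environment hashing each word to an integer matrix of
#'   (record, offset0, strand) postings; strand 1 = plus, 2 = minus.
#' @slot word_size word length used to build the index.
#' @slot total_length total plus-strand length.
#' @exportClass SearchDatabase
setClass("SearchDatabase",
    representation(ids = "character", sequences = "character",
                   revcomp = "character", index = "environment",
                   word_size = "integer", total_length = "numeric"))

#' CandidateReport: structural assessment of one database window
#'
#' @slot record_id database record containing the window.
#' @slot location integer(2), 1-based inclusive forward-strand interval.
#' @slot strand "+" or "-".
#' @slot window the extracted window as \linkS4class{RNASequence}.
#' @slot structure predicted fold of the window.
#' @slot bp_distance base-pair distance to the query structure.
#' @slot shapiro_distance Shapiro tree edit distance to the query.
#' @slot preserved_positions 0-based positions identical to the query.
#' @slot e_value E-value of the supporting similarity hit.
#' @slot verdict TRUE when the window is accepted as a candidate.
#' @exportClass CandidateReport
setClass("CandidateReport",
    representation(record_id = "character", location = "integer",
                   strand = "character", window = "RNASequence",
                   structure = "SecondaryStructure",
                   bp_distance = "integer", shapiro_distance = "integer",
                   preserved_positions = "integer", e_value = "numeric",
                   verdict = "logical"))

setClassUnion("MotifConstraintOrNULL", c("MotifConstraint", "NULL"))

#' PipelineConfig: full configuration of a search run
#'
#' @slot query the known aptamer as \linkS4class{RNASequence}.
#' @slot reference its reference secondary structure.
#' @slot constraint optional \linkS4class{MotifConstraint}.
#' @slot db the target \linkS4class{SearchDatabase}.
#' @slot mode "general" (inverse-folding restoration) or "covariant".
#' @slot n_escape number of escape traces (study-scale default 500).
#' @slot runs_per_seed inverse-folding runs per escaped seed (default 20).
#' @slot search_params \linkS4class{SearchParams}.
#' @slot schedule \linkS4class{AnnealSchedule}.
#' @slot engine \linkS4class{FoldEngine}.
#' @slot rng_seed master seed; every stage derives its own seed from it.
#' @slot max_mutations escape budget per trace (default 3 x query length).
#' @slot output_dir directory for stage outputs, NA to keep in memory only.
#' @exportClass PipelineConfig
setClass("PipelineConfig",
    representation(query = "RNASequence", reference = "SecondaryStructure",
                   constraint = "MotifConstraintOrNULL",
                   db = "SearchDatabase", mode = "character",
                   n_escape = "integer", runs_per_seed = "integer",
                   search_params = "SearchParams",
                   schedule = "AnnealSchedule", engine = "FoldEngine",
                   rng_seed = "integer", max_mutations = "integer",
                   output_dir = "character"),
    validity = function(object) {
        if (!object@mode %in% c("general", "covariant"))
            return("mode must be 'general' or 'covariant'")
        if (object@n_escape < 1L) return("n_escape must be >= 1")
        if (object@runs_per_seed < 1L) return("runs_per_seed must be >= 1")
        if (nchar(object@query@residues) !=
            nchar(object@reference@dotbracket))
            return("query and reference structure must have equal length")
        TRUE
    })
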