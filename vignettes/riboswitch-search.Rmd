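---
title: "Methods: structure-based riboswitch search by inverse folding"
author: "RiboSeek authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-based riboswitch search by inverse folding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its method: the model and its
assumptions, the parameters that matter, the synthetic fixtures the tests
run on, and the design decisions taken where the design was genuinely open.

## The method

The search rests on one biological premise: riboswitch aptamer domains are
conserved in *shape* more strongly than in sequence, and their predicted
minimum free energy (MFE) secondary structure is informative (for the
guanine aptamer of *B. subtilis xpt*, the MFE prediction closely matches
the experimentally derived structure — this is checked once, on the query,
by `preflight()`; it is the only folding accuracy assumption the pipeline
makes).

Instead of folding every window of the target database (quadratic cost,
unverifiable per-window accuracy), the method moves the *query* around
sequence space:

1. `randomEscape()` applies successive uniform single-point mutations,
   re-querying the database after every mutation, until the sequence has no
   similarity hits at the configured E-value cutoff.  The walk is recorded
   as an `EscapeTrace` and is replayable from its seed.
2. `inverseFold()` takes the escaped sequence as the starting point (rather
   than a random guess) and anneals it back toward sequences predicted to
   fold into the query's structure, under nucleotide and fragment
   constraints.
3. `searchHits()` screens every unique design against the database.
4. `extractWindow()` + `assessCandidate()` fold an aptamer-sized window
   around each hit and accept or reject it on coarse-grained shape.

The covariant mode (`runCovariant()`) is the special case in which both the
outbound and inbound walks use only structure-preserving (compensatory)
mutations: every intermediate folds exactly to the reference, so no solver
is needed.  It covers a far smaller portion of sequence space and exists
mainly because it is cheap and exactly reproducible; the general mode is
the method proper.

## The objective and its weights

`evaluateObjective()` scores a candidate against the target as

  f = 100·|Δneutrality| + 1·|ΔdG| + 1000·motif_missing +
  100·d_Shapiro + 0.01·d_bp

The weights are fixed constants of the method, not tunable parameters:

* **motif, weight 1000.** The protected fragment (for purine aptamers, the
  ligand-binding multibranch loop) is a hard constraint to be satisfied
  without compromise; the weight dominates every other term.  The formula's
  motif term is implemented as a *penalty indicator* — 1 when the required
  substructure is absent over the constraint region — since rewarding
  presence would favour motif-violating candidates, contradicting the
  constraint's intent.
* **Shapiro tree distance, weight 100.** The shape-preservation signal: the
  ordered tree edit distance (unit costs, Zhang–Shasha) between
  coarse-grained motif trees over labels {R, E, S, H, I, B, M}.  We use the
  unweighted coarse grain — no size annotations — because shape, not motif
  size, is the conserved signal; the acceptance rule tolerates motifs a few
  base pairs larger or smaller.
* **base-pair distance, weight 0.01.** Defined as the symmetric-difference
  cardinality of the two base-pair sets (the dominant convention, and a
  metric).  Its only role is to break ties among shape-identical solutions
  so designs are not over-dominated by shape; at weight 0.01 the choice of
  base-pair-distance dialect is immaterial to the search.
* **neutrality (weight 100) and dG (weight 1), both off by default.**
  Neutrality — mutational robustness — is computed as the mean over all 3L
  single-point mutants of `1 − d_bp(fold(mutant), fold(s))/L`, clipped to
  [0, 1]; the antecedent solver's exact formula is unpublished, so this
  definition is a declared, compatible stand-in.  Both terms are disabled
  by default because new riboswitches of different composition may
  legitimately differ in robustness and stability; flags on
  `ObjectiveWeights()` re-enable them.

## The annealer

`inverseFold()` is simulated annealing with geometric cooling
(initial temperature 10, factor 0.95 every 50 iterations, at most 10
000 objective evaluations, early exit at objective 0).  Moves are biased
shape-preserving: positions paired in the target mutate as compensatory
pair substitutions drawn from {AU, UA, GC, CG, GU, UG}; unpaired positions
mutate singly; fixed positions never move.  The "four-nucleotide
look-ahead" of the original solver is unpublished mechanism-wise; here it
is realised as proposal bundles of up to four jointly mutated positions
(bundle size uniform on 1..4), accepted by the Metropolis rule on the
objective change.  Wobble pairs are admitted in the covariant move set
because riboswitch stems contain them; `allow_wobble = FALSE` restricts to
Watson–Crick.

Runs are deterministic given the schedule seed; `designBatch()` derives an
independent seed per (seed sequence, run index) pair and collapses
duplicate designs with multiplicities.  The study-scale protocol sends 500
escaped sequences to the solver 20 times each; the testing profile uses
10 × 2 with a 800-evaluation budget, which is ample for the 53-nt fixture
aptamer.

## Fold engines

* `nussinovEngine()` — a Nussinov-style dynamic program with pair scores
  GC −3, AU −2, GU −1 (arbitrary energy units reported as dG), minimum
  hairpin loop 3 nt, and a deterministic traceback that prefers pairing the
  5'-most base at ties, to its nearest admissible partner.  It is exact for
  its own scoring model (verified against brute-force enumeration of all
  nested structures for short sequences) and fully reproducible, which is
  why tests and fixture pipelines use it.
* `viennaEngine()` — an adapter around `RNAfold` with current Turner
  parameters, for biological interpretation.  Predictions shift between
  energy-parameter revisions: the preQ1 worked example's 17-mutation escape
  sequence keeps the wild-type two-hairpin architecture but with a
  one-position stem shift under current parameters, so the tests assert the
  motif inventory rather than exact pair identity.  No temperature or ionic
  parameters are exposed; defaults are used throughout.

Lonely pairs are permitted at parse time (`parseDotBracket()` accepts any
balanced nested string; the engine decides what it produces); pseudoknots
are rejected — the whole machinery is nested-structure only.

## The similarity search and its significance model

`searchHits()` is a self-contained seed-and-extend local aligner standing
in for blastn's "somewhat similar sequences" task: word size 7, match +2,
mismatch −3, gap open −5, gap extend −2, E ≤ 10, with ungapped x-drop
extension first and a gapped (affine Smith–Waterman) re-extension for
seeds above a raw score of 22.  E-values use the Karlin–Altschul formula
with the published ungapped constants for +2/−3 (λ = 0.625, K = 0.41) —
calibration constants, not fitted values.  An adapter
(`readHitsTable()`) ingests standard 12-column tabular output, so real
blastn can be substituted behind the same hit type.

One parameter deserves emphasis: `search_space`.  On a genome-scale
database the E ≤ 10 threshold corresponds to a substantial alignment; on a
few-kilobase fixture the same formula makes chance 8-mers "significant",
and the zero-hit escape criterion would be unreachable.  Pinning
`search_space = 1e10` (as blastn's `-searchsp` option does) reproduces the
significance regime of a large database on a small fixture; every fixture
configuration in the package does this.  Verdicts were validated against a
full Smith–Waterman scan (via Biostrings) in that regime; under the
permissive raw default the known, documented miss class appears —
alignments whose score clears the tiny-database threshold without
containing any exact 7-word seed are found by the exhaustive scan only.
The implementation never reports a hit the scan would not.

## Candidate vetting

`assessCandidate()` folds the window and accepts iff the Shapiro distance
to the query is at most 2 *and*, when a motif constraint is configured, the
coarse label sequence over the constraint region matches the query's.  The
raw base-pair distance is reported but does not gate acceptance: shape-
preserved homologs routinely show base-pair distances in the tens from
minor shifts between coarse-grained motifs, which is precisely why the
method keys on the tree distance.  The textual "one or two base pairs" of
tolerance maps to motif-size flexibility inside the coarse tree, not to the
base-pair metric.  The default Shapiro threshold of 2 matches the distance
observed for confirmed bacterial candidates; it is configurable.

Window extraction anchors on the hit's query offset (the alignment's query
start dictates the upstream extension), clips at record edges by shifting
inward, and works in reverse-complement space for minus-strand hits.  For
gapped hits the anchoring convention is declared rather than derived — the
alignment's query start is taken at face value.

Hits whose window is a verbatim copy of the query are reported separately
as "known" sites rather than candidates, mirroring the expectation that
most hits of designed sequences are already-known riboswitches.  The
Shapiro label convention here includes the virtual root R in the tree (it
never contributes to distances between well-formed trees, since both roots
match).

## The synthetic fixture generator

`generateFixture()` builds the study conditions for all end-to-end tests:
uniform-random background records (default 4 × 600 nt in the testing
profile) with planted homologs produced by 15 covariant mutations of a
53-nt synthetic multibranch aptamer, placed at recorded coordinates on
random strands.  Positions 12–31 (0-based) form a conserved core emulating
the essential ligand-binding nucleotides that real aptamer families keep —
this is also what the design constraint fixes, so designed sequences and
genuine homologs share an anchor, as they do in reality.  The scrambled
negative control permutes all non-core positions of the plant (same
composition, destroyed structure), so it is still *findable* by sequence
similarity but must be rejected by the structural vetting: it tests the
vetting, not the aligner.

What the generator does not emulate: real genomic base composition and
repeats, gene context, homologs with insertions/deletions relative to the
query (windows are fixed-length), and families whose conservation pattern
differs from the planted core.  Passing fixture tests therefore
demonstrates the machinery — escape, restoration, screening, vetting,
coordinate bookkeeping — not sensitivity on real genomes, which depends on
the thermodynamic engine and the real database through their own error
modes.

## Problem sizes and numerical choices

Test and acceptance runs use sizes chosen to exercise every code path with
comfortable margins: fold-oracle enumeration up to 18 nt (23 434 nested
structures), tree-edit oracle over a systematic family of trees up to 6
nodes, search-oracle databases of a few kilobases, 50 inverse-folding
convergence runs on random nested targets of 15–25 nt at the default
budget, and 10 + 10 end-to-end pipeline runs on independently seeded
fixtures.  All randomness flows through explicitly derived 32-bit seeds;
identical configuration and seed give byte-identical outputs at every
stage.  Degenerate inputs behave conservatively: sequences too short to
pair fold to the open chain (dG 0) rather than erroring, a query that
already has no hits yields an empty escape trace, and exhausted mutation
budgets raise a typed error carrying the partial trace.

## Known limitations

* Nested secondary structure only; pseudoknotted aptamers are out of scope.
* The built-in engine's scoring is a maximum-stacking surrogate, not a
  thermodynamic model; conclusions about real sequences should use the
  ViennaRNA engine, whose predictions in turn shift between parameter
  revisions.
* The local aligner targets correctness at fixture scale, not BLAST's
  throughput; for genome-scale screening, run real blastn and ingest its
  tabular output.
* Fixed-length windows mean homologs with sizeable insertions relative to
  the query are assessed against a shifted frame.
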