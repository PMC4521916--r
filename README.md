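# RiboSeek

Structure-based riboswitch discovery by inverse RNA folding.

## The problem

Riboswitches are cis-acting mRNA elements that bind a small metabolite and
regulate gene expression without proteins. Their aptamer domains are
conserved in both sequence and structure, but sequence-only search (BLAST
and friends) has been largely exhausted for finding new ones — especially
outside bacteria — while naive structure-based search (folding every window
of a genome) is computationally prohibitive.

RiboSeek implements an energy-minimisation, structure-based search that
*transforms the structure search into sequence space*, so that a fast
sequence similarity search does the genome-scale work:

1. **Escape** — mutate a known aptamer (random point mutations, or
   structure-preserving covariant mutations in the special case) until it no
   longer has any database hits: the sequence has left its similarity
   "well".
2. **Restore** — give each escaped sequence to a flexible inverse-folding
   solver that mutates it back toward sequences predicted to fold into the
   aptamer's shape, while honouring fixed ligand-binding nucleotides and an
   exactly-preserved structural fragment (the multibranch loop of the
   purine aptamer, in the worked example).
3. **Screen** — search every designed sequence against the nucleotide
   database; hits in the borderline between "no hits" and "the familiar
   known sites" are candidate loci.
4. **Vet** — cut an aptamer-sized window around each hit, fold it, and
   compare to the query structurally; windows are accepted on the
   coarse-grained shape, not raw base-pair identity.

The inverse-folding solver minimises, by simulated annealing over sequence
space with proposals bundling up to four jointly mutated positions, the
five-term objective

```
f(candidate, target) = |neutrality_t − neutrality_c| · 100
                     + |dG_t − dG_c| · 1
                     + motif_missing(candidate) · 1000
                     + d_Shapiro(target, candidate) · 100
                     + d_bp(target, candidate) · 0.01
```

where `d_Shapiro` is the ordered tree edit distance between coarse-grained
(Shapiro) motif trees, `d_bp` is the symmetric-difference base-pair
distance, and `motif_missing` is a hard-constraint penalty indicator. The
neutrality (mutational robustness) and dG (thermodynamic stability) terms
are available but disabled by default: genuine new riboswitches may
legitimately differ in both.

Folding runs behind a pluggable engine contract: a fully deterministic
built-in Nussinov-style engine (oracle-verifiable, used by tests and
reproducible pipelines) or ViennaRNA's `RNAfold` (thermodynamically
realistic, used for biological interpretation).

## Worked example

The *B. subtilis xpt* guanine aptamer (69 nt) folds into its known
three-stem multibranch architecture:

```r
library(RiboSeek)
apt <- xptAptamer()
fold <- foldMFE(apt, viennaEngine())
fold$structure
#> SecondaryStructure (69 nt, 19 base pairs)
#>   ((((((((.....(((((.......)))))..........((((((.......))))))..))))))))
shapiroTree(fold$structure)
#> ShapiroTree (7 nodes): R(S(M(S(H),S(H))))
```

A full search run on a synthetic genome fixture with two planted,
sequence-diverged but structure-preserved homologs (15 covariant mutations
each, conserved ligand-binding core):

```r
builtin <- nussinovEngine()
query <- RNASequence(
    "AGACACCAUUCUAGUUGGUGCGAUUAGACCGGGAAGUUCGGGUUAUGGUGGGA",
    id = "demo_aptamer")
reference <- foldMFE(query, builtin)$structure
core <- c(12L, 32L)
constraint <- motifConstraintFromStructure(
    reference, c(12L, 41L),
    fixed_positions = core[1]:(core[2] - 1L),
    fixed_nucleotides = strsplit(substr(residues(query), 13, 32), "")[[1]])

fx <- generateFixture(query, reference, n_records = 4, record_length = 600,
                      n_planted = 2, divergence_steps = 15,
                      conserved_region = core, engine = builtin,
                      rng_seed = 101)
db <- buildDatabase(fx$sequences)

cfg <- PipelineConfig(query, db, reference = reference,
                      constraint = constraint, mode = "covariant",
                      n_escape = 10, runs_per_seed = 2,
                      search_params = SearchParams(search_space = 1e10),
                      engine = builtin, rng_seed = 5)
preflight(cfg)
#> $bp_distance      [1] 0
#> $shapiro_distance [1] 0
#> $dG               [1] -42
#> $n_hits           [1] 2

candidates <- runCovariant(cfg)
candidateTable(candidates)[, c("record_id", "start", "end", "strand",
                               "verdict", "bp_distance",
                               "shapiro_distance", "n_preserved")]
#>   record_id start end strand verdict bp_distance shapiro_distance n_preserved
#> 1 record_01   287 339      -    TRUE           0                0          47
#> 2 record_02    86 138      -    TRUE           0                0          43
```

Both planted loci (truth: `record_01:287-339(-)` and
`record_02:86-138(-)`) are recovered as accepted candidates: the windows
refold exactly to the query's shape (Shapiro distance 0) even though only
47 respectively 43 of 53 nucleotides are preserved. `mode = "general"`
replaces the covariant walk with random escape plus the inverse-folding
solver, which explores far more of sequence space at higher cost.

A thin command-line wrapper over the same functions is installed as
`exec/riboseek` (subcommands `preflight`, `escape`, `design`, `search`,
`assess`, `run`, configured by a YAML file; see `readPipelineConfig`).

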