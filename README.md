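# pseudophy

Detection and phylogenetic mapping of gene-inactivating (pseudogenizing)
mutations in codon alignments.

When a protein-coding gene decays into a pseudogene, the wreckage is
readable in a codon alignment: frameshift insertions and deletions (length
≢ 0 mod 3) and nonsense substitutions (a sense codon turned into `TAA`,
`TAG` or `TGA`), each introducing a premature stop codon. Given a gapped
DNA alignment with one intact reference taxon, `pseudophy`:

* **scans** every taxon for inactivating mutations in the reference reading
  frame, locates the premature stop each mutation introduces, merges
  identical mutations shared across taxa, and classifies each ORF as
  intact or disrupted;
* **infers** a maximum-likelihood phylogeny under nucleotide models up to
  HKY85 + Γ (Felsenstein pruning in compiled code, discrete-gamma rate
  variation, AIC model selection over the nested set
  {JC69, K80, F81, HKY85} × {uniform, +Γ}, heuristic
  stepwise-addition/NNI search, nonparametric bootstrap, outgroup
  rooting), coding insertions as excluded and deletions/nonsense codons as
  missing data;
* **maps** each mutation onto the branch where it arose under a
  single-origin (Dollo) assumption — the edge above the MRCA of its
  carriers — flagging homoplasy with Fitch extra steps instead of hiding
  it, and partially orders events along lineages;
* **simulates** codon alignments with planted mutations, including a
  canonical 14-taxon fixture emulating *Tas1r1* exon-3 pseudogenization in
  pinnipeds (453 aligned columns; a +4 bp insertion shared by four
  phocids, a −1 bp deletion and a nonsense codon in the northern elephant
  seal, a nonsense codon shared by two otariids, and a +2 bp insertion in
  the giant panda).

The model core: for sites *i* with pattern likelihoods computed by pruning,
log L = Σᵢ wᵢ log[ (1/k) Σ_c Σ_x π_x L_x^{root}(i; r_c) ], with HKY
transition probabilities P(t) from the rate matrix scaled to one expected
substitution per site, κ the transition/transversion rate ratio, π the base
frequencies (observed counts), and r₁…r_k the k = 4 equal-probability
discrete-gamma category rates (category means, mean 1). Model choice is by
AIC = 2k − 2 log L.

## Worked example

```r
library(pseudophy)

sim  <- simulate_pinniped_fixture(seed = 1)        # the 14-taxon fixture
scan <- classify_orf(sim$alignment)
mutation_table(scan$mutations)[, c("kind", "start_col", "end_col",
                                   "length_bp", "taxa",
                                   "introduced_stop_col")]
#>                    kind start_col end_col length_bp
#> 1   frameshift_deletion        61      61         1
#> 2 nonsense_substitution        61      63         3
#> 3  frameshift_insertion       188     191         4
#> 4 nonsense_substitution       248     250         3
#> 5  frameshift_insertion       297     298         2
#>                                                    taxa introduced_stop_col
#> 1                                       n_elephant_seal                  62
#> 2               australian_sea_lion,s_american_sea_lion                  61
#> 3 caspian_seal,harbor_seal,n_elephant_seal,spotted_seal                 193
#> 4                                       n_elephant_seal                 248
#> 5                                           giant_panda                 299

table(scan$orf_status$status)
#> disrupted    intact
#>         7         7
```

Five merged mutations: the 1-bp deletion at column 61 and the nonsense
codon at 248 are unique to the northern elephant seal, the 4-bp insertion
at 188–191 is shared by all four phocids, the nonsense codon at 61 by the
two otariids, and the 2-bp insertion at 297–298 by the giant panda alone —
so the six pinnipeds plus the giant panda are disrupted and the remaining
seven carnivorans intact. Each mutation's premature stop is located
(`introduced_stop_col`); for frameshifts it is found by translating the
carrier's own sequence in the shifted frame.

Continue to the phylogeny and the event mapping:

```r
mat <- encode_for_ml(sim$alignment, scan$mutations)   # 447 sites retained
model <- hky_gamma_model(4, c(0.30, 0.20, 0.25, 0.25), alpha = 0.5)
ml  <- search_ml_tree(mat, model, n_restarts = 5, seed = 1)
bs  <- bootstrap_support(mat, model, ml, n_replicates = 200, seed = 2)
rooted <- root_tree(bs$tree, c("domestic_dog", "red_fox"))
pl  <- place_events(rooted, build_event_matrix(scan$mutations,
                                               sim$alignment$taxa))
order_events(pl, rooted)
```

All five events place Dollo-consistently: the +4 bp insertion on the stem
of the four phocids, the otariid nonsense on the two-otariid stem, the
elephant-seal deletion and nonsense on its terminal branch (after the
shared insertion, which `order_events()` reports as preceding both), and
the panda insertion on its terminal branch. Or run everything in one call
— `run_pipeline(pipeline_config(fixture_seed = 1, ...))` — or from a
shell via `inst/scripts/run_pipeline.R`.

For real data, `read_fasta_alignment()` ingests any pre-aligned gapped
multi-FASTA (for the emulated study these would be GenBank accessions
AB697513–AB697524, HM468451 and HM468447, aligned upstream; fetching is
deliberately outside the library).

## Package layout

* `R/seqio.R` — alignment/Newick/report I/O, `codon_alignment` data model
* `R/orf_scan.R` — frame map, indel/nonsense detection, stop location,
  ORF classification
* `R/model.R`, `R/likelihood.R`, `R/optimize.R`, `R/search.R`,
  `src/pruning.cpp` — HKY+Γ likelihood, fitting, AIC selection, tree
  search, bootstrap, rooting
* `R/event_mapping.R` — Dollo placement, Fitch steps, event ordering
* `R/synth_data.R` — simulator and the 14-taxon fixture
* `R/pipeline.R` — end-to-end orchestration
* `vignettes/pseudogene-mapping.Rmd` — methods, assumptions, design
  rationale and limitations
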