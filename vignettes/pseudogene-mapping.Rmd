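---
title: "Detecting and mapping gene-inactivating mutations on a phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and mapping gene-inactivating mutations on a phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis

A protein-coding gene becomes a pseudogene when its reading frame is
disrupted — by a frameshift insertion or deletion (length not a multiple of
3) or by a nonsense substitution that converts a sense codon into `TAA`,
`TAG` or `TGA`. Each such mutation introduces a premature stop codon and
truncates the protein. The canonical example this package ships as its
validation fixture is the umami taste receptor gene *Tas1r1* in pinnipeds:
a partial exon-3 codon alignment of 14 carnivorans in which all six
pinnipeds and the giant panda carry inactivating mutations while seven other
carnivorans retain an intact open reading frame.

`pseudophy` reproduces that style of analysis end to end:

1. **Scan** a gapped codon alignment against an intact reference taxon,
   report every frameshift indel and nonsense substitution with 1-based
   inclusive alignment columns, locate the premature stop codon each
   mutation introduces, and classify every taxon as `intact` or `disrupted`.
2. **Infer** a maximum-likelihood phylogeny under HKY85 with discrete-gamma
   rate variation, select the substitution model by AIC, attach
   nonparametric bootstrap supports, and root with a designated outgroup.
3. **Map** each mutation onto the branch where it arose under a
   single-origin (Dollo) assumption and order events along lineages.
4. **Simulate** codon alignments with planted mutations to validate all of
   the above.

## Scanning for inactivating mutations

The scan works entirely in the *reference frame*: the reading frame of a
designated taxon whose ORF is intact (the domestic dog in the fixture).
Columns where the reference has a gap are *inserted relative to the
reference*; the remaining columns inherit codon indices and codon positions
cycling 1–2–3 from the alignment's frame anchor (`frame_offset`, the codon
position of the first reference column — 1 by default, exposed as a
parameter because a partial exon segment need not begin on a codon
boundary).

Three deliberate conventions, chosen to mirror how such alignments are
annotated in practice:

* **Nonsense calls are made in the reference frame even downstream of a
  frameshift in the same taxon.** The fixture's northern elephant seal
  carries a 1-bp deletion at column 61 and a nonsense codon at column 248;
  annotating in the reference frame reports both, exactly as the emulated
  figure does.
* **Indel runs are defined against the reference row only**, not a
  consensus, and runs are contiguous in reference coordinates, so an
  unrelated insertion block cannot split a deletion in two.
* **Codons containing `N` or a partial gap are skipped, not called**, and a
  stop codon truncated by the segment edge is not called. Both rules are
  conservative: a partial exon should not yield speculative calls.

Identical mutations in different taxa (same kind, same columns, same
inserted/deleted/substituted bases — for nonsense, the same stop codon) are
merged into one shared record, because a shared identical mutation is the
signature of a single ancestral event. The merged record's
`introduced_stop_col` is the earliest located stop over its carriers. For a
frameshift, the stop is located by translating the taxon's *own* ungapped
sequence through the mutation: its other deletions and insertions shift the
frame as well, which is also why a deletion/insertion pair whose lengths sum
to a multiple of 3 restores the downstream frame and yields no attributable
stop.

## The likelihood machinery

The phylogenetic core follows the study design the fixture emulates:
maximum likelihood under HKY + Γ, model chosen by AIC, with a specific
missing-data coding — *insertions are not considered; deletions and
nonsense substitutions are coded as missing data*. `encode_for_ml()`
implements that coding: inserted columns are dropped (453 → 447 sites in
the fixture); deletion gaps and the three bases of each nonsense codon are
recoded `?` in the affected taxa only; every remaining gap or `N` also
becomes `?`. A `?` contributes a partial likelihood of 1 for all four
nucleotides, one mechanism for all missing data.

The pruning algorithm runs in compiled code over compressed site patterns,
with the closed-form HKY transition matrix (rate matrix scaled to one
expected substitution per site, so branch lengths are in
substitutions/site). Among-site rate variation uses `k = 4`
equal-probability discrete gamma categories represented by their category
means (the mean rule), renormalised to average exactly 1. The model family
is the nested set {JC69, K80, F81, HKY85} × {uniform, +Γ} — eight
candidates that bracket the fixture's generating model; AIC = 2k − 2 logL
with `k` counting substitution free parameters (0/1/3/4, +1 for the gamma
shape) plus one branch length per edge. Branch lengths are shared by every
candidate on a fixed topology, so including them shifts all AIC values
equally and the ranking matches the conventional model-selection count.
Base frequencies are estimated by observed counts, standard HKY practice.

Numerical choices: branch lengths are optimised by Brent search on
[1e−8, 10] (the floor keeps the transition matrix well-conditioned; the
ceiling is far beyond saturation); coordinate-ascent sweeps stop when the
log-likelihood improves by less than 1e−6; κ and α are optimised on log
scale within [0.02, 100] and [0.05, 20]. The likelihood is invariant to
re-rooting (the model is time-reversible), which the tests verify to 1e−8,
and the pruning kernel is checked against brute-force summation over all
ancestral-state assignments on trees of up to 5 taxa.

## Tree search, bootstrap, rooting

The search contract is "find the ML tree", not any particular search
mechanism. For ≤ 7 taxa the package is exhaustive over all unrooted
topologies (each gets a light branch-length pass, the top three a full
optimisation). Beyond that it uses random-addition-order stepwise addition
(5 starts by default) followed by NNI hill-climbing: neighbours are screened
with inherited branch lengths, the best is re-optimised and accepted only if
it improves, and at convergence no neighbour screens above the fully
optimised tree. Exact likelihood ties are broken toward the
lexicographically smallest canonical Newick string, so results are
reproducible. All stochastic choices flow from a single integer seed.

Bootstrap pseudoreplicates resample encoded sites with replacement and rerun
the search; supports are the percentage of replicate trees containing each
ML-tree bipartition. Replicate searches use two stepwise-addition starts
rather than five — a deliberate effort/accuracy trade-off: at the fixture's
size a single start was measurably prone to NNI local optima, while two
starts removed the artefact at half the cost of the main search. The
default replicate count is 1,000; the validation suite runs 200, which is
ample to separate ≥ 95% supports from weak ones.

Rooting is by outgroup (both canids in the fixture): the root is placed on
the edge separating the outgroup from the ingroup, and a non-exclusive
outgroup raises an error naming the missing bipartition rather than rooting
arbitrarily.

## Dollo placement of events

Each merged mutation is assigned to the edge above the most recent common
ancestor of its carriers. When the carriers are exactly that clade the
placement is Dollo-consistent: one origin, no losses. Anything else is
homoplasy, which is *reported, never silently resolved* — the record keeps
`dollo_consistent = FALSE` together with the number of extra steps required
by Fitch parsimony on the binary presence/absence character. Events whose
carriers span the root are flagged rather than placed, because an origin on
the root edge is not identifiable from the data. Events are partially
ordered: A precedes B when A's branch is a strict ancestor of B's; events on
one branch — like the elephant seal's deletion and nonsense codon, whose
relative timing the data cannot resolve — stay incomparable.

## What the simulator emulates — and what it does not

`simulate_alignment()` generates the statistical structure the analysis
assumes: a root sequence drawn codon-wise from the stationary frequencies
(rejecting in-frame stops), HKY + Γ substitution noise along a rooted tree
(each site keeps one gamma category across the whole tree), and planted
events inherited from their branch by all descendants. The canonical
`make_pinniped_fixture()` instantiates the 14-carnivoran study structure: 149
reference codons (447 bp; 453 aligned columns with the two insertions), the
+4 bp insertion at columns 188–191 on the four-phocid stem, the −1 bp
deletion at 61 and nonsense at 248 on the elephant seal terminal branch,
the nonsense at 61 on the two-otariid stem, and the +2 bp insertion at
297–298 on the giant panda terminal branch. With the default frame anchor,
columns 61 and 248 both fall on first codon positions once insertion
columns are removed — the printed positions are internally consistent.
Four additional intact taxa (`intact_carnivoran_1`–`4`) are generic
placeholders rather than named species; the fixture's topology groups the
phocids, the otariids, the pinnipeds as a whole and the two canids exactly
as the analysis expects, with standard carnivoran relationships elsewhere.

Four generator design points deserve justification:

* **Stop-codon repair.** Substitution noise occasionally creates an
  in-frame stop in a lineage that should be intact; left alone, such a stop
  would fake a nonsense event. Every reference-frame codon that is not a
  carried planted-nonsense codon is therefore kept sense, in every lineage,
  by resampling the offending codon from its parent (the repair is applied
  per codon rather than per taxon so that taxa carrying planted events are
  equally protected against *additional* accidental stops). Repairs are
  logged in the returned `repairs` table.
* **Frozen event sites.** Planted payloads, planted nonsense codons and the
  planted downstream stops are excluded from substitution noise in carrier
  lineages. Shared events must remain base-identical across carriers for
  the scanner's merge rule to see one ancestral event, which is precisely
  the property the emulated figure displays.
* **Deterministic planted stops.** Each planted frameshift is paired with a
  `TGA` planted in the shifted frame directly downstream (columns 193–195,
  62–64 and 299–301 for the three frameshifts), at positions chosen so the
  planted bases can never form a stop in the *reference* frame of any
  carrier. Every disrupting event therefore yields a locatable premature
  stop under every seed.
* **Nonsense planting** substitutes the minimal number of bases to reach
  `TGA`, falling back to `TAA` when `TGA` is not reachable in one change —
  transition-biased, as real nonsense mutations tend to be.

Model defaults (κ = 4, π = (0.30, 0.20, 0.25, 0.25), α = 0.5, branch
lengths 0.02–0.15) give carnivoran-like divergence: enough noise that the
scan's conservatism matters, enough signal that the generating topology is
recoverable. Within those lengths the phocid and otariid stems carry on the
order of 10–20 expected substitutions across the 447 retained sites, which
is what makes their ≥ 95% bootstrap supports attainable.

What the simulator does **not** model: stochastic indels (all indels are
planted, so indel false-positive behaviour is untested against indel
noise), selection or dN/dS structure, base-for-base mimicry of the real
GenBank sequences, sequencing error, and alignment error (inputs are taken
as correctly aligned — the alignment step itself is out of scope). Passing
the validation suite therefore demonstrates correctness of the machinery on
data satisfying the model assumptions, not robustness to misalignment or to
indel-rich histories.

## Problem sizes used in validation

The test suite exercises: the exhaustive-summation likelihood oracle on
100 random trees of ≤ 5 taxa; model selection and κ recovery on a 6-taxon
tree at 10,000 sites (10 and 20 simulation seeds respectively); planted-event
recovery on the full fixture across 20 seeds; ML search on the 14-taxon,
447-site fixture with 5 restarts; and a 200-replicate bootstrap. These
sizes were chosen so each property is tested at a scale where failure would
be unambiguous while the whole suite stays comfortably runnable on a
laptop.

## Worked example

```{r, eval = FALSE}
library(pseudophy)

sim <- simulate_pinniped_fixture(seed = 1)
scan <- classify_orf(sim$alignment)
mutation_table(scan$mutations)

mat <- encode_for_ml(sim$alignment, scan$mutations)
fit <- select_model(mat, nj_tree <- ape::nj(
  ape::dist.dna(ape::as.DNAbin(tolower(mat$states)), "JC69",
                pairwise.deletion = TRUE)))
ml <- search_ml_tree(mat, fit$model, n_restarts = 5, seed = 1)
bs <- bootstrap_support(mat, fit$model, ml, n_replicates = 200, seed = 2)
rooted <- root_tree(bs$tree, c("domestic_dog", "red_fox"))
pl <- place_events(rooted, build_event_matrix(scan$mutations,
                                              sim$alignment$taxa))
order_events(pl, rooted)
```

Or in one call:

```{r, eval = FALSE}
res <- run_pipeline(pipeline_config(fixture_seed = 1, n_bootstrap = 200,
                                    seed = 1, output_dir = "run1"))
res$placements
```

## Known limitations

* The likelihood kernel does not rescale partial likelihoods per node; for
  the tree sizes this package targets (tens of taxa) double precision has
  orders of magnitude of headroom, but trees of many hundreds of taxa could
  underflow.
* IUPAC ambiguity codes beyond `N` are rejected rather than interpreted.
* The candidate model set is the nested eight; models with invariant-site
  classes or free rate matrices (GTR) are out of scope.
* NNI hill-climbing from multiple random-addition starts is a heuristic; as
  with any heuristic search, a sufficiently adversarial likelihood surface
  could defeat it. The exhaustive path (≤ 7 taxa) and the restart mechanism
  are the mitigations.
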