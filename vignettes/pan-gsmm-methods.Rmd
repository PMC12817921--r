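---
title: "Methods: pan-GSMM reconstruction and multi-strain phenotype prediction"
author: "panmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-GSMM reconstruction and multi-strain phenotype prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panmet)
```

This vignette is the package's account of the science behind its
pipeline: the models and procedures, the parameters that matter and why
they default to what they do, the numerical choices, what the synthetic
test world does and does not establish, and the known limitations.

## The constraint-based model

A genome-scale metabolic model (GSMM) in `panmet` is a stoichiometric
network: metabolites with element formulas and charges, reactions with
stoichiometric coefficients and flux bounds (mmol·gDW⁻¹·h⁻¹), a biomass
objective, and one gene-protein-reaction rule (GPR) per reaction. A GPR
is a boolean tree whose AND nodes represent enzyme complexes (all
subunits required) and OR nodes isoforms (any suffices); the EMPTY rule
means "no gene requirement" and always evaluates true, so reactions
curated into a reference without gene assignments (orphans, the biomass
equation, maintenance requirements) survive derivation. Absence of genes
is expressed by the distinct UNSATISFIABLE marker that
`gpr_substitute()` produces when a complex loses all support — this
separation is what lets reference orphans flow into every strain model
while gene-losing reactions are pruned.

Flux balance analysis (FBA) maximizes the objective flux subject to
steady state ($S v = 0$) and bounds. The linear programs involved here
are small (tens of reactions), so the package carries its own dense
two-phase primal simplex with Bland's rule (`lp_solve()`); Bland's rule
trades speed for guaranteed termination on the heavily degenerate
steady-state systems metabolic networks produce. Feasible models whose
objective cannot carry flux report an optimum of 0, never
"infeasible" — infeasibility is reserved for inconsistent bound systems
(for example a maintenance flux floor that no carbon source can
sustain). The growth threshold defaults to $10^{-6}$ for `run_fba()` and
$10^{-4}$ for phenotype calls; both are exposed because the biologically
meaningful question is "can the network sustain flux at all", not the
exact LP value.

## Quality control

Strains are kept only if they satisfy, inclusively, all four thresholds:
at most 2% missing and 100% fragmented expected single-copy orthologs,
N50 of at least 50,000 bp, and at most 200 contigs. Inclusive comparison
follows from reading the thresholds as maxima/minima: a strain exactly
at a bound fulfills the criterion. The ortholog percentages are consumed
from a table rather than computed, which keeps the package free of
reference databases; N50 and contig counts are computed from the
assembly FASTA.

## Pangenome construction

Proteins are clustered greedily: sort by length descending (ties by gene
id, making the procedure a pure function of the input set), then each
sequence joins the best-scoring cluster whose representative it matches
at global identity ≥ 0.90 with coverage ≥ 0.70 of both representative
and candidate, or founds a new cluster. Identity is counted against the
shorter sequence, coverage as each sequence's aligned non-terminal-gap
span over its length; alignments are exact global ends-free alignments
(BLOSUM62, gap open 10, extend 0.5) rather than k-mer-prefiltered
heuristics — at the scale of tens of strains, exactness is affordable
and removes a source of order dependence. The PAM stores, per cluster ×
strain cell, the member gene ids; it is a partition of the gene set and
stays one through recovery.

### Gene recovery

Assembly and gene-calling artifacts systematically delete genes from
proteomes. Three scenarios are re-examined against the genome:

* **(i) split genes** — two adjacent same-strand annotated genes (gap ≤
  300 bp) whose concatenated proteins align to one representative at the
  clustering thresholds merge into one record flagged
  `premature_stop = TRUE`, replacing both parts in the PAM.
* **(ii) unannotated genes** — unannotated regions of at least 60 bp are
  six-frame translated and searched against representatives of clusters
  empty for the strain; the aligned span becomes a recovered record
  (flagged broken only if an internal stop interrupts it).
* **(iii) truncated annotations** — a window extending an annotated gene
  into adjacent unannotated sequence (up to 900 bp, clipped at
  neighbors, in the gene's own reading frame) is searched the same way;
  a hit reaching past the annotated part yields a record flagged
  `premature_stop = TRUE` that *replaces* the truncated annotation. The
  replace-rather-than-coexist choice was open; keeping both would
  double-count one locus and break the PAM's partition invariant, so the
  recovered call wins.

Scenarios (i) and (iii) search only clusters empty for the strain: a
cluster the strain already fills intact cannot gain a fragment call
(otherwise an intact gene adjacent to an unrelated fragment is
re-absorbed spuriously). Overlapping calls at one locus resolve by
highest identity, then longest span, then smallest cluster id. The
60 bp minimum region, 300 bp pair gap, and 900 bp window are pragmatic
defaults exposed through `recovery_params()`: the first is two typical
spacer lengths below the shortest credible gene remnant, the others
bound the search without crossing neighboring genes.

## Reference-free carving

Cluster representatives are aligned one-way against the universe's gene
sequences; a (gene, cluster) pair supports at identity ≥ 0.40 and
coverage ≥ 0.70 of the universal gene, scored identity × coverage. The
0.40 floor is the conventional twilight-zone boundary for confident
homology over 70% of a protein; both are configuration, not dogma. Each
universe reaction's GPR is rewritten by substituting genes with the OR
of supporting clusters, and the reaction is included only if the result
is satisfiable: a complex missing any subunit is excluded. This is
deliberately conservative — a false negative surfaces as a visible gap
for curation, while a permissively included reaction hides a wrong
network behind a right phenotype. Spontaneous reactions (marked by a
sentinel gene id in the universe, converted to a flag on load) and
EMPTY-GPR reactions are kept. Exchanges are created for every retained
extracellular metabolite with bounds (0, 1000): uptake is a property of
the medium, applied later, not of the network.

## Reference expansion

When a curated reference model exists, it is the backbone. Orthologs are
determined per strain by bidirectional best hits (score = identity ×
min coverage, thresholds 0.40/0.70; mutual best with lexicographic tie
break), and each reference gene maps to the cluster holding the
majority of its BRH partners (ties to the smallest cluster id; conflicts
are logged in the assignment table). Reference genes without partners
become placeholder leaves that evaluate absent for every strain — the
reaction stays in the pan model (the reference is trusted) but no strain
inherits it without other support. Scoring by identity × coverage rather
than alignment bitscore keeps the contract free of a substitution-matrix
dependency; at BRH-scale identities the rankings agree.

Draft reactions absent from the translated reference are added only if
they are not element/charge-unbalanced under reference-priority
metabolite definitions (the reference's formula/charge wins on id
collision). An `undetermined` verdict — unknown formula or charge
anywhere, or a boundary reaction, which cannot balance by construction —
passes by default: treating missing annotation as disqualifying would
silently reject most of any real universe; a strict flag inverts this.
The biomass equation and the non-growth-associated maintenance (NGAM,
reaction id `ATPM` by default) keep the reference's bounds bit-exactly.
Finally, reference orphans whose id exists in the draft with a non-empty
GPR get the draft's cluster-space rule; non-empty GPRs are never
overwritten, so the orphan count cannot increase. Orphan accounting
counts internal, non-spontaneous, EMPTY-GPR reactions whose name lacks
"diffusion"; by that definition the biomass and NGAM reactions
themselves count as orphans, which is why even a fully supplemented pan
reports a nonzero floor.

## Strain derivation and gap-filling

A strain's model is the pan model after GPR substitution: a cluster is
present only if the strain's PAM cell holds at least one gene without a
premature stop (one intact gene rescues a cluster; broken copies do not
contribute to the OR of substituted genes). Reactions whose GPR becomes
UNSATISFIABLE are removed, then metabolites used by no reaction and
boundary reactions serving only themselves are pruned — so a strain
without the xylose pathway also loses the xylose exchange.

Gap-filling finds a minimum-penalty set of repository reactions whose
addition lets the objective reach `min_flux` (default 0.001, a floor
just above solver noise) on a medium. The search is exact: best-first
branch-and-bound over candidates with two prunings — a node already
feasible needs no supersets (penalties are positive), and a node whose
fully open relaxation cannot reach `min_flux` is cut. Candidates unable
to carry flux even in the full augmentation are removed up front. Among
equal-penalty optima the lexicographically smallest id set is returned,
making results reproducible. For the automated ("autopilot") pan-level
gap-fill, penalties derive from the alignment evidence:
$p = p_{\min} + (1 - s)(p_{\max} - p_{\min})$ with fractional support
$s$ computed over the GPR (min across AND members, max across OR
branches, per-gene best score; EMPTY rules score 0 since they carry no
gene evidence), $p_{\min} = 0.1$, $p_{\max} = 10$. The formula is one
reasonable concretization of "penalties from alignment metrics" and is
isolated in `compute_penalties()` so alternatives plug in. Strain-level
gap-filling defaults to uniform penalties: at that stage the candidates
all come from the already-evidence-weighted pan. Multiple media are
processed in rounds, later rounds seeing earlier additions; an
infeasible medium is recorded and skipped, and the whole step can be
skipped for auxotrophy studies.

The default minimal aerobic medium opens glucose, ammonia, phosphate,
and sulfate as sole C/N/P/S sources at 10 mmol·gDW⁻¹·h⁻¹, plus o2, h2o,
h and a configurable trace-ion list, each restricted to exchanges the
model actually has.

## Phenotypes and multi-strain analysis

Substrate tests close the element's default source, open the candidate
at the same rate (keeping calls comparable), and ask whether growth
reaches the threshold; candidates without an exchange score 0.
Auxotrophy is defined as biosynthetic incapacity: maximize a temporary
demand for the cytosolic compound on the minimal medium with the
compound itself withheld — supplying it in the recipe cannot flip the
call. This demand-based definition stays meaningful when the minimal
medium alone does not support growth (the growth-rescue alternative is
undefined there); a rescue variant remains a configuration choice.
Biosynthesis tests are the same demand maximization with the opposite
polarity. All calls depend only on LP optima, never on a particular flux
vector, so solver degeneracy cannot flip them.

Binary feature tables (features × strains, cells 0/1) collect phenotype
calls and reaction presence. Strain similarity is the Jaccard index over
1-features (a pair with no features at all is at distance 0 by
convention, the only value that keeps the diagonal consistent);
dissimilarity is 1 − J, the standard complement. Ward's agglomerative
clustering is applied through the Lance–Williams update directly on
those distances — Jaccard distances are not Euclidean embeddings, so
this is Ward in its dissimilarity-update reading, accepted as-is and
matching `stats::hclust(method = "ward.D")`; ties merge the pair with
the smallest label pair, making the tree deterministic. Constant
features are kept by default (they do affect Jaccard similarity);
dropping them, or excluding named feature blocks such as an entire
pathway, are explicit options of `merge_bfts()`. Cutting the tree at
`k` yields groups labeled by decreasing size; characteristic features
rank by in-group minus out-group frequency. Confusion metrics against
experimental tables exclude missing cells and report undefined ratios as
`NA`, never 0.

## The synthetic world

`generate_world()` builds the complete study system from a seed: ~22
gene families (120–300 aa) with within-family identity ≈ 0.97 (well
above the 0.90 clustering threshold) and between-family identity at
random background (< 0.1); a universe of 39 reactions with element
formulas constructed so that every internal reaction except the biomass
and one deliberately unbalanced artifact balances exactly; 20 strains in
3 groups distinguished by a xylose-catabolism module, a
histamine-synthesis module, and loss of tryptophan synthase (an
auxotroph group); three planted recovery cases; two designed QC
failures; a curated reference covering the core metabolism with one
orphan reaction, an NGAM floor of 8.39, and one reference-only gene; and
two media recipes. Ground truth (cluster partition, post-recovery PAM,
per-strain reaction sets under both reconstruction routes, the three
phenotype tables, the strain partition) is computed from the planted
design by explicit module lists, not by running the pipeline machinery
on itself.

Passing against this world shows that every stage implements its
contract exactly under clean separations: identity margins are wide,
modules are discrete, truth is unambiguous. It does not show robustness
to the gradients of real data — borderline homology, mosaic gene
families, mis-assemblies beyond the three planted classes, biomass
equations in disagreement with the universe — and real phenotype
accuracy depends on universe and reference quality, which the world
idealizes. Problem sizes were chosen as the smallest that exercise every
code path with a three-group structure: 20 strains, ~313 proteins, a
39-reaction universe; the test suite and the acceptance script complete
in minutes on one core at those sizes.

## Numerical and degenerate-input choices

* LP tolerance 1e-9; phase-1 artificials above 1e-7 mean infeasible.
* Balance verdicts distinguish `unbalanced` from `undetermined`;
  exchange/sink/demand reactions (exactly one participating metabolite,
  classified by the `EX_`/`SK_`/`sink_`/`DM_` prefix dialect, which is
  configurable) are `undetermined` by convention.
* A medium recipe applied twice equals applied once; recipes resolve by
  exchange id or exchanged metabolite id, and unresolvable entries are an
  error by default (skippable).
* An empty reaction intersection in a species consensus yields a valid
  empty model plus a warning, not an error.
* Clustering, BRH, gap-filling, Ward merging, and cluster labeling all
  carry explicit deterministic tie-breaks; two runs on the same inputs
  are bit-identical, which the run manifest (config hash + seed) makes
  checkable.

## Limitations

* The simplex and the exact gap-fill search target desk-scale networks
  (≤ a few hundred reactions); genome-scale universes with thousands of
  reactions need an external MILP solver behind the same interfaces.
* SBML support covers Level 3 + FBC v2 core constructs (species,
  reactions, bounds-as-parameters, gene-product associations,
  objectives); exotic constructs (rate laws, hierarchical models) are out
  of scope.
* The auxotrophy definition is biosynthetic incapacity, not
  growth-rescue; the two differ for compounds that are growth-limiting
  but synthesizable.
* Gene recovery assumes prokaryotic single-exon genes; it will not
  reassemble spliced genes.
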