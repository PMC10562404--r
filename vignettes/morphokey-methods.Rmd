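---
title: "Morphological diagnosability and key logic in morphokey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological diagnosability and key logic in morphokey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphokey)
```

## The problem

The *Schistura cincticauda* species group comprises twelve small nemacheilid
loaches from streams of eastern Myanmar and western/southern Thailand. The
species are told apart not by any single character but by combinations of
meristic counts (fin rays, cephalic pores), a two-lobe caudal-ray formula,
and qualitative colour-pattern and anatomical states. `morphokey` turns that
diagnostic apparatus into computable objects: a character matrix, a
dichotomous key, diagnosability queries, specimen classification, and
unordered-parsimony mapping of the group's integer morphocode on a species
tree.

## The character model

A matrix cell is one of four value shapes:

* a **count range** `[lo, hi]` for meristic characters (a printed single
  value `n` is the degenerate range `[n, n]`);
* a **two-lobe formula** — a pair of count ranges, used for branched
  caudal-fin rays (`8 + 8`) and for the infraorbital pore formula (`4 + 9`);
* a **state set**, a non-empty subset of a closed per-character vocabulary;
  a set of size two or more is polymorphism (the table's "Variable" lip-mark
  entries become `{present, absent}`);
* the **unknown** marker `?`.

Two relations drive everything downstream:

* `compatible(value, observation)` — a point observation matches a taxon
  value (membership for states, inclusion for counts, both lobes in range
  for formulas; an observation *set* such as the holotype's asymmetric
  `{7, 8}` pectoral count matches if any member matches; unknown matches
  everything);
* `values_overlap(a, b)` — two taxon values admit a common observation.
  Two taxa are *distinguished* by a character exactly when their values do
  **not** overlap. Requiring disjointness (not merely different ranges)
  mirrors how the revision treats the overlapping Phuket counts as
  non-diagnostic, and unknown never distinguishes.

### Diagnostic grades

Each character carries a grade, `hard` or `soft`. The five pore-count rows
(lateral-line, supraorbital, infraorbital, supratemporal,
preoperculo-mandibular) are graded soft in the packaged matrix: the printed
table does show between-species differences in them, yet the revision's own
comparisons (e.g. *S. robertsi* vs *S. peninsulae*, stated to differ
externally *only* in pectoral and caudal ray counts) never rely on them —
they vary with preservation, observer and tiny sample sizes.
`pairwise_diffs()` reports all distinguishing characters with their grades,
so the hard subset reproduces the published statements while nothing is
hidden.

## The dichotomous key engine

A key is a set of numbered couplets, each with exactly two leads; a lead is
a conjunction of predicates and a target (another couplet or a taxon). The
reference graph must be acyclic with every couplet reachable — validated at
load.

Execution semantics, chosen to make the engine total over real data:

* a predicate is satisfied by a taxon record when the record's value
  *overlaps* the predicate's value set — so a wide range or polymorphic cell
  can satisfy both leads, and both branches are then explored (the printed
  key itself contains a lead reading "or at equal distance", proving leads
  are not always exclusive);
* an unknown or unobserved character satisfies both leads rather than
  dead-ending (the table's `?` cells would otherwise strand
  *S. paucifasciata*);
* a couplet where neither lead is satisfied contributes a dead end;
* **soft predicates** — statements about live coloration, body colour
  pattern or geography, which the matrix cannot represent — are recorded
  but skipped during routing by default (`use_soft = FALSE`). A lead whose
  predicates are all skipped is treated as satisfiable.

A consequence worth stating plainly: evaluated against the matrix alone,
the printed key does not route every species cleanly. *S. aurantiaca* is
scored "Middistance pelvic-anal" in the table yet the key sends it through
the anus-closer-to-anal leads; its record dead-ends at couplet 8, and
`verify_key()` reports exactly that. Species separated only by colour
pattern or live colours (*S. balteata*/*S. ataranensis*,
*S. paucifasciata*/*S. tenebrosa*, *S. peninsulae*/*S. crocotula*) trace as
ambiguous. The package reports these conflicts; it does not decide whether
the table or the key is authoritative.

### Key generation

`generate_key()` builds a key greedily: at each node it enumerates binary
splits of one character's value space (state-subset splits; integer
thresholds for counts and for each formula lobe), preferring splits that
assign every taxon at the node wholly to one side, then optimising the
objective (`minimax-branch` minimises the larger branch;
`min-expected-depth` a `n log n` expected-depth proxy), with ties broken by
character order and a lexicographic split description — construction is
fully deterministic. When no exact split exists (wide ranges, polymorphism,
unknowns) a fallback split separating one incompatible pair is used and
straddling taxa descend both branches; recursion still terminates because
each side excludes at least one taxon. Greedy construction is not provably
optimal; exact search is exponential and nothing here claims optimality.
When every node admits an exact split the key has exactly `n − 1` couplets,
as it does for the packaged matrix (11 couplets for 12 species), and
`verify_key()` passes for every taxon by construction.

## Diagnosability and classification

`minimal_diagnostic_sets()` enumerates all character subsets up to `k_max`
(default 4 — exhaustive enumeration over 18 characters is exact and cheap
at that size) and keeps the minimal subsets that separate the focal taxon
from every other taxon. Characters where the focal value is unknown can
never contribute; values carrying a printed uncertainty mark (the
*S. paucifasciata* caudal formula "9 + 8?") are demoted by default and
re-admitted with `include_uncertain = TRUE`.

One fixture-level finding: the *S. ataranensis* Diagnosis presents its 2–3
dorsal-fin stripes as uniquely distinguishing, but the binary table
character also scores stripes present for *S. balteata*, so no size-1
diagnostic set exists for it in the matrix — the stripes appear only in
size-2 minimal sets. The package reports what the matrix supports.

`classify_specimen()` computes, per observed character, the taxa compatible
with the observation; the overall candidate set is the intersection. An
empty intersection with two or more observed characters is a **conflict**,
reported with the characters whose candidate sets are mutually disjoint —
precisely the structure of the Phuket material, where 8 pectoral rays point
to *S. robertsi* while an 8+8 caudal formula points to *S. peninsulae*.
Matching is crisp throughout; there is deliberately no partial-credit
scoring.

## Parsimony mapping and synapomorphies

`fitch()` reconstructs unordered multistate characters on rooted trees,
polytomies included, with polymorphic tips entering as multi-state sets and
unknown tips as the full vocabulary. It is implemented as a two-pass
unit-cost dynamic programme (the polytomy-safe generalisation of the
classic set-intersection passes), so the reported quantities are exact:
`steps` is the minimum number of state changes, the downpass sets are the
states attaining the minimum subtree cost, and the uppass sets are the full
most-parsimonious-reconstruction (MPR) state sets. Branch lengths are
ignored. Tests and the acceptance script check `steps` against an
exhaustive enumeration over all internal assignments on hundreds of random
trees (up to 8 tips and 4 states, where enumeration is tractable).

Synapomorphy detection is two-tiered. Strictly, a character is a
synapomorphy of a clade when the MPR set at the clade's ancestor contains
only states absent from the outgroup. But a polymorphic tip adjacent to the
ancestor can pull the ancestral state into the MPR set even though every
clade member can show the derived state — exactly the situation of the
lower-lip marks, variable in *S. balteata* and *S. cincticauda* and
unobservable in the single old *S. paucifasciata* specimen. The second tier
therefore reports a state that (i) is present in every clade tip's set,
(ii) is absent from the outgroup, and (iii) reconstructs uniquely at the
ancestor once the polymorphic tips are resolved to it — flagged with a
caveat naming those tips. On the packaged data, with an outgroup known only
to lack the lip marks (every other outgroup state is unknown, hence
uninformative), the scan reports exactly one synapomorphy — lip marks,
state present — on every seeded resolution of the constraint tree.

The species tree itself is deliberately minimal: only the group's monophyly
and the (*S. balteata*, *S. paucifasciata*) sister pair are supported by
data, so `load_constraint_tree()` fixes those two clades and resolves the
rest randomly from an explicit seed, flagged `arbitrary_resolution`.
Anything claimed about reconstructions is therefore either proved invariant
across resolutions (the lip-mark synapomorphy) or reported per-resolution
(e.g. the axillary-lobe character needs at least two changes whenever the
four lobe-bearing species do not form a clade — an observation, not an
assertion, since the topology beyond the constraints is arbitrary).

Homoplasy indices follow the standard closed forms: `ci = (k − 1)/steps`
for `k` observed states, and `ri = (g − s)/(g − m)` with `m = k − 1` and
`g` = (tips with known states) − (modal state frequency); both are reported
absent when undefined (constant characters, `g = m`).

## The synthetic-data generator

`random_matrix()` emulates the structure of the packaged table: a mix of
qualitative, count and formula characters (default fractions 0.50 / 0.35 /
0.15, close to the table's 9 / 7 / 2), three states per qualitative
character, meristic ranges of width 0–2 as in real fin-ray counts, and
configurable polymorphism (default 0.05) and unknown (default 0.03) rates
matching the sparsity of "Variable" and "?" cells. `specimens_from_taxon()`
draws point observations uniformly from a taxon's value sets and perturbs
each with a configurable noise rate to an adjacent count or alternative
state, logging every perturbation together with whether it left the taxon's
value set. `random_resolved_tree()` produces seeded random coalescences
honouring required clades. All generators take an explicit integer seed,
scope their randomness locally (the caller's RNG state is untouched), and
are bit-reproducible.

What the generator does *not* emulate: correlated characters, clinal or
geographic variation within species, observer error structure beyond
single-step perturbation, and continuous morphometrics. Passing the
recovery experiments therefore shows the engine's logic is sound on data
matching its assumptions; it does not show that real specimens of
overlapping species are identifiable — the Phuket panels exist precisely
because sometimes they are not.

## Numerical and scale choices

Problem sizes in the tests and acceptance script were chosen so that every
oracle is exhaustive rather than sampled: parsimony is checked on 200 trees
of at most 8 tips and 4 states (at most 4^7 internal assignments each,
enumerated vectorised); diagnosticity on the 18-character fixture with
`k_max` up to 4; recovery experiments use 6-taxon disjoint matrices with 96
simulated specimens per run. Determinism is total: there are no tolerances
anywhere — every compared quantity is an integer or an exact set.

## Limitations

* The printed key's colour-pattern couplets cannot be routed from the
  matrix; with soft predicates enabled (`use_soft = TRUE`) they still
  require subjects that carry those extra characters.
* Minimal-set enumeration is exponential in `k_max`; the default of 4 is
  exact and fast at fixture scale but not meant for matrices with hundreds
  of characters.
* Parsimony is unordered and unweighted only; no likelihood or Bayesian
  reconstruction, and no molecular characters — the group's molecular
  phylogeny enters only as topological constraints.
* Nomenclature, morphometrics and distribution mapping are out of scope.
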