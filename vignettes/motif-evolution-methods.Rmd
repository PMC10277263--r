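---
title: "Methods: tracing degenerate motifs across a protein family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracing degenerate motifs across a protein family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motiphy)
```

`motiphy` operationalizes a common style of molecular-evolution analysis:
a deep protein family (the motivating case is the selenium-binding
protein / methanethiol oxidase family, with homologues from archaea to
mammals) carries a handful of short functional motifs — CC, CxxC/CSSC,
`*DEL`, HxD, HxxHC, a clathrin-binding box — whose canonical form,
lineage-specific variants, and gains and losses are traced across a
phylogeny.  This vignette records the models, parameter choices and
numerical conventions, and what the validation experiments do and do not
establish.

## The motif grammar

A motif pattern is an ordered list of position specifications compiled
from a small DSL: an uppercase letter is a literal residue, `x` matches
any of the 20 canonical residues, `[GKRDN]` an enumerated class, and
`{phi}` / `{pol}` property classes.  The built-in catalog
(`motif_catalog()`) covers CC, CxxC, CSSC, `[GKRDN]DEL`, HxD, HxxD,
HxxHC and the clathrin box `{pol}L{phi}{pol}{phi}{pol}`.

Choices worth recording:

- **Property classes.** The clathrin box is conventionally described
  verbally (φ a bulky hydrophobic residue, p any polar residue).  The
  operational memberships here are φ = {F, I, L, M, V, W, Y} and
  p = {C, D, E, H, K, N, Q, R, S, T, Y}; tyrosine deliberately belongs
  to both.  They are this package's definition, visible in
  `motif_classes()` and overridable per compilation.
- **Unknown residues.** `X` (and `-`) satisfy no position, including
  `x`.  An unknown residue must never fabricate a motif hit; the cost is
  that a motif overlapping a sequencing gap is reported as a variant or
  absent rather than guessed present.
- **Overlaps.** All windows satisfying a pattern are reported, including
  overlapping and nested ones, and each catalog entry is scanned
  independently: `CCSS` yields an intact CC match *and* a broken CxxC.
  Whether such a window "is" a CC or a damaged CxxC is an interpretive
  question the scanner deliberately does not answer; both reports are
  emitted.
- **HxD and HxxD** are both in the catalog.  Source descriptions of this
  family name both spellings without distinguishing them; keeping both
  is the neutral choice, and a scan simply reports each.

### Variant classification

`classify_variant()` aligns an observed window to a pattern by minimum
edit count: a residue satisfying its position spec costs 0, a violating
residue 1 (substitution), insertions and deletions 1 each.  Ties prefer
substitutions over indels, then the leftmost edit, making the reported
edit list deterministic.  Status is `canonical` at distance 0;
otherwise, windows longer than the pattern are `insertion`, shorter
`deletion`, equal-length `substitution` (with the substitution-first
tie-break, an equal-length optimum uses indels only when strictly
cheaper, which the equal lengths preclude); beyond `max_edits` the motif
is `absent`.  The default `max_edits = 2` is chosen because every named
lineage variant of the catalogued motifs (CSSS, CCSS, CSSSC, `*DEI`,
`*SEV`, HxE, HxN, RxD) lies within 2 edits of its canonical form.

## Alignment conservation

Column profiles follow sequence-logo conventions: frequencies are taken
over non-gap residues, entropy is `H = -sum f_a log2 f_a`, and the
information content is `R = max(0, log2(20) - H - e_n)` with the
Schneider–Stephens small-sample correction `e_n = 19 / (2 ln2 n)`.
Negative corrected values (possible at small `n`) are clipped to zero so
logo stacks remain drawable.  Unknown residues are treated as missing
observations, like gaps: they join neither the frequency denominator nor
an invariance claim.

**Invariant columns** require every row to carry the same canonical
residue with *zero* gaps.  "100% identical" could also be read as
ignoring gap rows; the stricter rule is adopted because conservation
claims tied to structural models implicitly concern fully occupied
columns.  For censuses restricted to, e.g., the positions resolvable in
a crystal structure, `invariant_residue_census()` accepts a column
subset, so either reading can be evaluated.

**Motif occupancy.** Canonical matches are located in each degapped row
and projected to alignment columns; overlapping column intervals are
merged, and merged intervals supported by at least 25% of rows become
the motif's anchor windows.  Every row is then called at each anchor:
`canonical` if it has a canonical match there, otherwise the best
`classify_variant()` result over sub-windows of the anchor slice
(`variant` with observed text and distance, or `absent`).  The 25%
threshold is an artifact parameter — a practitioner locates motif loci
by eye on a master alignment; 25% is low enough to anchor a motif
carried by one large clade and high enough to suppress most
chance matches.  Chance anchors still arise in diverged families (any
25% of rows sharing, say, an `HxD`-compatible triplet column-wise); they
are reported and are recognizable by their high change counts in the
parsimony stage.  Anchor detection sorts intervals, so the result is
invariant to row order.

## Homologue detection and profiling

The detection rule is: best local alignment per proteome, called present
iff identity ≥ 70% **and** query coverage > 80%.  Conventions, each of
which can shift results by a point or two and is therefore fixed
explicitly:

- Alignment is exact Smith–Waterman–Gotoh (via `Biostrings`), BLOSUM62,
  gap open 11, extend 1 (a length-L gap costs `11 + L`).  A heuristic
  seeded search would be faster on large proteomes but is out of scope;
  exactness keeps results deterministic and oracle-checkable.
- Identity = identities / all alignment columns, gap columns included.
- Coverage = (last − first + 1 aligned query position) / query length —
  the query-span convention, not the count of aligned residues.
- The identity threshold is non-strict (≥ 70), the coverage threshold
  strict (> 80); one best-scoring target per proteome is thresholded.

A consequence worth stating: a 70% identity rule is a *close-homologue*
criterion.  Family members at ~58% identity to the query — the typical
depth of the motivating family — fall below it by construction, which
the profiling stage of the analysis scripts demonstrates explicitly.
Detection experiments therefore use shallower divergence (~88% expected
identity), where the rule is decidable, and the thresholds remain
configuration values for users who want the screen itself to reach
deeper.

## Gain/loss mapping

Motif states (canonical / each observed variant text / absent, or a
collapsed present/absent mode) are mapped on the rooted tree exactly as
parsed — no re-rooting — by small parsimony over unordered states.  For
binary nodes this is Fitch's algorithm; multifurcations use Hartigan's
generalization (tally the children's preferred state sets; the deficit
from unanimity is the node's change count), which remains exact.
Branch lengths are ignored.  The ancestral labeling is made
deterministic by taking the parent's state wherever optimal and
otherwise the first (as parsed) child's preferred state; the change
*count* is tie-independent, and the reported labeling always realizes
it.  No statistical test for lateral transfer is implemented: parsimony
incongruence counts are reported, interpretation is left to the analyst.

## The simulator

The generator provides ground truth for every stage, under deliberately
simple models:

- **Substitutions**: per branch, each unprotected site mutates with
  probability `p`, uniformly to one of the other 19 residues.  The
  chance a site matches the root after `b` branches is
  `1/20 + (19/20)(1 − 20p/19)^b`, so `p` can be set from a target
  identity in closed form (`subst_prob_for_identity()`).  This is a
  20-state Jukes–Cantor-style model, not an empirical matrix: adequate
  for testing thresholds and recovery, non-biological in its residue
  preferences, and documented as such.
- **Indels**: Poisson events per branch, geometric lengths, placed
  outside protected windows so ground-truth motif coordinates stay
  well-defined (an indel never splits an implant).
- **Implants and switches**: motif instances are written into the root
  at fixed positions; protected windows evolve only through designated
  switch events on designated branches.  Protection makes switch
  branches homoplasy-free by construction — which is exactly what makes
  exact switch-branch recovery a fair test of the parsimony stage.
- **Proteomes**: each leaf's proteome is its family sequence (omitted
  for designed-absent leaves) plus composition-matched decoys, each
  rejection-screened against the query under the profiler's own rule so
  designed absences cannot be spoiled by a chance decoy hit.  The
  default of 20 decoys per proteome keeps profiling desk-scale.

Defaults mirror the motivating study's conditions: ~480-residue
proteins, target leaf–root identity 58.2%, the full catalog implanted.
Realized identities sit a point or two above the substitution-only
expectation because protected windows (≈21 of 480 residues under the
default implants) cannot diverge.

The synthetic **master-alignment stand-in**
(`simulate_master_alignment()`) provides a 129 × 479 alignment with a
designed conservation structure — exactly 43 invariant columns, 6 of
them histidine, a per-row fixed gap count so every row has equal
ungapped length, and a columnwise substitution probability solved from
the target mean identity.  The pairwise-alignment readout of mean
identity lands 1–2 points below the columnwise design because both rows
contribute gap columns to the alignment denominator; this approximation
is accepted rather than corrected, and validation tolerances account
for it.  The stand-in is fully synthetic: it exercises the conservation
statistics at a realistic scale, it is not the family's real alignment.

### What the validation does and does not show

The test suite and `scripts/acceptance.R` validate, at fixed seeds:
scanner equivalence with a window-by-window oracle (1,000 random
500-mers × the full catalog, plus exhaustive short-sequence sweeps);
variant-caller distances against exhaustive edit-path enumeration
(windows ≤ 8); aligner scores against exhaustive alignment enumeration
(pairs ≤ 6 over a 4-letter alphabet); parsimony counts against
exhaustive ancestral enumeration (500 trees ≤ 8 leaves, ≤ 3 states);
the closed-form information-content limits; and end-to-end recovery of
designed presence/absence and switch branches over 100 replicate
families (six leaves, 250 residues, ~88% expected identity — sizes
chosen to keep the full validation in the minutes range on one CPU).

These establish algorithmic correctness and closed-loop consistency on
data the generator can produce.  They do not establish robustness to
what it does not emulate: empirical substitution preferences, rate
heterogeneity across sites, domain-level rearrangements, alignment
uncertainty (the pipeline consumes alignments, it never infers them),
annotation noise in real proteomes, or compositional bias beyond the
query-matched decoys.  Results on real families inherit those caveats.

## Known limitations

- The aligner is exact but quadratic; screening very large proteomes
  wants a seeded heuristic upstream, with this package's rule applied
  to candidate pairs.
- Identity/coverage conventions differ slightly from heuristic search
  tools; absolute percentages near a threshold can flip between tools.
- Parsimony reports minimum-change scenarios only; it cannot
  distinguish lateral transfer from repeated loss, and no branch-length
  or model-based reconstruction is attempted.
- The occupancy matrix requires a trustworthy alignment; in highly
  gapped regions anchor windows can widen and variant texts lengthen.
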