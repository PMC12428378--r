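---
title: "Detecting alpha-satellite higher-order repeats with horscan"
author: "horscan maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting alpha-satellite higher-order repeats with horscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(horscan)
```

## The problem

Primate centromeres are built from ~171 bp alpha-satellite monomers
arranged head to tail over megabases. Monomers fall into *types*:
sequences less than 5% diverged from one another belong to the same type,
while different types typically diverge by 10–40%. In many arrays the
types recur in a fixed order — a higher-order repeat (HOR) unit of *n*
monomers, itself tandemly repeated with very low copy-to-copy divergence
(often well under 1%). Classical ("Willard-type") HOR units use each type
exactly once. More complex *cascading* units repeat some types
internally; laid out with one column per type, such a unit occupies
several rows, and structural variant copies arise by duplicating or
deleting whole rows or individual monomers.

`horscan` turns a raw assembly FASTA into: monomer coordinates and
orientations, a monomer type assignment, the monomer-distance (MD)
diagram and repeat-period frequency table, segmented HOR copies labelled
canonical (`C`) or variant (`V<m>`, by monomer count), the family
consensus sequence with divergence statistics, and the column-aligned
multi-row schematic of the unit.

## Pipeline and model choices

### Monomer extraction

Monomers are located by aligning a consensus monomer against the
sequence in both orientations and keeping matches with alignment identity
of at least `minIdentity` (default 0.95). Identity is edit-distance
based: matching columns divided by alignment columns of a unit-cost
global alignment, so isolated indels are tolerated. Implementation:
exact 12-mers of the consensus seed candidate locations (`matchPDict`);
each candidate is refined to exact boundaries by a *fit alignment*
(consensus aligned globally, the surrounding window free at both ends),
computed by a small C++ kernel; monomers that no exact seed survives are
recovered by aligning into the gaps left between accepted neighbours;
finally overlapping candidates are tiled greedily — higher identity
wins, ties go to the leftmost start. On sequences small enough to check,
this equals an exhaustive all-start/all-length alignment scan (tested).

The package ships a **synthetic** 171 bp consensus stand-in
(`defaultConsensus()`), generated once and frozen. It anchors all
simulations and tests; for real assemblies you should supply a curated
alpha-satellite consensus via the `consensus` arguments. All identity
thresholds are relative to whatever consensus is configured.

One geometric constraint deserves emphasis: if the monomer types of an
array are mutually at least `d` diverged, no single consensus can be
closer than `d/2` to all of them, so detection of every type requires
`minIdentity <= 1 - d/2 - noise`. For simulated libraries at 15%
inter-type divergence we scan at `minIdentity = 0.88`. The 0.95 default
is kept for conventionally curated consensus/array combinations.

### Monomer types

Types are assigned by greedy static-centroid clustering in enumeration
order: a monomer joins the first existing type whose *founding* monomer
is strictly less than `typeThreshold` (default 0.05) away, otherwise it
founds a new type. Static centroids avoid the chaining that single-link
clustering would allow (two monomers >5% apart ending up in one type),
and make the assignment order-stable and deterministic. After a
provisional HOR segmentation exists, `reconcileTypesWithColumns()`
re-checks monomers against the majority type of their aligned column and
reassigns them when the majority centroid is within the threshold —
positional context breaking ties that pairwise divergence alone cannot.
The operation is idempotent.

The divergence primitive itself (`pairwiseDivergence()`) divides the
Levenshtein distance by the number of alignment columns, taking among
cost-optimal alignments the one with the fewest columns; this makes the
ratio deterministic and symmetric. For clustering, a banded variant
answers "is the divergence below t?" exactly while skipping hopeless
comparisons.

### MD diagram and period calling

An MD-point `(l, p)` records that the monomer at enumeration `l` recurs
in type at distance `p` with no intervening occurrence. Counts per
period form the repeat-period frequency table. Horizontal line segments
at a period are called by chaining points whose enumeration gaps stay
within two periods and requiring at least `minRun` points (default 20)
at density `minDensity` (default 0.3).

Two numerical choices matter here and are deliberate:

* **Density default 0.3, not 0.5.** In a cascading unit only types
  occurring once per unit produce MD-points at exactly the unit period;
  a 58-monomer unit with 30 singleton types has expected density 30/58
  even before variant copies dilute it further, and the spec example
  unit `1,2,3,4,2,3,4,5` has density 2/8 at period 8. A 0.5 cut-off
  would reject precisely the structures the tool exists to find, while
  0.3 still rejects random type sequences (tested: no 20-point chain
  survives on uniform random types).
* **Unit period by coherence, not histogram argmax.** Internally
  repeated types concentrate MD-points on subfragment periods that can
  outnumber the unit period (in doublet-heavy arrays the period-2 count
  exceeds the unit count). Within each candidate region the unit period
  is therefore the smallest lag whose type-autocorrelation ("coherence":
  fraction of monomers whose type recurs exactly that lag later) reaches
  95% of the maximum. Exact multiples of the true period score equally
  high; taking the smallest qualifying lag resolves them.

Candidate regions are the union of qualifying segments over all periods,
merged with up to `maxPeriod` monomers of slack — variant copies
interrupt individual period chains, while genuinely distinct arrays sit
thousands of monomers apart.

### HOR copies, canonical unit, variants

Within a region, copy boundaries are fixed by an *anchor* type: among
types that occur once in the first observed exact cycle (cutting at an
internally repeated type would split units), the one that most
frequently begins an exact `n`-cycle, preferring candidates with the
fewest total occurrences (variants that duplicate a block inflate the
counts of duplicated types; cutting at one would split those variants),
ties to earliest occurrence. Occurrences of the anchor chained at gaps
of at most `2n` — never across a tandem-array boundary — delimit the
copies. The chain extends past the density-called region on purpose: a
variant-rich head or tail depresses exact-period density but still
carries the anchor in every copy. Partial stretches before the first and
after the last anchor are dropped, so a run of `c` planted copies yields
`c - 1` reported copies; stretches longer than `2n` are treated as
breaks, not copies.

The canonical unit is the most frequent complete `n`-mer among copies
(ties to earliest occurrence). A copy is `C` only on exact type-sequence
match; anything else is `V<m>` by monomer count, with the monomer-level
edit script against the canonical recorded. The rotation of the
canonical is whatever the anchor rule fixes; rotation affects neither
counts nor divergence.

The family consensus is a per-column majority vote over canonical
copies, columns given by unit position and, within a monomer, by global
alignment to the type centroid; base ties resolve alphabetically. Copy
divergence is measured monomer-by-monomer against this consensus (total
edits over total columns, reported in percent), and the family statistic
is the mean over canonical copies. Consensus-referenced divergence is
roughly half the mean pairwise value under independent noise; we use the
consensus reference because it is the quantity the consensus sequence
itself calibrates, and the simulator's calibration test pins the
estimator to the planted substitution rate within two standard errors.

### Cascade layout

`layoutCascade()` defines the aligned schematic constructively: a cursor
walks the unit left to right; a monomer of an already-columned type goes
to its column if that column lies right of the cursor, else it opens a
new row; a new type inserts a fresh column immediately right of the
cursor. The resulting grid provably satisfies both schematic invariants
(rows hold distinct types, columns hold one type) and flattening it
reproduces the unit exactly (property-tested). Willard-type units are
fixed points: one row, columns in unit order. Variant schemes are
row-aligned to the canonical by a type-overlap alignment; duplicated
rows appear as inserted repeat slots (the canonical showing a dash
there), deleted rows as dashes, which is exactly the familiar
row-count-table presentation of variant structure.

## The simulator, and what passing tests do and do not show

`simulateHORArray()` generates arrays with full ground truth. Type
libraries are planted as substitution sets on the consensus
(`ceiling(interTypeDiv * 171 / 2) + 2` substitutions per type, preferring
unused positions, resampled until all pairwise divergences reach
`interTypeDiv`); copies get i.i.d. per-base substitutions at
`perBaseMutRate` (default 0.0025, the sub-percent regime of recently
homogenised arrays); variant copies duplicate a cascade row (never the
first, which carries the likely anchor); uniform-random flanks (default
2 kb) exercise boundary handling, and optional N-runs exercise the
assembly-gap rule. Substitution-only noise keeps the divergence
arithmetic exactly binomial, which the calibration tests rely on; an
indel-bearing generator would blur that and is deliberately not the
default.

What the simulator does *not* emulate: unequal-crossover evolution and
the resulting gradients of relatedness between copies, monomer-length
polymorphism beyond alignment indels, interspersed non-alpha repeats,
strand switches inside one array, and sequencing/assembly artefacts. A
green test suite therefore demonstrates that the algorithms recover
planted structure under the stated noise model — not that every real
centromere will be segmented correctly; borderline canonical/variant
calls on real data remain possible exactly where local divergence blurs
copy boundaries.

Problem sizes in the tests were chosen so the whole suite stays
comfortably interactive: property tests use type sequences up to length
500 and units up to ~50 monomers; end-to-end recovery runs twenty seeded
arrays of 15–20 copies with 7–8-monomer units; calibration uses 50
copies of the full 58-monomer unit; the study-scale acceptance run uses
the complete 310-copy organisation (about 3.2 Mb). The same code path
handles chromosome-scale FASTA; only wall-clock time grows.

## Degenerate inputs and edge behaviour

Empty FASTA records, invalid BED intervals and empty monomer arrays
raise immediate errors. Sequences shorter than the consensus, random
sequence, and aperiodic type sequences yield empty results rather than
errors. IUPAC ambiguity codes other than N are normalised to N on input,
and any monomer overlapping an N is excluded before typing. Regions
shorter than two unit periods produce no copies. All tabular outputs are
written deterministically; re-running a pipeline with identical inputs
and configuration reproduces byte-identical TSV/JSON.

## Known limitations

* A structural variant that deletes the anchor-carrying row merges with
  its neighbour into one long variant copy; the copy count then differs
  from a row-level truth by one. Duplication variants — the dominant
  kind in real arrays — are unaffected.
* The anchor rule fixes a rotation of the canonical unit that need not
  match a published rotation; comparisons should be made up to rotation.
* The trailing copy of every array lacks a closing anchor and is
  reported as dropped, so copy counts are systematically one below the
  planted count on simulated data.
* Greedy first-fit typing depends on enumeration order at exact-boundary
  divergences (mitigated, but not eliminated, by column reconciliation).
* The MD-frequency table and the repeat-period diagram are computed from
  the same per-period point counts; if a use case requires the
  DNA-level k-mer variant of period detection, this package does not
  provide it.
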