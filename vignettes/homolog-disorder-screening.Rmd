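---
title: "Screening homologs by intrinsic disorder: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening homologs by intrinsic disorder: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexscan)
```

## The problem

Intrinsically disordered regions (IDRs) — stretches of a protein with no
fixed three-dimensional conformation — are a common reason recombinant
constructs express poorly, aggregate, resist crystallization or degrade.
Because disorder content varies considerably between orthologs of the same
protein, a practical route to a better-behaved construct is to screen the
query's homologs for one that is close in sequence but lower in disorder,
or to identify disordered regions of the query that are absent from its
more ordered relatives and truncate them. `flexscan` automates that
screen: homology search, per-residue disorder prediction, a hybrid score
that ranks hits on both axes at once, and comparative disorder-trace
alignment.

## The scores

**IDS.** For a protein of length $l$ with per-residue disorder scores
$s_r \in [0,1]$,

$$\mathrm{IDS} = \frac{\sum_{r=1}^{l} \gamma_r}{l} \times 100\%,\qquad
\gamma_r = \begin{cases}1 & s_r > \theta\\ 0 & \text{otherwise}\end{cases}$$

with threshold $\theta = 0.5$ by default. The inequality is strict: a
residue scoring exactly $\theta$ is not counted. IDS is displayed in
percent throughout.

**E-value transform.** Homology strength enters through a hyperbolic
transform of the search E-value $E$:

$$t(E) = 1 - 0.99^{(-\log_{10} E)^2}, \qquad t(0) \equiv 1.$$

As a function of $\log_{10} E$ this is sigmoidal and bounded in $[0,1]$:
near-linear between $E = 10^{-3}$ and $10^{-14}$, with the tails
approaching 0 (weak hits, $t(1) = 0$) and 1 (very strong hits). The
purpose is to converge the extreme low-end E-value range — once two hits
are both at astronomically small E-values their difference is not
biologically meaningful — while still resolving the middle and high
ranges where ranking matters. The $E = 0$ convention covers the query's
own entry (a self-hit always carries E-value 0) and E-value underflow.
Numerically, $t$ is within double-precision machine epsilon of 1 for
$E \lesssim 10^{-55}$; tests of strict monotonicity therefore restrict
themselves to the resolvable range.

**FLEX.** The hybrid score is a weighted average of homology and
intrinsic *order*:

$$\mathrm{FLEX} = (1-\eta)\, t(E) + \eta \left(1 -
\frac{\mathrm{IDS}}{100}\right)$$

where $\eta \in [0,1]$ is the priority coefficient, default $0.5$. IDS
enters as a fraction so that $\mathrm{FLEX} \in [0,1]$. At $\eta = 1$ the
score reflects intrinsic order only; at $\eta = 0$, homology only; the
score is linear in $\eta$. A hit with a FLEX score above the query's own
is a *superior homolog*: close enough to be a plausible functional
replacement and more ordered. `screen_summary()` counts superior homologs
and reports their IDS improvements (binned in 5-point increments by
`bin_improvements()`).

Three conventions in these formulas are deliberate and verified by the
test suite against the published 20-row worked example of the human CDC7
kinase screen: the logarithm is base 10 (natural log does not reproduce
the published FLEX values), IDS enters FLEX as a fraction although it is
displayed in percent, and $t(0) = 1$ (required by the query row). The
published table truncates FLEX to 4 decimals and prints E-values to 3
significant figures, which bounds how exactly any reimplementation can
reproduce it from the printed inputs (about $2.3 \times 10^{-4}$ in the
worst case); the acceptance test asserts that envelope and full printed
precision where the inputs are exact.

## Homology search

The built-in engine computes the optimal local alignment (affine gaps,
BLOSUM62, gap open 11 / extend 1) of the query against every library
sequence and converts raw scores $S$ to E-values with Karlin–Altschul
statistics,

$$E = K\,m\,n\,e^{-\lambda S},$$

with $m$ the query length, $n$ the **total** residue count of the library
(database-search convention, so E-values are comparable across subjects
and double exactly when the library doubles), and fixed published gapped
constants $\lambda = 0.267$, $K = 0.041$ for BLOSUM62/11/1. Exact numeric
agreement with NCBI BLAST is explicitly not promised — BLAST applies
edge-effect and composition corrections — but ranks agree in practice,
which is what the screen consumes; an optional adapter
(`external_blast_adapter()`) shells out to a BLAST+ executable when one
is available, and a test compares ranks between the two engines.
The pairwise aligner itself is delegated to
`Biostrings::pairwiseAlignment()`; an independent affine-gap dynamic
program written in plain R cross-checks its raw scores on hundreds of
small random instances in the acceptance suite.

Conventions fixed here (each one has to be *some* way, and these are
documented in the output): identity and similarity percentages use the
full alignment length including gap columns as denominator; similarity
counts columns with a positive substitution score, identities included;
equal E-values are broken by accession lexicographically; a self-hit is
detected by accession equality *or* full-sequence equality; the ambiguity
codes B/Z/X score via the matrix's published ambiguity rows and
selenocysteine (U) scores 0 against everything — tolerated, never
rewarded. Libraries at construct-design scale are small, so no heuristic
word seeding is used: every alignment is optimal.

## Disorder prediction is pluggable

Dedicated disorder predictors (IUPred being the classic
pairwise-energy-based one) are separate published methods with their own
parameter sets; reimplementing one is out of scope, and this package
makes no claim of accuracy parity with them. Instead the per-residue
trace is an interface with two providers:

* **External scores** (`read_score_file()` + `external_trace()`, or
  `score_dir` in a pipeline run): one score per residue in $[0,1]$, e.g.
  genuine IUPred output. This is the recommended path for real projects.
* **Built-in heuristic** (`predict_trace()`): over a centered window
  (long mode: 101 residues; short mode: 25; truncated at the termini),

  $$s = \mathrm{clamp}_{[0,1]}\!\left(0.45 - 0.08\,\overline{h} +
  0.25\,\lvert\overline{q}\rvert\right)$$

  with $\overline{h}$ the mean Kyte–Doolittle hydropathy and
  $\overline{q}$ the mean net side-chain charge of the window. The
  constants are fixed so that low-complexity polar/charged stretches
  (E/K/S/P/Q) score above 0.5 and hydrophobic globular cores well below —
  the compositional signal that underlies most disorder predictors. The
  long/short window pair mirrors the long-disorder vs short-disorder
  context distinction; long is the default for typical screens.

All scoring and alignment modules are provider-agnostic: nothing
downstream knows which predictor produced a trace.

## Viral polyproteins

A hit on an unprocessed polyprotein would inherit the disorder content of
thousands of residues the mature protein never sees. Given a local
chain-annotation TSV (columns `accession`, `chain_name`, `start`, `end`,
1-based inclusive — mirroring UniProt CHAIN features, since live feature
retrieval is out of scope), the pipeline maps each hit to the chain with
maximal residue overlap (ties to the smaller start) and computes IDS over
that fragment only, with the fragment length as denominator. When no
chain overlaps, the whole sequence is used and a warning logged. The
hit's E-value is kept as computed against the full polyprotein — the
homology evidence is what it is — and only the disorder metric is
restricted; this choice is deliberate and documented here because the
alternative (re-searching the fragment) changes the meaning of the
reported E-value.

## Trace alignment and segment calling

`align_sequences()` is a built-in progressive aligner, so comparisons
need no external binary: all-pairs global alignments (BLOSUM62, gap open
10 / extend 0.1) give distances $1 - \text{fractional identity}$, a UPGMA
tree (`stats::hclust`, average linkage) orders the merges, and profiles
are merged by profile–profile dynamic programming with column scores
$f_A^{\top} M f_B$ over residue frequency vectors (gap characters carry
zero weight). The defaults are this package's own convention — no claim
is made that boundaries match any particular external aligner — so
alignment-dependent outputs such as segment coordinates are
convention-bound, and the invariants the tests enforce are the ones that
matter regardless of convention: every row ungaps to its input exactly,
and identical sequences align without gaps.

`project_traces()` places each row's disorder scores at its non-gap
columns and sets gap cells to exactly 0.0, making insertions/deletions
visible in an overlaid trace; the cost is that 0.0 is overloaded (gap
vs. a genuinely ordered residue), which consumers are warned about — the
projected matrix carries an explicit gap mask for exact bookkeeping.
`disorder_conservation()` then calls maximal runs of query columns above
the threshold, reports them 1-based inclusive in query *residue*
coordinates (gap columns skipped), annotates each with the mean fraction
of other rows also disordered there, and flags segments below
`conserved_min` (default 0.5) as deletion candidates — disorder the
homologs do without, hence a rational truncation point.

## Synthetic fixtures

`make_family()` generates the test bed: an ancestor built from
composition pools (disordered blocks from {E,K,S,P,Q,G}, ordered blocks
from {L,I,V,F,W,Y,A,M}) and descendants derived by seeded point
substitutions (redrawn from the block's own pool, preserving block
character) and single-residue indels, with a ground-truth table of every
member's post-edit block structure. `make_score_profile()` emits
per-residue scores at $0.8 \pm 0.1$ (disordered) and $0.2 \pm 0.1$
(ordered), so at the default noise width every score stays on its block's
side of the 0.5 threshold and the profile's IDS equals the ground-truth
block fraction *exactly* — the property the IDS round-trip tests assert.

Defaults model a disorder-enriched kinase-like query at desk scale: a
400-residue ancestor with a disordered N-terminal region (15%), one
ordered core (65%) and a disordered tail (20%) — 35% disordered overall,
in the range where homolog screening is most useful; six family members;
5% substitutions and 1% indels per lineage, far enough for distinct
E-values, close enough that every descendant is found. The generator
emulates *architecture*, not evolution: substitutions are pool-uniform
rather than matrix-driven, there is no rate heterogeneity, and the
composition pools are deliberately chosen so the built-in heuristic
separates the block kinds cleanly (a documented calibration coupling).
Passing tests therefore demonstrate the pipeline's correctness on
sequences with designed, known disorder architecture — they do not
demonstrate predictor accuracy on natural proteins, where the
external-score path exists.

Problem sizes used by the test and acceptance suites — families of 4–6
members of 120–400 residues, 200 random oracle instances with both
lengths ≤ 12 — were chosen as the smallest sizes at which every property
under test is non-trivially exercised.

## Numerical and degenerate-case choices

* Strict inequalities throughout: `ids()` counts $s > \theta$;
  superior homologs satisfy $\mathrm{FLEX} > \mathrm{FLEX}_{query}$.
* FLEX is reported at 4 decimals, IDS at 3, E-values as 2-decimal
  scientific mantissas; full precision is kept internally.
* `evalue_transform()` needs no clamping anywhere: for $E \ge 1$ the
  squared exponent is still nonnegative, so $t \in [0,1]$ naturally
  ($t$ rises again past $E = 1$, which is immaterial since hits are
  thresholded far below 1).
* A scan of a library containing the query itself reports the query row
  once, under the self-hit convention; with no passing hits the report
  degrades to the query row plus a warning, not an error.
* Reruns with identical configuration are byte-identical: the run log
  carries no timestamps and all sorting has deterministic tie-breaks.
* A single-row comparison matrix reports segments with an undefined
  (`NA`) cross-row fraction rather than failing.

## Known limitations

The built-in disorder heuristic is compositional only — it sees no
pairwise interaction energies and will misjudge sequences whose order
arises from context rather than composition (use external scores there).
The E-value constants are fixed for BLOSUM62/11/1; other matrices are not
built in. The progressive MSA has no iterative refinement and its segment
boundaries are convention-bound. Proteome-scale screens (tens of
thousands of queries against full databases) are out of scope at desk
scale; the summarization operations (`screen_summary()`,
`bin_improvements()`) that such screens would aggregate are implemented
and tested on fixtures.
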