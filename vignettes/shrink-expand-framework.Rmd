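---
title: "The Shrink/Expand framework for two-phase cell-cell communication comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Shrink/Expand framework for two-phase CCC comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SEcomm)
```

## What the framework measures

Cell–cell communication (CCC) inference from single-cell RNA-seq
reports, for each ordered pair of annotated cell types, the
ligand–receptor (LR) pairs whose co-expression is statistically
supported. SEcomm compares such inventories between two biological
states. The comparison is deliberately *two-phase*: consecutive states
are compared pairwise (1m vs 3m, 3m vs 18m, ...), never a single
early-vs-late contrast, because interactions can vanish and later
return — a pattern a two-endpoint design cannot see.

The unit of analysis is the *CCC inference unit*: one (communication
type, LR pair) combination, where a communication type $t(A \to B)$ is
a directed source/target cell-type pair ($A = B$, autocrine signalling,
is allowed). Communication types are kept directed because the
upstream inference distinguishes ligand expression in $A$ from receptor
expression in $B$; users who want symmetric types can merge
$(A,B)$ with $(B,A)$ upstream of the comparison.

### Input filtering

Only interactions with both method p-values (CellPhoneDB-style and
CellChat-style) *strictly* below the threshold (default 0.05) are
retained, applied independently per state table — each state's
inference run is independent, so there is no cross-state quantity the
filter could share. Strict inequality means boundary values are
dropped. Presence is thus "statistically supported in this state";
absence is *not* statistically verified, which is why losses are only
ever "potential".

### The SE score and its sign

For state sets $L(1)$ (reference) and $L(2)$ (comparator) with
intersection $I$, the intersection ratios are $r(1) = |I|/|L(1)|$ and
$r(2) = |I|/|L(2)|$, and the Shrink/Expand score is

$$SE = |I|\left(\frac{1}{|L(1)|} - \frac{1}{|L(2)|}\right) = r(1) - r(2),
  \qquad SE \in [-1, 1].$$

The sign was a genuine design decision. Written as a difference of
ratios the score can be oriented either way; the orientation above is
the one under which the *semantics* every downstream step relies on
hold: a comparator that strictly gains pairs has $r(1) = 1 > r(2)$, so
expansion is positive, shrinkage negative, and the organ-level
aggregation below counts positives as expanding. The package also
ships the opposite orientation (`seSignConvention = "literal"`, i.e.
$r(2) - r(1)$) so that analyses written against either algebra can be
audited; the two conventions differ only by sign, and all bounds and
antisymmetry properties hold under both.

Two further conventions cover cases the formula leaves undefined:

* **Emergent / vanished types.** A communication type present in only
  one state has no ratio on the empty side. It is reported with
  direction `emergent` ($SE = +1$) or `vanished` ($SE = -1$) under the
  semantic convention — the limit of the formula as the empty side
  grows from nothing — and flagged by its direction label so it can be
  excluded. Organ aggregation includes these types by default
  (`includeEmergent = TRUE`); whether to count wholesale appearance or
  disappearance of a cell-type pair as expansion/shrinkage is a
  judgement call, so it is a switch, not a rule.
* **Complete turnover.** Disjoint equal-sized sets give $SE = 0$,
  direction `stable`, with $GR = PLR = 1$. The score says the turnover
  *balances*, not that nothing changed; the ratios carry the turnover
  information.

Both sets empty is an error rather than a silent zero.

### Classification and ratios

Each unit is Consensus ($C = I$), Gain ($G = L(2) \setminus L(1)$) or
Potential Loss ($PL = L(1) \setminus L(2)$); $C$, $G$, $PL$ partition
$L(1) \cup L(2)$, with $|C| + |G| = |L(2)|$ and $|C| + |PL| = |L(1)|$.
The gain ratio $GR = |G|/|L(2)|$ and potential-loss ratio
$PLR = |PL|/|L(1)|$ normalise turnover by the size of the state it is
measured against: $GR = 1$ means the comparator's content is entirely
new, $PLR = 0$ means the reference was fully preserved. A ratio whose
denominator state is empty is reported as `NA`, never 0 or 1.

Set membership is exact string equality on (ligand, receptor);
multi-subunit complexes (e.g. `ITGA1_ITGB1`) are atomic at this level
and only decomposed in the single-molecule analysis.

### Organ aggregation

Types are classified by SE sign; only those with a net directional
change enter the total:
$$SE_{organ} = \frac{N_{expand} - N_{shrink}}{N_{expand} + N_{shrink}}.$$
Stable types are counted and reported but excluded from the
denominator, so one changing type among fifty stable ones still
registers at full strength — the statistic measures the *balance* of
change, not its prevalence. When no type changes the score is
undefined and reported as `NA` with a warning, never coerced to 0.

## Statistical testing

### Consensus shifts

Whether the magnitudes (`lr_mean`, the mean expression of ligand and
receptor across the interacting cell types) of a type's consensus
pairs shift between states is tested with the two-sided Wilcoxon
signed-rank test on paired differences, one test per communication
type pooling its consensus pairs. Choices worth stating:

* Zero differences are dropped before ranking (classic signed-rank
  handling rather than Pratt's method); with no nonzero difference the
  type is flagged untestable rather than given a p-value.
* The exact null distribution is used for up to 25 nonzero
  differences; with ties among absolute differences, or larger $n$,
  the normal approximation with continuity correction is used (this is
  `stats::wilcox.test`'s behaviour, relied on rather than reimplemented;
  the test suite checks it against a full $2^n$ sign enumeration).
* Multiple testing across communication types is *not* corrected by
  default: the framework uses a conventional fixed threshold with
  contextual interpretation, and per-type significance calls feed a
  binary pattern matrix rather than a discovery count. A
  Benjamini–Hochberg option (`adjust = "BH"`) is available.

### The permutation null for non-stochastic change

If ageing (or any state transition) shuffled categorical labels at
random, the three categories would spread across each LR pair's
occurrences, and many top pairs would carry multiple labels. The test
statistic is therefore the number of distinct top-$k$ pairs (default
$k = 20$, most frequent across all categories) carrying two or more
distinct category labels. "Overlapping labels" admits more than one
reading; this count-of-multi-label-pairs reading is the one that
contrasts "most pairs change in only one category" with random
assignment, and a total-extra-labels variant is available
(`statistic = "occurrences"`). Each of the 200 (default) permutations
draws $k$ distinct pairs uniformly without replacement from the
stage's pair universe and assigns every occurrence of a drawn pair a
uniform random category; the p-value uses the add-one estimator
$(1 + \#\{null \le obs\})/(n+1)$ on the lower tail (ordered change
means the observed count is *low*), so it is never exactly zero and
its resolution is bounded by $1/(n+1) \approx 0.005$ at the default
200 replicates. A single seeded generator drives each run, with
per-stage seeds fanned out by stable hashing of stage names
(`deriveSeed`), so results are bit-reproducible and adding a pipeline
stage never perturbs another stage's stream.

## Shortlisting

Gain and potential-loss units are prioritised by magnitude: the
`lr_mean` values of a category within one communication type are split
into two clusters and the higher-mean cluster is selected. The split
is the exact optimum of two-group 1-D clustering — the partition
minimising within-group sum of squares, found by scanning the $n - 1$
split points of the sorted values (the 1-D case of $k$-means, solved
exactly; no iterative refinement, no initialisation sensitivity). With
a single value or all values tied the split is degenerate: everything
is selected and flagged. Only a two-cluster split is supported —
`nClusters` exists as a config field for explicitness but rejects any
other value, because "the higher-mean cluster" is only well defined
for two.

Consensus units persist in both states, so magnitude alone says
nothing about change; they are scored by rank dynamics instead. Within
each communication type the consensus pairs are ranked by `lr_mean`
separately per state (rank 1 = largest; ties get average ranks, a rule
the method needs but that matters only for tied magnitudes), and the
score is the absolute rank change, clustered and selected the same
way. Shortlisting is per communication type by default with a pooled
option (`perCommType = FALSE`); per-type is the default because
magnitudes are comparable within a cell-type pair but confounded by
cell-type abundance across pairs.

Frequency ranking counts, per stage interval and per category, the
number of *distinct* communication types in which a pair shows that
categorical change; top-$k$ selection (default 20, per category) sorts
by frequency descending with a full lexicographic tie-break (category,
ligand, receptor, C locale) so output is deterministic and
order-invariant. Single-molecule decomposition splits each top pair
into its ligand and receptor, optionally splitting complex names on
the `_` subunit separator (the LIANA convention; configurable), and
accumulates occurrence counts with a ligand/receptor role breakdown.

## The synthetic-data generator

`generateTwoState()` and `generateLifespanSeries()` emulate exactly the
contract the analysis consumes: per-state tables in which each
communication type has planted consensus/gain/potential-loss sets,
log-normal `lr_mean` magnitudes (positive and right-skewed like
expression means; default meanlog 0, sdlog 1), and p-values in two
regimes — significant rows draw both p-values in $(0, 0.05/2]$, decoy
rows draw the failing value(s) in $[0.05, 1]$. The gap around the
threshold is deliberate: boundary behaviour of the strict filter is
pinned by dedicated tests, not left to sampling luck. Defaults emulate
a desk-scale organ: 12 directed communication types over a small
cell-type vocabulary, 4–12 consensus and 0–6 gain/loss pairs per type,
3 decoys per type and state, pairs drawn from a shared 150-pair pool so
the same pair can recur across types as in real LR resources. The
series generator chains transitions so state $s{+}1$'s reference set is
exactly state $s$'s comparator set, with per-transition gain/loss
intensities.

What it does *not* emulate: counts, cells, dropout, cell-type
abundance, upstream inference behaviour, or any correlation between a
pair's magnitude and its significance. Passing the round-trip tests
therefore shows the comparison layer is correct given its input
contract; it says nothing about upstream inference quality, and real
LIANA output will contain boundary p-values, shared-subunit complexes
and magnitude-significance correlation that the generator intentionally
leaves out.

## Numerical and scale choices

Test and verification problem sizes were chosen so the full suite runs
in about a minute: exhaustive SE enumeration over all $31 \times 31$
ordered pairs of non-empty subsets of a 5-pair universe; 1000 random
set pairs against a naive set-arithmetic oracle; 100 generator seeds
for exact round-trip recovery (4 communication types each); 500 random
vectors of length $\le 12$ against exhaustive-bipartition split search;
full $2^n$ sign enumeration of the signed-rank null up to $n = 8$; 50
seeded replicates for permutation calibration at 200 permutations.
Output tables are sorted with C-locale (radix) ordering throughout, so
files are byte-identical across platforms and runs; duplicate input
keys are collapsed deterministically (minimum first-method p-value,
then second, then first occurrence) and logged.

## Limitations

The SE score inherits the upstream inference's blind spots: rare or
lowly expressed interactions are under-represented, presence is a
statistical call rather than protein-level evidence, and gained and
lost interactions are weighted equally regardless of functional
relevance (no expression-magnitude weighting of SE is attempted).
Potential losses are conservative by construction — absence of
significance is not significance of absence. The organ score discards
effect sizes (a type at $SE = 0.05$ counts as much as one at 0.9) by
design; consult the per-type table when magnitudes matter.
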