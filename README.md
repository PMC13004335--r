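# SEcomm

Quantifying directional change in inferred cell–cell communication (CCC)
between two biological states.

Single-cell CCC inference tools (CellPhoneDB, CellChat, and LIANA's
consensus over them) report, per pair of annotated cell types, the
ligand–receptor (LR) interactions whose co-expression is statistically
supported in one dataset. Comparing two states — consecutive ages,
disease vs. healthy, treated vs. untreated — then becomes a question
about *sets*: which interactions persist, which appear, which drop out,
and whether the communication repertoire of each cell-type pair is
expanding or shrinking overall. SEcomm implements that two-phase
comparative layer. It consumes per-state LR inference tables (LIANA
consensus CSV schema by default, fully remappable), not raw expression
data, and is aimed at analysts doing secondary analysis of CCC output
across conditions or a lifespan series.

## The model

For a communication type *t(A→B)* (source cell type A signalling to
target B; A may equal B), let *L(1)* and *L(2)* be the sets of LR pairs
passing the double p-value filter (both method p-values strictly below
0.05) in the reference and comparator state, and *I = L(1) ∩ L(2)*.
With intersection ratios *r(1) = |I|/|L(1)|* and *r(2) = |I|/|L(2)|*,
the Shrink/Expand score is

    SE = |I| · (1/|L(1)| − 1/|L(2)|)  =  r(1) − r(2),   SE ∈ [−1, 1]

so SE > 0 means net expansion of the comparator repertoire, SE < 0 net
shrinkage, and SE = 0 a balance of gains and losses (not necessarily an
unchanged network: complete turnover also balances). A `"literal"`
convention returning *r(2) − r(1)* is available for audit. Every CCC
inference unit (one (communication type, LR pair) combination) is
classified as **Consensus** (*C = I*), **Gain** (*G = L(2) \\ L(1)*) or
**Potential Loss** (*PL = L(1) \\ L(2)*), with gain ratio
*GR = |G|/|L(2)|* and potential-loss ratio *PLR = |PL|/|L(1)|*. At the
organ level, types with non-zero SE are counted as expanding or
shrinking and aggregated as
*SE_organ = (N_expand − N_shrink)/(N_expand + N_shrink)*.

Downstream, consensus magnitude shifts are tested per communication
type with the two-sided Wilcoxon signed-rank test on `lr_mean`
differences; gain/potential-loss units are shortlisted by exact
two-cluster partitioning of `lr_mean` (consensus units by absolute rank
change); LR pairs are ranked by how many communication types show the
same categorical change; and a seeded permutation null tests whether
top pairs carry fewer multi-category labels than random assignment
would produce (non-stochastic change).

## Worked example

```r
library(SEcomm)

syn <- generateTwoState(nCommTypes = 4, seed = 101)   # planted ground truth
res <- compareTables(syn$ref, syn$cmp)                # filter, build, compare
res
#> CCCComparison: '1m' (reference) vs '3m' (comparator), semantic convention
#>   4 communication types: 0 expanding, 4 shrinking, 0 stable
#>   CCC inference units: 33 consensus, 8 gain, 19 potential loss

seTable(res)[, c("source", "target", "n_ref", "n_cmp", "se", "direction")]
#>   source target n_ref n_cmp      se direction
#> 1   CT01   CT01     9     8 -0.0833 shrinking
#> 2   CT02   CT03    16    15 -0.0500 shrinking
#> 3   CT03   CT02    12     7 -0.3571 shrinking
#> 4   CT03   CT03    15    11 -0.2182 shrinking

aggregateOrgan(res)$se_organ
#> [1] -1
```

Every communication type lost more LR pairs than it gained between the
two planted states (all SE < 0), so the organ-level score is at its
shrinkage bound: all four changing types shrink, none expand. The
per-type SE magnitudes say how unbalanced the turnover was — CT03→CT02
kept only 6 of 12 reference pairs while adding one. Consensus-shift
testing on the same comparison (`consensusShiftAll(res)`) finds no
significant `lr_mean` shift in any type (all p > 0.4 here), as expected
when magnitudes are drawn independently per state.

A shell front-end wrapping the same functions (subcommands `compare`,
`series`, `shortlist`, `permtest`, `simulate`; exit codes 0/1/2) is
installed at `system.file("scripts", "secomm", package = "SEcomm")`.

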