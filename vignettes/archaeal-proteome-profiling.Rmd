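---
title: "Comparative proteome profiling of archaea: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative proteome profiling of archaea: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(archaeproteo)
```

# The problem

Archaea occupy extreme and metabolically specialised niches — methanogenesis,
sulphur respiration, hypersaline basins, thermal vents — and these
adaptations leave signatures in the composition of their proteomes.
`archaeproteo` implements a comparative-proteomics workflow for detecting
such signatures from predicted proteomes and their orthology annotations:

* relative amino-acid usage per organism, including a reduction to residues
  whose codons carry no G+C bias, so niche signals are not drowned by
  genomic mutational bias;
* per-protein physico-chemical indices (isoelectric point, GRAVY,
  aromaticity, aliphatic and instability indices) and binned proteome-wide
  pI distributions;
* multivariate structure: complete-linkage clustering of usage profiles and
  correspondence analysis (CA) with axis–covariate correlations;
* directional amino-acid substitution bias between ortholog sets (which
  residues one lineage systematically gains at the expense of another);
* COG repertoire set algebra: functional-category profiles, group cores,
  group-exclusive cores, and four-way Venn partitions.

A deterministic synthetic-data module generates all inputs the pipeline
consumes, so every stage is exercisable and testable without genome
downloads.

# Input conventions

Proteomes are protein FASTA files. Records shorter than 100 residues are
excluded by default (`read_proteome_fasta(min_length = )`), reflecting the
common practice of dropping short annotated ORFs to reduce sampling error;
a trailing `*` stop character is stripped before the length check, so the
threshold counts residues, not codons, and is configurable to cover either
reading. Ambiguity codes (B, Z, X, U) are accepted in sequences but excluded
from every composition denominator — usage frequencies, GRAVY, aromaticity
and replacement counting — because inventing frequencies for them would
distort compositional statistics.

Organism metadata (taxonomy, genomic GC%, temperature/oxygen/salinity
adaptation, metabolic group) travel in a TSV with controlled vocabularies;
group membership for every grouped analysis is driven entirely by this
table, never inferred from organism names.

# Amino-acid usage

Usage is computed over the concatenated proteome (residue-weighted), not as
a mean of per-protein frequencies; for organism-level composition the two
differ only when protein lengths correlate with composition, and the
residue-weighted total is the convention of codon-usage tooling.

The GC-unbiased reduction keeps Val, Ser, Thr, His, Gln, Asp, Glu and Cys
and sums the remaining twelve residues into a single `other` column so row
sums are preserved and the reduction introduces no clustering artefact. The
eight-residue list is a fixed domain constant: a naive codon-GC rule would
also admit Leu, which is deliberately not included.

Heat-map standardisation is the column z-score (`standardize_columns()`);
range scaling would be an alternative reading of "colour gradient per
column", and the transformation is therefore isolated in one function.
Extremes tables (`summarize_extremes()`) report per-group mean frequencies
as percentages rounded to two decimals, with ties broken toward the
lexicographically first group name.

# Physico-chemical indices

The isoelectric point is the root of a Henderson–Hasselbalch net-charge
model: positive groups (N-terminus, His, Lys, Arg) contribute
$n_g/(1+10^{pH-pK_g})$, negative groups (C-terminus, Asp, Glu, Cys, Tyr)
contribute $-n_g/(1+10^{pK_g-pH})$. The charge is strictly decreasing in pH,
so bisection over $[0, 14]$ always brackets the root. Iteration continues
until the interval is below `tol` (default 0.01 pH units) *and* the residual
charge is below `charge_tol` (default $10^{-4}$); the second criterion
matters because for large proteins the charge slope near the root can exceed
tens of units per pH unit, so an interval criterion alone would not pin the
charge down. The pKa values are the EMBOSS set, shipped as a swappable table
(`default_pka_set()`): published pI methods differ mainly in this
calibration, and no single set is canonical, which is why all pI claims in
the test suite are property-based (root quality, monotonicity under
acidic/basic appends, oracle agreement) rather than fixed reference values.

pI distributions are binned into half-open $[lo, lo+0.5)$ bins over
$[2, 14]$, values outside clamped into the end bins, percentages summing
to 100; group profiles are per-bin mean ± sample SD across organisms. The
0.5 width matches the resolution at which archaeal pI profiles are usually
displayed, and is configurable.

GRAVY uses the Kyte–Doolittle scale; the aliphatic index uses Ikai's
coefficients $100(X_{Ala} + 2.9X_{Val} + 3.9(X_{Ile}+X_{Leu}))$; the
instability index is $(10/L)\sum w(d_k)$ over consecutive dipeptides with
the published 400-entry weight table (Guruprasad convention, $L$ = sequence
length, dipeptides containing a non-standard residue contribute zero). All
three tables ship as plain-text data files under `inst/extdata/` rather
than hard-coded literals.

# Multivariate structure

Complete-linkage clustering runs on Euclidean distances between usage rows
via `stats::hclust`; merge heights are monotone and the cophenetic distance
dominates the input distance (both are asserted in tests against a naive
$O(n^3)$ re-scan oracle). Tie-breaking among exactly equal merge candidates
follows `hclust`'s convention; on continuous usage data exact ties have
measure zero, and no attempt is made to reproduce any particular published
leaf ordering. Dendrograms export to Newick with branch lengths derived
from merge heights (`dendrogram_newick()`).

Correspondence analysis is implemented from first principles: with
$P = X/\mathrm{grand\ total}$, row masses $r$ and column masses $c$, the
standardised residual matrix $S = D_r^{-1/2}(P - rc^\top)D_c^{-1/2}$ is
decomposed by SVD; principal coordinates are the mass-rescaled singular
vectors and axis $k$ explains $\sigma_k^2/\sum\sigma^2$ of the total
inertia. Singular values below $10^{-10}$ are treated as numerical noise
(entries of $S$ are $O(1)$-scaled), so an independence-structured table is
reported as rank-degenerate rather than returning noise axes. Rows entering
CA are raw per-organism frequency profiles; row-standardised input is a
configuration away (standardise first, then pass the matrix). Axis signs
are arbitrary, as in any SVD; all correlations against covariates
(`axis_variable_correlation()`, Pearson r with a two-sided t-test p-value)
should be interpreted through $|r|$.

# Directional substitution bias

Ortholog pairs are accepted when similarity ≥ 40%, length difference
< 20% of the longer sequence (the denominator is a choice; the criterion's
source does not specify one), and e-value ≤ $10^{-10}$. When a hit table is
supplied, its similarity column is taken at face value rather than
recomputed.

Alignments are global Needleman–Wunsch with affine gaps (Gotoh recursion;
default BLOSUM62, gap open 10, extend 0.5, a gap of length $L$ costing
$10 + 0.5L$), with a deterministic traceback preferring substitution, then
a gap in the subject, then a gap in the query. Pre-aligned pairs can be
supplied directly to `count_replacements()`, bypassing alignment entirely.

Replacement counting scans alignment columns with fixed source/target
roles: differing standard residues increment the directed count
$N[source, target]$, identities increment the diagonal, and columns with a
gap or ambiguity code are skipped. For each of the 190 unordered residue
pairs, the *forward* direction is the more common of the two directed
counts, so ratio ≥ 1 and gain ≥ 0 by construction; a zero reverse count
flags the ratio as undefined and such pairs are ranked last in ratio
tables. Printed ratios use half-up rounding to two decimals.

Significance uses a 2×2 contingency chi-square with one degree of freedom.
The first row is fully determined by the convention's description: the
i→j count against the remaining replacements from i. The second row is an
interpretation; the default (`"mirror"`) uses the j→i count against the
remaining replacements from j, and `"expected"` instead tests the two
directed counts against their 1:1 expectation,
$\chi^2 = (f-r)^2/(f+r)$. Identity columns never enter the remainders —
remainders are replacements, not alignment columns. One subtlety worth
knowing: the mirror statistic conditions on source-row replacement totals,
so it is not invariant under swapping the two organisms (transposing $N$)
even though forward, reverse, ratio and gain all are; the `"expected"`
statistic is fully orientation-free. Tiers count the thresholds passed
among $p < 10^{-3}, 10^{-4}, 10^{-5}, 10^{-6}$; symbol legends vary across
publications, so tiers are reported numerically.

# COG repertoire

Category profiles are percentages of COG-annotated proteins whose category
string contains each of the 25 letters; multi-letter strings count fully
toward each letter, so profiles may sum to more than 100 (the fractional
alternative and a whole-proteome denominator are both one argument away).
The denominator defaults to annotated proteins because unannotated proteins
are excluded at parse time. Core COGs are plain set intersections;
exclusive cores subtract the union of all outside organisms, and can
legitimately be empty — a group may have no exclusive repertoire even when
the reverse contrast does. Four-way Venn partitions count all 15 membership
regions with per-set totals, and are permutation-equivariant under
relabelling.

# The synthetic-data generator

The generator exists to make every claim in the package testable at desk
scale. It emulates three features of real comparative datasets and
deliberately nothing else:

**GC-driven proteomes.** Codons are drawn with weight
$g^{GC}(1-g)^{AT}$ over the 61 sense codons and translated through the
standard genetic code — the simplest model that couples amino-acid usage to
genomic GC. Realised codon GC lands within ±0.02 of the target once
$\ge 10^4$ codons are drawn. Optional per-residue weight multipliers
emulate niche-adaptive shifts (acidic Asp/Glu enrichment for the
methanogen analogue, basic Lys/Arg for the sulphur analogue in
`simulate_study()`). The model has no codon context, no gene-level
heterogeneity and no selection; passing tests on it demonstrates that the
*pipeline* recovers planted signal, not that real archaea behave this way.

**Bias-injected ortholog pairs.** Columns are independent; each substitutes
with probability `divergence`. Substituted columns follow a two-arm design:
a `focus` fraction (default 0.2) are focal-pair events on the chosen pair
(i, j), taking direction i→j with probability $m/(m+1)$ so that the
expected directed ratio is exactly the injected multiplier $m$; the rest
draw uniformly from the remaining 378 ordered pairs. The design is that of
a planned experiment: it concentrates enough events on the focal pair for
the ratio to be estimable with useful precision at $10^4$ substituted
columns (a uniform process would leave ~26 expected counts per directed
pair, and no estimator could then sit within 20% of $m$ in 95% of
replicates). With $m = 1$ nothing is injected and the focal arm disappears
— all 380 ordered pairs are uniform — which is also what the mirror
chi-square's null requires, since that statistic reacts to unequal
source-row totals and the focal arm inflates exactly those. Divergence is
substitution-only, so true directed counts are exact column bookkeeping and
equal what `count_replacements()` recovers; an aligned-pair file can still
be stress-tested through `global_align()` separately. The package's
parameter-recovery checks run 100 replicates of 40,000 columns at
divergence 0.25 (10,000 substituted columns in expectation), a size chosen
to keep the whole suite fast while leaving the estimator comfortably
powered.

**Planted COG universes.** Each group's core is carved as a disjoint block
of the shuffled universe, with the exclusive set as a subset of the core —
exclusive COGs *are* core COGs that no outsider carries. Noise IDs sprinkle
independently per organism. Two structural guarantees make recovery exact
for any seed rather than with high probability: every non-exclusive core ID
is seeded into at least one organism outside its group (ungrouped organisms
are preferred hosts, so grouped repertoires stay clean — at zero noise a
group member's set is exactly its planted core), and any noise ID that
lands in all members of a group by chance is removed from one member. The
default specification (`default_cog_spec()`) mirrors the archaeal study
design at full organism count: 69 organisms, a 25-member group with a
488-ID core containing 22 exclusives, a 26-member contrast group with a
196-ID core and no exclusives, and 18 ungrouped organisms over a 3,000-ID
universe.

All generators take a single integer seed and are byte-identical under it.

# What the tests do and do not establish

Numerical engines (complete linkage, CA, Needleman–Wunsch, the pI root
finder) are checked against independent oracles: a naive $O(n^3)$
re-scanning agglomerator, an eigen-decomposition of the residual
cross-product, exhaustive alignment enumeration at tiny lengths, a
$10^6$-step grid search, and cross-checks against `vegan::cca`,
`Biostrings::pairwiseAlignment` and `chisq.test`. Statistical behaviour
(ratio recovery, type-I control, planted-set recovery, the GC–axis-1
correlation, acidic/basic pI separation) is established on the synthetic
generator under its stated conditions. None of this validates biological
conclusions about real archaea: full-scale results on real genomes require
the genomes and a COG annotation pipeline, both outside this package's
scope.

# Known limitations

* The pI model ignores charge–charge interactions, phosphorylation and
  terminal modifications; pKa sets are calibrations, not measurements.
* The CA implementation returns principal coordinates only; standard
  biplot scalings other than symmetric-by-singular-value are left to the
  caller.
* `global_align()` is a plain R implementation intended for hundreds of
  residues per sequence; genome-scale all-vs-all alignment should use a
  dedicated search tool upstream, with results supplied as hit tables and
  pre-aligned pairs.
* The synthetic codon model draws codons i.i.d.; it cannot emulate
  gene-level compositional heterogeneity, codon context effects or indel
  evolution (ortholog simulation is substitution-only by design, so that
  truth bookkeeping stays exact).
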