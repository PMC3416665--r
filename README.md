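# archaeproteo

Comparative proteome profiling for archaea (and other prokaryotes): an R
package for asking which compositional and repertoire features of a set of
predicted proteomes track lineage, genomic GC bias, or niche adaptation
(methanogenesis vs sulphur metabolism, aerobes vs anaerobes, thermal or
saline habitats). It is aimed at comparative genomicists who have per-
organism protein FASTA files, COG annotations and an organism metadata
table, and want tested, scriptable implementations of the standard analyses
rather than a chain of GUI tools.

## What it computes

* **Amino-acid usage** — relative frequencies per organism over the
  concatenated proteome; column z-scores for heat maps; a GC-unbiased
  reduction keeping the eight residues whose codons carry no G+C bias
  (Val, Ser, Thr, His, Gln, Asp, Glu, Cys) with the rest summed into
  `other`; per-group extreme-value tables.
* **Physico-chemical indices** — per protein: isoelectric point (bisection
  on a Henderson–Hasselbalch charge model,
  $Q(pH)=\sum_{+} \frac{n_g}{1+10^{pH-pK_g}} - \sum_{-} \frac{n_g}{1+10^{pK_g-pH}}$),
  GRAVY (mean Kyte–Doolittle hydropathy), aromaticity, aliphatic index and
  instability index; binned pI distributions per organism and mean ± SD
  group profiles.
* **Multivariate structure** — complete-linkage clustering on Euclidean
  distances (Newick export) and correspondence analysis from first
  principles (SVD of $D_r^{-1/2}(P-rc^\top)D_c^{-1/2}$, per-axis inertia
  percentages) with Pearson axis–covariate correlations.
* **Directional substitution bias** — ortholog filtering (similarity ≥ 40%,
  length difference < 20%, e-value ≤ 1e-10), global Needleman–Wunsch
  alignment (affine gaps, BLOSUM62), a 20×20 directed replacement matrix,
  and for each of the 190 residue pairs the forward/reverse counts, ratio,
  gain and a 1-df chi-square for directional bias, with top-k rankings by
  gain and by ratio.
* **COG repertoires** — functional-category profiles, group core COGs
  (set intersection), group-exclusive cores (core minus everything outside
  the group) and four-way Venn partitions.
* **Synthetic data** — deterministic generators for GC-driven proteomes,
  ortholog pairs with an injected directional replacement preference, and
  COG universes with planted core/exclusive structure, plus
  `simulate_study()` which writes a complete end-to-end input bundle.

See the vignette (`vignettes/archaeal-proteome-profiling.Rmd`) for the
models, conventions and design decisions.

## Worked example

Everything below runs from a synthetic bundle, so it works on a fresh
machine with no downloads:

```r
library(archaeproteo)

bundle <- simulate_study(file.path(tempdir(), "demo"), seed = 42)
md     <- read_metadata_table(bundle$metadata)
prots  <- lapply(bundle$fastas, read_proteome_fasta)

## usage matrix and correspondence analysis
usage <- build_usage_matrix(lapply(prots, compute_relative_usage))
ca    <- correspondence_analysis(usage)
ca
#> Correspondence analysis: 8 rows, 20 columns, 7 axes
#> Inertia explained (%): 79.25, 18.02, 1.41, 0.90, 0.17 ...
axis_variable_correlation(ca$row_scores, 1, md$gc_percent, name = "gc_percent")
#>   axis  covariate         r      p_value
#> 1    1 gc_percent 0.9981521 1.575319e-08
```

Axis 1 of the usage CA is almost perfectly aligned with genomic GC — in
this bundle GC bias is, by construction, the dominant force on amino-acid
usage, and the analysis recovers that.

```r
## directional replacement bias across the bundled ortholog alignments
alns <- read.delim(bundle$alignments)
N    <- count_replacements(Map(function(q, s) list(query = q, subject = s),
                               alns$query, alns$subject))
bias <- pair_bias_statistics(N)
rank_bias_pairs(bias, k = 3, key = "gain")[, c("pair", "forward", "reverse",
                                               "ratio_2dp", "gain", "tier")]
#>   pair forward reverse ratio_2dp gain tier
#> 1 D->K      63      11      5.73   52    4
#> 2 V->F       5       0        NA    5    0
#> 3 K->M       4       0        NA    4    0
```

The bundle injects a 3× Asp→Lys replacement preference between the two
metabolic groups; `D->K` tops the gain ranking at the strongest
significance tier (p < 1e-6), while the runner-up pairs are unbiased noise
(`NA` ratios mean the reverse count is zero; such pairs are flagged and
ranked last in ratio tables). The observed ratio for a single short
alignment set scatters widely around the injected value — the package's
acceptance checks quantify recovery across 100 replicates at 10,000
substituted columns, where it is within 20% of the truth in every run.

```r
## binned pI distribution of one proteome
pis <- vapply(prots[[1]]$sequences, isoelectric_point, numeric(1))
head(subset(bin_pi_distribution(pis), percent > 0), 3)
#>   bin_lo bin_hi   percent
#> 6    4.5    5.0 15.000000
#> 7    5.0    5.5  1.666667
#> 8    5.5    6.0  1.666667
```

This organism belongs to the acidic-shifted (methanogen-analogue) group,
and its pI histogram leans accordingly toward the acidic bins.

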