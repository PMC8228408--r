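# rnaccretion

RNA molecules do not appear in evolution fully formed: they grow by
gradually accreting substructural parts — helical stems, loops, bulges,
joints and free ends. `rnaccretion` is an R toolkit for dissecting that
accretion history from secondary structures and rooted phylogenies, aimed
at molecular evolutionists studying ancient RNAs (tRNA, 5S rRNA, RNase P
RNA, rRNA).

The pipeline has four stages, each usable on its own:

1. **Structure coding** — parse secondary structures (dot-bracket, CT,
   bpseq), decompose each molecule into substructures, and code the length
   of every homologous substructure as an ordered (Wagner) multistate
   character with the alphanumeric states `0`–`9`, `A`–`Z` (`0` = absent),
   written to/from NEXUS matrices.
2. **Character-state tracing** — reconstruct ancestral states on rooted
   trees under generalized (Sankoff) parsimony with the ordered cost
   |i − j|, extract the changes that are *unambiguous* (identical in every
   most-parsimonious reconstruction), and aggregate them into 36 × 36
   step-matrices: the data behind bubble charts of state-change
   frequencies.
3. **Chronology** — read rooted trees of substructures and assign each
   substructure a relative age *nd* (node distance): the count of internal
   nodes from the root, rescaled to [0, 1] with 0 = origin of the molecule
   and 1 = the present molecule.
4. **Diminishing returns** — join mean substructure lengths with ages,
   test the negative length–age association (OLS slope, Pearson *r*,
   Spearman *ρ* with exact small-sample permutation p-values, KS
   normality), and fit the Menzerath–Altmann (MA) law.

The statistical core is the MA law, "the greater the whole, the smaller
its constituents", in its special form

> *y*(*x*) = *A e*<sup>−*cx*</sup>

where *x* is the number of substructures in the molecule, *y*(*x*) the mean
length of its parts, *A* the length of the first molecular construct and
*c* the decay rate per added part. Fitting is a straight line in log space,
ln *y* = ln *A* − *cx*, with F statistics; the general form
*y*(*x*) = *Ax*<sup>*b*</sup>*e*<sup>−*cx*</sup> and the equivalent
evolutionary decay parameterization *N*(*t*) = *N*₀*e*<sup>−λ*t*</sup>
(with *N*₀ = *A*, λ = *ck*) are also provided.

A synthetic-data module generates pectinate trees of substructures,
accretion series with known (A, c), stepwise-evolving ordered characters
and self-checking dot-bracket molecule sets, so every stage can be
validated end to end without external data.

## Worked example

Simulate 15 molecules sharing a 6-stem template, code them, age the
substructures on a pectinate tree and test diminishing returns:

```r
library(rnaccretion)

cfg  <- synthetic_config(n_sub = 6, n_taxa = 15, seed = 42)
mols <- gen_molecule_set(cfg)
cm   <- build_character_matrix(lapply(mols$structures, decompose))
cm
#> Ordered multistate character matrix: 15 taxa x 19 characters (6 helical, 13 unpaired)

tree   <- pectinate_tree(ncol(mols$lengths), labels = colnames(mols$lengths))
ages   <- node_distance_ages(tree)
series <- build_series(mean_lengths(cm), ages, class_filter = "helical")
correlate(series)
#> Length-vs-age correlation (n = 6, df = 4)
#>   OLS: slope = -5.95, intercept = 6.71, R2 = 0.755
#>   Pearson r = -0.869 * (p = 0.0247)
#>   Spearman rho = -0.829 (two-tailed p = 0.0583)
#>   KS normality: D = 0.306, p = 0.529, Lilliefors p = 0.0823

fit_ma_special(series)
#> Menzerath-Altmann special-form fit (n = 6)
#>   A = 8.022 (+-1.88)  c = 0.2544 (+-0.0602)
#>   R2 = 0.817  R = 0.9039  F(1,4) = 17.86  p = 0.0134
```

The negative slope and the fitted decay (*A* ≈ 8.0 nt for the first stem,
*c* ≈ 0.25 per added substructure) recover the diminishing-returns signal
built into the simulated template, in which older stems are longer.
Step-matrices for the tracing stage come from `build_step_matrix()` /
`export_bubble()`, and `run_pipeline()` (or
`inst/scripts/accretion-pipeline.R` from a shell) orchestrates all stages
from a JSON config.

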