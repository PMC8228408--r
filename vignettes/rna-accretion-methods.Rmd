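---
title: "Methods: tracing RNA accretion history and fitting the Menzerath-Altmann law"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracing RNA accretion history and fitting the Menzerath-Altmann law}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaccretion)
```

## The model in brief

RNA molecules grow in evolution by accreting substructures. `rnaccretion`
makes that history quantitative in three steps. First, each molecule's
secondary structure is decomposed into substructures whose lengths become
ordered multistate characters. Second, rooted phylogenies supply two kinds
of signal: trees of molecules, along which ancestral character states are
reconstructed and changes aggregated into step-matrices; and trees of
substructures, whose branching order dates each substructure on a relative
0-1 scale. Third, the dependence of mean substructure length on age - and,
equivalently, on the number of parts already in the molecule - is tested
with correlation statistics and fitted with the Menzerath-Altmann (MA)
law, whose special form

$$y(x) = A\,e^{-cx}$$

says each added part is smaller than the last by a constant factor. The
underlying assumptions are (i) substructure homology across molecules can
be assigned (here, positionally), (ii) the input trees are rooted
correctly - the package never re-roots, and (iii) character evolution is
well described by ordered (Wagner) states, i.e. lengths change through
intermediate values, so a change from state $i$ to $j$ costs $|i-j|$.

## Character coding

Lengths are coded with the 36-symbol alphanumeric alphabet `0`-`9`,
`A`-`Z` used in NEXUS matrices (`A` = 10 ... `Z` = 35), with `0` reserved
for *absence* of the substructure. Two consequences follow. Lengths above
35 cannot be represented and are clipped to `Z` with a warning; for the
RNA types this package targets, stem and loop lengths above 35 are rare
enough that clipping is a reporting convenience, not a modeling choice. A
present substructure can never have coded length 0, which is why the
synthetic generator floors lengths at 1.

Decomposition follows strict stacking: a stem is a maximal run of
consecutively stacked pairs, so a single-nucleotide bulge splits a helix
into two stem characters - stems and the interruptions between them are
separate characters by design. Unpaired runs are classified by flanking
context (hairpin loop, bulge vs two-sided internal loop, multiloop
segment, exterior joint, 5'/3' free end); a fully unpaired molecule is a
degenerate single 5' free end. Crossing (pseudoknot) pairs are kept and
form their own stems by the same maximal-stacking rule; only the
*classification of unpaired runs* uses the maximal non-crossing subset of
stems, because loop context is undefined on a crossing scaffold.

G:U wobble pairs count toward stem length (they stack inside helices),
and, when sequence is available, an optional `gu_pairs` character per stem
records the wobble count separately (`gu_separate`). Since wobble pairs
are helical by position but destabilizing by effect, their class is
configurable (`substructure_class(..., gu_class=)`); the default codes
them `unpaired`, keeping the helical class strictly canonical-stem length.
Both codings are one flag apart because neither is uniquely "correct".

## Ages from trees of substructures

A leaf's age is its node distance: the number of internal nodes on the
root-to-leaf path, counting the root, linearly rescaled so the shallowest
leaf (the molecule's origin) sits at 0 and the deepest (the present) at 1.
Branch lengths are deliberately ignored - the age is a count of branching
events, not a molecular-clock estimate - and sister leaves at the same
depth share an age. Whether the root is counted is immaterial after
rescaling; the raw `depth` column states the convention (root counted) for
debugging. Trees in which every leaf is equally deep carry no chronology;
they get `nd = 0` everywhere plus a warning rather than an error, so
screening loops over many trees keep running.

## Parsimony tracing and unambiguous changes

Ancestral states are reconstructed with the Sankoff dynamic program over
the full 36-state space under the ordered cost $|i-j|$; polytomies enter
the recursion directly (children's minima are summed) rather than being
binarized arbitrarily. A change $i \to j$ on a branch is counted in the
step-matrix only when it is *unambiguous*: every most-parsimonious
reconstruction (MPR) assigns $i$ to the parent and $j$ to the child. Two
criteria are implemented: explicit MPR enumeration (used when the MPR
count is within `mpr_limit`, default $10^5$) and the singleton-final-set
test (the fallback, flagged `approximate` in the result). On trees the two
coincide - a branch's endpoint states are fixed across all MPRs exactly
when both final sets are singletons, by the conditional independence of
subtree optima given the parent state - and the test suite verifies the
equivalence on randomized instances; the fallback flag is kept purely as
provenance. Multi-step changes (e.g. $3 \to 0$) are recorded as a single
off-diagonal cell, not decomposed into unit steps, so step-matrices retain
the multistep structure visible in bubble charts. Leaves with no recorded
state are treated as absence (state 0) by default, matching the coding
convention; `missing_as_zero = FALSE` turns this into an error.

Bubble exports report both raw counts and per-character average
frequencies (`normalization = "raw"` / `"mean"`), since either
normalization is defensible for comparing matrices of different sizes.
Iteration order (preorder, children in input order) is fixed, making all
outputs bit-reproducible.

## Correlation statistics

The length-age association is summarized by the OLS slope of mean length
on `nd` (so slopes are in nucleotides or base pairs per unit relative
time), Pearson's $r$ with a two-sided t test on $n-2$ df, and Spearman's
$\rho$. For $n \le 9$ the two-tailed $\rho$ p-value is computed by exact
permutation over all $n!$ orderings (ties handled by average ranks); for
larger $n$ the t approximation is used. Without ties, $\rho$ itself is
computed from the rank-difference formula, which returns exact $\pm 1$ for
perfectly monotone series - a floating-point nicety that matters because
"$\rho = -1$ exactly" is a meaningful qualitative outcome for monotone
accretion. Normality of the lengths is assessed by a Kolmogorov-Smirnov
test against a normal with plug-in sample mean and SD; because plug-in KS
p-values are conservative, the Lilliefors-corrected p-value is reported
alongside (for $n \ge 5$).

## Fitting the MA law

The special form is fitted as a straight line in log space,
$\ln y = \ln A - cx$, the procedure standard in the MA-law literature;
this weights multiplicative (lognormal) errors correctly, which is also
how the synthetic generator produces noise. $A$ and its standard error are
back-transformed by the delta method ($\mathrm{SE}_A = A \cdot
\mathrm{SE}_{\ln A}$). The regression F statistic is taken from the linear
fit, with df $(1, n-2)$ for the special form and $(2, n-3)$ for the
general form $\ln y = \ln A + b\ln x - cx$; degenerate flat series return
$c = 0$, $F = 0$, $p = 1$ rather than NaN. An optional nonlinear
least-squares refit (Levenberg-Marquardt, started at the log-space
estimates) is available; when the two routes disagree by more than 1% both
are reported and the log-space fit stays primary. For the general form the
regressors $\ln x$ and $x$ can be nearly collinear over short ranges of
$x$; the fit flags condition numbers above $10^8$. Mapping to the decay
parameterization $N(t) = N_0 e^{-\lambda t}$ is the identity $N_0 = A$,
$\lambda = ck$, justified by the approximately linear growth of the number
of substructures $x$ with relative time.

The accretion rank $x$ of a substructure is the cumulative count of
substructures with age $\le$ its own, ties sharing a rank. Only present
substructures contribute ranks; absences are excluded both from mean
lengths and from the $x$ axis.

## The synthetic generator

The generator emulates exactly the statistical structure the analysis
assumes: fully pectinate trees of substructures (so ages are a clean
ladder), mean lengths decaying as $A e^{-cx}$ with lognormal noise on the
log scale, ordered characters taking Poisson-distributed $\pm 1$ steps per
branch with reflection at the alphabet boundaries 0 and 35, and
dot-bracket molecule sets sharing a template topology whose decomposition
provably returns the generating lengths (each record is verified before it
is emitted). Defaults are tRNA-scale: 10 substructures, $A = 13.56$ (base
pairs), $c = 0.490$ per substructure, noise SD 0.2 on $\ln y$, 0.1
expected steps per branch; they describe a small, strongly decaying
molecule, the sharpest version of the diminishing-returns signal.

Two honest gaps between the generator and real data: on a pectinate tree
the two youngest substructures tie in both age and rank (a cherry has no
internal order), and the floor at length 1 truncates the exponential
wherever $A e^{-cx} < 1$ - at the tRNA-scale defaults that happens beyond
$x \approx 5$, so noisy tRNA-scale histories are *not* expected to refit
$(A, c)$ exactly; parameter-recovery checks therefore generate from the
law directly. The generator also does not emulate sequence substitution,
indels, thermodynamic refolding, homology ambiguity, or non-pectinate
substructure trees; passing tests demonstrate correctness of the
machinery under the model's assumptions, not that real RNA data satisfy
them.

## Problem sizes and numerical tolerances

The validation suite runs at desk scale by choice: parsimony is compared
against exhaustive enumeration on 200 random instances of at most 6
leaves and 6 states (where enumeration is exact and fast); noiseless MA
round trips are required to recover parameters to 10 significant digits;
noisy recovery uses 500 replicates of 10-point series, requiring mean
estimates within 10% and at least 90% coverage of 95% CIs; single-step
dominance uses 50 characters on a 100-leaf tree at 0.1 steps per branch,
requiring at least 80% of unambiguous changes on the $\pm 1$ diagonals.
`scripts/acceptance.R` recomputes all of these from scratch under a
caller-supplied seed.

## Known limitations

Homology must be positional or user-supplied; there is no alignment-based
homology inference. Trees are consumed as rooted; no rooting, inference or
consensus machinery is included. Step-matrices are descriptive output and
are not converted back into transformation-cost models for tree
re-searching. Statistical characters (e.g. base-pairing entropies) and
structure prediction are out of scope. The analysis of published RNA-type
chronologies requires the corresponding external data matrices and trees,
which cannot be redistributed here; `read_series()` accepts transcribed
chronology TSVs to bridge that gap.
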