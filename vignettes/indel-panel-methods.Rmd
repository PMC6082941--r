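---
title: "Statistical methods behind indelpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind indelpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indelpanel)
```

indelpanel analyses panels of diallelic insertion/deletion (InDel) markers
of the kind used for forensic identification — the worked reference design
throughout is a 30-locus autosomal panel (Investigator DIPplex layout)
typed in a single population sample of n = 169 individuals. This vignette
explains each statistical component, its assumptions, the tunable
parameters and their defaults, and the design decisions taken where more
than one defensible choice existed.

## Data model

A `genotype_matrix` stores unphased calls `II`, `ID`, `DD` (I = insertion
allele, D = deletion allele) with a population label per sample. Missing
calls are excluded locus-wise (complete-case per locus): each locus
therefore carries its own effective sample size `n`, matching how forensic
summaries report a single `n` per locus. All frequency containers store
only the insertion frequency `p`; the deletion frequency is `1 - p` by
construction.

## Per-locus forensic efficiency parameters

Writing `q = 1 - p` and genotype counts `(n_II, n_ID, n_DD)` with
`n = n_II + n_ID + n_DD`:

* **Allele frequency** `p = (2 n_II + n_ID) / 2n`.
* **Observed heterozygosity** `Ho = n_ID / n`.
* **Match probability** `MP = sum_g (count_g / n)^2` over the three
  *observed* genotype classes, and `DP = 1 - MP`. Using observed rather
  than Hardy-Weinberg-expected genotype frequencies is deliberate: on the
  reference panel the expected-frequency version gives 0.3768 at the first
  locus where the published table prints 0.3481, which the observed-count
  formula reproduces exactly.
* **Polymorphism information content**
  `PIC = 1 - (p^2 + q^2) - 2 p^2 q^2`.
* **Expected heterozygosity** is Nei's unbiased small-sample estimator
  `He = (2n / (2n - 1)) (1 - p^2 - q^2)`; the correction factor is what
  lets published 4-decimal values reproduce at n = 169.
* **Typing paternity index** `TPI = 1 / (2 (1 - Ho))`; `Ho = 1` is
  reported as a domain error rather than `Inf`.
* **Power of exclusion** uses the single-parent (Brenner) form
  `PE = Ho^2 (1 - 2 Ho (1 - Ho)^2)`, verified against published panel
  values.

Panel-wide, `CMP = prod(MP_l)` and `CPE = 1 - prod(1 - PE_l)` are computed
in log space (`sum(log)` / `log1p`) so 30-locus products near `1e-12`
lose no precision; `log10` forms are returned alongside. These
combinations assume locus independence, which is why the HWE and LD
screens below are part of the same workflow.

`reconstruct_counts()` inverts a published `(p, TPI, n)` triple to integer
genotype counts (heterozygotes from TPI, insertion copies from `p`,
homozygotes by closure), erroring on inconsistent inputs. Reporting
follows the forensic convention of 4 decimal places with round-half-even.
A subtlety worth knowing: statistics computed from the *rounded* published
frequency can land one unit of the fourth decimal away from the published
cell (published tables are computed from unrounded frequencies); computing
from reconstructed counts avoids this.

## Hardy-Weinberg testing

`hwe_exact()` is the Levene-Haldane exact conditional test: given the
observed allele counts, all heterozygote counts of matching parity are
enumerated, each configuration's conditional probability computed (via
log-gamma, normalised in a numerically stable way), and the p-value is the
total probability of configurations no more probable than the observed one
— the standard two-sided convention. Monomorphic loci return 1. Ties in
configuration probability are resolved with a `1 + 1e-12` relative guard
so equal-probability configurations count as ties across platforms.

`hwe_chi2()` is the 1-df goodness-of-fit companion. The two tests agree
closely where decisions are made (differences under 0.05 when either
p-value is below 0.1 at n = 169) but can differ substantially in the
mid-range, where the exact tail is a lumpy sum over a discrete support;
the exact test is the default everywhere and the chi-square value is
reported for cross-checking. Multiple testing uses Bonferroni
(`alpha / L`, i.e. 0.05/30 ≈ 0.00167 for the reference panel).

## Linkage disequilibrium

For each locus pair the 3×3 genotype-pair table (insertion dosage at each
locus) is reduced to haplotype frequencies by EM. Only the
double-heterozygote cell is phase-ambiguous; the E-step splits it between
coupling and repulsion phases in proportion to current haplotype
frequencies. Initialisation is the linkage-equilibrium product of the
observed allele frequencies — the diallelic problem has a single free
parameter and a unimodal likelihood in practice, so no restarts are used.
Convergence is declared when the largest frequency change falls below
`1e-10` (cap 1,000 iterations). From the fitted frequencies,
`D = f_II - p1 p2`, `D' = |D| / Dmax` with the sign-dependent feasible
maximum, and `r2 = D^2 / (p1 q1 p2 q2)`. Pairs with a monomorphic margin
have undefined `D'`/`r2` and are excluded from threshold counting rather
than propagating `NaN`. The screen over `L` loci emits all `L(L-1)/2`
pairs (435 for L = 30) against a default `r2` cutoff of 0.8, the
conventional "worrying LD" level for forensic panels.

## Interpopulation differentiation and distances

Locus-by-locus differentiation between two populations is tested by
Fisher's exact test on the 2×2 allele-count table (default), or by a
permutation test on the single-locus Weir-Cockerham theta (individuals
permuted between populations, `p = (1 + #{theta* >= theta}) / (n_perm +
1)`). Two tests are offered because published workflows in this field
describe the procedure only as "locus-by-locus AMOVA": for diallelic loci
the allelic exact test is the sharper and fully deterministic choice, and
the permutation route is retained for method comparison. Counts of
significant loci use the Bonferroni-corrected threshold `alpha / L`.

**Nei's D_A** between frequency vectors is
`1 - (1/L) sum_l sum_a sqrt(x_la y_la)`; it accepts frequency tables
directly so published reference-population frequencies can be compared
without genotype-level data. **F_st** is the Weir-Cockerham (1984) theta:
per-locus variance components are summed across loci and the ratio of
sums taken (not the mean of per-locus ratios), the standard stabilisation
for small per-locus variance; slightly negative estimates on
undifferentiated data are legitimate and preserved, though the assembled
distance matrix floors them at 0 (raw values kept as an attribute) so the
matrix remains a valid distance input for trees and ordination.

## Trees and ordination

`neighbor_joining()` is the Saitou-Nei algorithm with the Studier-Keppler
Q-criterion and the standard branch-length formulas; it is exact on
additive matrices. Ties in the Q minimisation are broken on the
lexicographically smallest sorted label pair, making results independent
of input order and platform. Negative branch lengths (possible on
non-additive input) are kept by default — matching mainstream NJ software
— with an option to clamp to zero while transferring length to the sister
branch so path lengths through the join are preserved.

`classical_mds()` is Torgerson metric scaling (double-centred squared
distances, eigendecomposition) delegated to `stats::cmdscale`; classical
scaling was chosen over stress-majorisation variants because it is
deterministic, dependency-light and exact on Euclidean input. Negative
eigenvalues (non-Euclidean input — typical for F_st matrices) are dropped
with a warning, as are requested dimensions beyond the positive spectrum.
`group_separation_score()` summarises an ordination with a
centroid-silhouette (singleton groups contribute distance 0 to their own
centroid), used to state "groups separate in the plot" as a testable
number.

## Admixture clustering

`structure_fit()` implements the admixture model for unphased diallelic
data with per-allele-copy latent cluster assignments, a Gibbs sampler with
conjugate `Beta(1 + n_I, 1 + n_D)` updates for cluster insertion
frequencies and `Dirichlet(alpha + counts)` updates for each individual's
ancestry vector. Defaults follow the reference workflow: burn-in 10,000
sweeps and 10,000 retained sweeps (the published protocol states the
burn-in; the retained length is this package's choice), K explored over
2–7.

The hyperparameter `alpha` is inferred by default (uniform prior on
(0, 10), Gaussian random-walk Metropolis with sd 0.05, the scheme
STRUCTURE itself uses). This was a genuinely open design point: a fixed
`alpha = 1` variant is simpler, but on two-population test data at
moderate divergence (theta = 0.2, 100 loci) it plateaus at mean
self-cluster membership around 0.88 because the flat Dirichlet keeps
ancestry vectors soft, while inferring `alpha` (posterior mass near 0.1
on such data) reproduces the crisp assignments practitioners expect from
STRUCTURE (≈ 0.97). Pass a numeric `alpha` to fix it. No within-chain
label-switching correction is applied — on separable data chains do not
switch in practice — and `align_runs()` reconciles cluster labels across
independent runs by greedy RMSE matching against the first run. The
observed-data log-likelihood (and `alpha`) are recorded along the chain;
a Geweke-style comparison of the two halves of the post-burn-in trace is
the recommended convergence check and is what the test suite asserts.

## Synthetic data: what it does and does not emulate

Every analysis stage is exercised against generators with known ground
truth; all take a mandatory seed and are bit-reproducible:

* `simulate_hwe_population()`: genotype classes drawn with probabilities
  `(p^2 + Fpq, 2pq(1-F), q^2 + Fpq)`; `F = 0` is Hardy-Weinberg.
* `simulate_balding_nichols()`: population frequencies drawn around an
  ancestral frequency from the Beta parameterisation with `c` equal to
  the target F_st — the standard divergence ground truth. Ancestral
  frequencies default to `Uniform(0.1, 0.9)`, keeping loci informative the
  way a curated forensic panel is (panel loci are ascertained for
  intermediate frequencies; a uniform-on-(0,1) choice would include
  near-fixed loci such panels avoid).
* `simulate_admixed()`: each allele copy picks a cluster by the ancestry
  vector, then an allele by that cluster's frequency — exactly the model
  `structure_fit()` fits.
* `simulate_ld_pair()`: 2n haplotypes i.i.d. from four haplotype
  frequencies, paired randomly into unphased genotypes.
* `simulate_panel_like()`: a "study-scale" stand-in — n = 169 individuals
  at the 30 published panel insertion frequencies under HWE.

These generators emulate the *statistical* structure the analyses assume
(HWE within populations, Beta-distributed divergence, independent loci
unless LD is requested). They do not emulate genotyping artefacts
(allelic dropout, null alleles), mutation, linked marker blocks, or real
ascertainment noise — so passing tests demonstrate correctness of the
estimators under their assumed models, not robustness to violations of
those models.

## Numerical choices and problem sizes

Products over loci are always log-space; exact-test tie comparisons use a
`1e-12` relative guard; distance matrices must be symmetric to `1e-12`
with an exactly zero diagonal; EM converges at `1e-10`; NJ tie-breaks are
lexicographic. The test suite sizes its simulations to what a desk check
needs rather than study scale everywhere: exhaustive exact-test oracles
to n = 50, 10,000-replicate type-I-error calibration at n = 169,
Balding-Nichols F_st recovery at 500 loci × 500 individuals per
population, and a scaled-down admixture run (burn-in 2,000 + 2,000 sweeps
at 100 loci, two populations of 100) standing in for the full 10,000-sweep
protocol.

## Known limitations

Strictly diallelic markers only (no STRs, no multi-allelic extensions);
no kinship likelihood ratios beyond TPI; no haplotype-block detection or
multi-locus phasing beyond pairs; no hierarchical AMOVA variance
decomposition (locus-wise exact/permutation tests are provided instead);
no bootstrap support on NJ trees; MDS is metric-only; the admixture
sampler uses uncorrelated frequency priors (no F-model) and no linkage
model, and single chains can in principle blur under label switching on
weakly separated data.
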