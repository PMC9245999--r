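---
title: "Forensic Y-STR population analysis with ystrpop: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forensic Y-STR population analysis with ystrpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ystrpop)
```

## The problem

Forensic Y-STR panels type a few dozen short-tandem-repeat loci on the
male-specific Y chromosome. Because the loci are inherited as a single
non-recombining block, the unit of analysis is the *haplotype* — the joint
allele profile of one male — and the questions a population report answers
are: how polymorphic is each locus (gene diversity), how well does the
panel separate unrelated males (haplotype diversity, discrimination
capacity), how differentiated is the sampled population from reference
populations (pairwise Rst via AMOVA, visualized by MDS and a
neighbor-joining tree), and which Y-SNP haplogroups do the sampled
haplotypes most likely belong to.

`ystrpop` implements that entire analysis as a reusable, tested pipeline,
together with a forward stepwise-mutation-model simulator that generates
haplotype tables with *known* population structure. The simulator is what
makes the statistical components testable: every estimator in the package
is validated against closed-form expectations of the simulation model,
not against irreproducible published tables.

## Data model

A haplotype table is samples x loci. Three features of real Y-STR data
shape the design:

* **Multi-copy loci.** DYS385a/b and DYS527a/b amplify duplicated
  regions and yield an *unordered pair* of alleles per male. Pairs are
  canonicalized in ascending numeric order on input, so `"14,13"` and
  `"13,14"` are the same call, and frequency counting works on the
  canonical pair label (the "allelic combination").
* **Microvariants.** Alleles with an incomplete repeat unit are written
  `"27.2"`. The designation is stored exactly as an integer pair
  (repeats, fractional part) — never as a floating-point number — and
  maps to the repeat score `R + f/10` where a numeric score is needed.
  The fractional offset is a nomenclature device, so an alternative
  `microvariants = "exclude"` drops such calls from distance
  computations; the default keeps them, which retains samples.
* **Missing calls.** Encoded as empty cells. A missing call removes the
  sample from that locus's frequency table, but haplotype comparisons
  keep the row (missing compares equal only to missing). Complete
  profiles are unaffected by this rule; it only matters for partial
  typings.

Two optional score adjustments exist because common practice varies:
multi-copy loci can be included in distances via the sum of their two
designations (`include_multicopy = TRUE`; default off, since there is no
defensible single repeat score when allele pairing is ambiguous), and
DYS389II can be adjusted by subtracting DYS389I (`dys389_adjust = TRUE`;
default off) because the DYS389II amplicon physically contains DYS389I.

## Estimators

**Gene diversity** per locus is Nei's unbiased estimator
$GD = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)$, computed from counts
in the cancellation-free form $\frac{n}{n-1}(1 - \sum_i c_i^2 / n^2)$ so
that a locus where all $n$ observations differ gives exactly 1.
**Haplotype diversity** is the same statistic applied to whole-haplotype
frequencies, and is computed from the *frequency spectrum* — the counts
of haplotypes seen exactly $k$ times — which is its sufficient
statistic. **Discrimination capacity** is the number of distinct
haplotypes divided by the sample size. Reported values are rounded half
away from zero at 4 decimals (the convention of forensic reports); full
precision is kept internally. For a single-sample table HD and DC are
undefined and raise an error rather than returning NaN.

For multi-copy loci, GD is computed over allelic-*combination*
frequencies (the canonical pair labels), consistent with how
combinations are counted; computing it over pooled single-allele
frequencies instead would mix per-copy and per-male sampling units.

**Rst** comes from a single-level AMOVA on squared repeat-score
distances $d(a,b) = \sum_\ell (r_{a\ell} - r_{b\ell})^2$:

$$SSD_{WP} = \sum_p \frac{1}{n_p}\sum_{i<j \in p} d_{ij},\qquad
  SSD_T = \frac{1}{N}\sum_{i<j} d_{ij},\qquad
  SSD_{AP} = SSD_T - SSD_{WP}$$

$$\sigma_w^2 = \frac{SSD_{WP}}{N-P},\qquad
  \sigma_a^2 = \frac{SSD_{AP}/(P-1) - \sigma_w^2}{n_c},\qquad
  n_c = \frac{N - \sum_p n_p^2/N}{P-1},\qquad
  R_{st} = \frac{\sigma_a^2}{\sigma_a^2 + \sigma_w^2}$$

The permutation test reshuffles individuals between the two populations
holding sizes fixed and uses the add-one estimator
$p = (1 + \#\{R_{st}^{perm} \ge R_{st}^{obs}\})/(n_{perm}+1)$, which can
never report zero; ties count against the observed value (conservative).
The default is 999 permutations. $\sigma_a^2$ can legitimately be
negative (it is a method-of-moments estimator); the package reports it
as computed, with `clamp = TRUE` available for presentation, because
clamping silently would bias any downstream averaging of Rst values.
Per-pair permutation seeds are derived from the master seed and the
sorted label pair, so a pairwise matrix is identical regardless of
population order or processing order.

## Ordination and phylogeny

MDS is the classical (Torgerson) metric form: double-center the squared
distance matrix, eigendecompose, scale eigenvectors by the square roots
of their eigenvalues. It is deterministic and exactly recovers any
Euclidean-embeddable matrix, which is what makes it testable; iterative
stress-minimizing (nonmetric) MDS is out of scope. Rst matrices are not
guaranteed Euclidean, so negative eigenvalues are reported but never
used for axes, and negative Rst entries are floored at zero by default
before embedding (distances must be nonnegative; `floor_negative =
FALSE` disables this). PCA of haplogroup frequency tables is a
column-centered covariance eigendecomposition; explained-variance
fractions sum to 1 over all components.

The neighbor-joining tree is Saitou–Nei agglomeration, delegated to
`ape::nj()` — the reference implementation in R — behind the package's
`nj_tree()` surface; its deterministic internal tie handling is used
as-is. For an additive input matrix NJ recovers the generating tree
exactly, and the test suite verifies this on random trees of up to six
taxa. Negative *branch lengths* (which NJ can produce on noisy input)
are preserved and serialized as-is in Newick output.

## Haplogroup prediction

Published Y-haplogroup assignments from STR profiles rely on large
proprietary reference panels; the panel is therefore a user input here.
The predictor is deliberately transparent: k-nearest-neighbor (default
`k = 5`) under the mean per-locus squared repeat difference over shared
usable loci, with multi-copy loci contributing the minimum-cost pairing
of their two designations (each copy counted in the locus total). Vote
ties break by smaller mean distance, then lexicographically, so results
are deterministic. A query is `"unassigned"` when fewer than
`locus_overlap_min` (default 10) designations are shared with any
reference, or when the winning score exceeds `threshold` (default
infinity — always assign when the overlap suffices, mirroring the
always-predict behavior of database lookups). Haplogroup labels are
treated as flat strings; the hierarchical structure of the Y phylogeny
is ignored because reported haplogroup tables are flat percentages. A
Bayesian allele-frequency scorer would be the natural extension point
but is not implemented.

## The simulator and what it does (and does not) show

`simulate_table()` runs a forward *star genealogy*: an ancestral
haplotype, one founder per population after `Poisson(mu * t_split)`
symmetric single-step mutations per locus copy, and each sampled male
after `Poisson(mu * t_within)` further steps from his founder; repeat
counts are floored at 1. Dual-copy loci are two independent copies,
canonicalized; microvariants can be injected at a configurable per-call
probability to exercise parsing and scoring paths.

Under this model each mutation step contributes variance 1 to the
repeat count, so two lineages separated by total time $T$ satisfy
$\mathrm{E}[(r_i - r_j)^2] = 2\mu T$ per locus. That yields the
closed-form truth shipped with every simulation: expected within-pair
distance $2\sum_\ell \mu_\ell t_{within}$, expected between-pair
distance $2\sum_\ell \mu_\ell(t_{within}+t_{split})$, and expected
$R_{st} \approx t_{split}/(t_{split}+t_{within})$.

Defaults are chosen once and used throughout: the bundled 30-copy panel
(26 single-copy plus two dual-copy loci, matching the locus count of
the slowly/moderately mutating forensic kits), `mu = 0.05` per time
unit, `t_within = t_split = 10`, founder allele 13 repeats. Time units
are arbitrary; only the products `mu * t` matter, and 0.5 expected
mutations per locus per lineage segment gives the moderate
within-population diversity such panels show in practice while keeping
the floor-at-1 bias negligible at a founder allele of 13.

The star genealogy is *not* a coalescent: sampled lineages within a
population are independent given the founder, so within-population
genealogical correlation is absent. This is intentional — it buys exact
expectations for validation — but it means a passing test demonstrates
estimator correctness under the stated model, not robustness to the
correlation structure, mutation-rate heterogeneity, multi-step
mutations, migration or selection present in real data. The
divergence-recovery checks (mean Rst near its expectation; Rst ordering
monotone in divergence time) use 2 x 50 samples over 26 single-copy
loci: at that size the sampling noise of the founder drift dominates
(about 0.09 standard deviation in a single replicate's Rst), so means
over 20 replicates resolve the expectation to within ±0.1.

## Numerical and degenerate-input choices

* HD of an all-unique spectrum is exactly 1 (counts form, no
  cancellation); verified to 1e-12.
* All-identical populations give $\sigma_a^2 = \sigma_w^2 = 0$; Rst is
  defined as 0 there rather than 0/0.
* Matrix writers validate symmetry to 1e-9 and a zero diagonal;
  MDS/NJ reject asymmetric input the same way.
* `k` larger than the number of positive MDS eigenvalues is reduced
  with a warning rather than padding axes with noise.
* Frequency-vector input to PCA is validated loosely (row sums within
  0.02 of 1 warn, not error) because published tables are themselves
  rounded.

## Problem sizes used by the test suite

The suite validates on deliberately small configurations — tables of
tens to a few hundred rows, 4–28 loci, permutation counts of 49–4999,
20-replicate simulation grids — chosen so the full statistical battery
(exhaustive-permutation agreement, null p-value uniformity, divergence
recovery, predictor accuracy on 500 held-out queries) runs in well
under a minute per file. These sizes are stated here as the package's
validation design; all estimators are O(N^2) in samples at worst and
run comfortably at realistic study sizes (hundreds of males, dozens of
populations).

## Known limitations

* Rst treatment of multi-copy loci and microvariants differs between
  published tools and is rarely documented; numeric equality with any
  specific published Rst table is therefore not a goal. The package's
  conventions are explicit and switchable.
* The haplogroup predictor's accuracy depends entirely on the supplied
  reference panel; the shipped accuracy bound holds for the simulated
  deep-split panel described above, not for any real panel.
* Nonmetric MDS, hierarchical (multi-level) AMOVA, haplotype match
  statistics with population-substructure corrections, and bootstrap
  support on NJ trees are out of scope.
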