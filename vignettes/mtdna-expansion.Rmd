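---
title: "Molecular diversity, neutrality tests and expansion dating with mtexpand"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular diversity, neutrality tests and expansion dating with mtexpand}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtexpand)
library(dplyr)
```

mtexpand implements the classical single-locus toolkit of intraspecific
mtDNA phylogeography: haplotype accounting, molecular diversity indices,
Tajima's D and Fu's Fs with simulation p-values, mismatch-distribution
fits of the sudden-expansion model with calendar-year dating, Tamura–Nei
model distances, and median-joining haplotype networks. The package ships
the golden jackal (*Canis aureus*) control-region and cytochrome-b
haplotype tables as worked fixtures, and a coalescent simulator that
generates data under the same models the statistics assume, so every
estimator can be checked against data with known truth.

## Data model

Published mtDNA surveys usually print a haplotype-by-variable-site table:
distinct haplotypes in rows, the variable alignment columns (with their
coordinates on a reference mitogenome) in columns, and per-locality
frequency counts alongside. `mt_haplotypes()` / `read_haplotype_table()`
hold exactly that, and `expand_table()` /  `collapse_haplotypes()` convert
between the haplotype-table and per-individual-alignment views. Because
only variable columns are stored, per-site quantities such as nucleotide
diversity need the total locus length `L`, which travels as an attribute
and is always overridable — for the jackal control region the amplified
fragment is ~440 bp, but the length underlying the published π values is
not stated, so `L` is deliberately a user-facing parameter rather than a
constant.

Two characters get special treatment everywhere: `-` is an alignment gap
(an indel state actually observed) and `?` is missing data (never a
state). The programs this field traditionally uses disagree on gap
handling, so every statistic takes an explicit `gap_policy`:

* `gap_as_state` — `-` is a fifth character; used by default for counting
  segregating sites S (this reproduces the published India S = 25 from
  the control-region table),
* `gap_as_missing` — pairwise deletion; default for mean pairwise
  differences k and π,
* `complete_deletion` — columns containing any `-`/`?` are dropped
  wholesale; default for the neutrality tests, mismatch distributions and
  model distances, matching the stated conventions of the source
  analyses.

These per-stage defaults are pinned and documented rather than unified,
because each statistic in the published tables was evidently produced
under a different convention.

## Diversity and neutrality statistics

Haplotype (gene) diversity uses the unbiased estimator
$h = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)$ with Nei's (1987)
sampling variance; nucleotide diversity is $\pi = k/L$ with the classical
variance approximation combining sampling and coalescent stochasticity.

Tajima's D standardizes $k - S/a_1$ with the constants of Tajima (1989);
it is negative when rare variants are in excess, the footprint of recent
demographic expansion. Fu's Fs asks how surprising the observed number of
distinct haplotypes $K$ is under the Ewens sampling distribution with
$\hat\theta = k$:

$$F_s = \ln\frac{S'}{1-S'}, \qquad
  S' = P(K \ge k_{obs}) = \sum_{j \ge k_{obs}}
  \frac{|s(n,j)|\,\theta^j}{\theta_{(n)}},$$

where $|s(n,j)|$ are unsigned Stirling numbers of the first kind. The
Stirling table is built by the standard recursion entirely in log space
(log-sum-exp), so the statistic is stable up to thousands of sequences;
$F_s$ itself is computed as $\log S' - \log(1-S')$ in log space, so a
vanishingly small tail probability yields a large negative but finite
value. Only the genuinely degenerate cases ($k = 0$, a single haplotype,
or an exact 0/1 tail) raise typed errors.

P-values for both statistics come from constant-size coalescent
simulation at $\theta = k$ with the observed sample size, as in the
standard programs: the reported p is the lower-tail fraction of simulated
statistics at or below the observed one (the direction that indicates
expansion). The run is seeded and reproducible.

## Mismatch distributions and expansion dating

Under a sudden (stepwise) expansion from $\theta_0$ to $\theta_1$ at
mutational time $\tau = 2ut$ before the present, the expected distribution
of pairwise differences is the Rogers–Harpending curve

$$F_i = \hat F_i(\theta_1) + e^{-\tau(\theta_1+1)/\theta_1}
  \sum_{j=0}^{i}\frac{\tau^j}{j!}
  \left[\hat F_{i-j}(\theta_0) - \hat F_{i-j}(\theta_1)\right],$$

with $\hat F_i(\theta) = \theta^i/(\theta+1)^{i+1}$ the equilibrium
geometric. `fit_sudden_expansion()` minimizes the sum of squared
deviations between this curve and the observed relative frequencies,
using a coarse grid over $\tau \in [0, 2 d_{max}]$ and
$\theta_0 \in [0, \bar d]$ followed by `optim(L-BFGS-B)` refinement.
$\theta_1$ is fixed at 99 999 by default — the convention of the classical
mismatch software; freeing all three parameters on shallow data is
ill-conditioned — and can be freed with `free_theta1 = TRUE`. Observed
frequencies are zero-padded to twice the largest observed difference so
that model mass beyond the data's support is also penalized. Harpending's
raggedness $r = \sum_{i=1}^{d+1} (x_i - x_{i-1})^2$ (with $x_{d+1}=0$)
quantifies the smoothness of the observed distribution.

Two conventions matter for reproducing published numbers:

* **Haplotype-level distributions.** The jackal analysis estimated τ
  from pairwise differences *among haplotypes*, i.e. each distinct
  haplotype enters once regardless of its frequency. The pipeline follows
  that convention (`mismatch_level = "haplotype"`, via
  `haplotype_alignment()`); the frequency-weighted per-individual
  distribution is available as an option. On the control-region fixture
  the haplotype-level mean pairwise difference (5.25) is close to the
  published k = 5.091, while the individual-level value (3.26) is not —
  strong evidence that this is what the original analysis did.
* **Dating arithmetic.** $\tau = 2\mu t$ is inverted as
  $t = \tau/(2\mu)$ generations with μ treated as a *whole-locus*
  per-generation rate, exactly as the source analysis applied it (its
  printed 37,083 and 20,548 years follow only under that reading, with
  fractional years rounded up). A `per_bp` mode ($u = \mu L$) is provided
  but off by default, since the published arithmetic did not use it.

Confidence intervals for τ come from a parametric bootstrap
(`tau_bootstrap_ci()`): simulate from the fitted model with the same
sample size, refit, and take percentile bounds. Dates are mapped through
the same transform.

## Median-joining networks

`build_mjn()` implements a Bandelt-style median-joining construction:

1. equal (or user) site weights define weighted Hamming distances;
2. the ε-relaxed minimum spanning network connects the haplotypes — with
   ε = 0 this is the union of all minimum spanning trees (Kruskal with
   equality grouping), which minimizes alternative connections;
3. for every triplet of nodes with at least two links, the columnwise
   majority consensus is a candidate median (Steiner) vector; all
   candidates achieving the minimal connection cost (within ε) are added;
4. the network is rebuilt to a fixpoint, and median vectors with fewer
   than two links are pruned.

All ties — candidate order, majority ties in median construction — break
lexicographically, making the output deterministic; the published
algorithm is order-sensitive, so this pinning is essential for testable
behaviour. Non-binary columns use the majority state rather than the full
quasi-median expansion, a simplification that is exact for the fixture
data (every column there is at most tri-allelic and medians arise from
triplets). Indel-containing columns should be removed first
(`drop_indel_sites()`), mirroring the published treatment of alignment
blocks containing indels; degree counts in `network_stats()` include
links to median vectors.

On the 18 control-region haplotypes (22 substitution-variable columns
after removing the five indel columns) the network reproduces the
published topology: eleven haplotypes are peripheral (degree 1), Ind11 is
the most interior with six connections, and Ind1, Ind7, Ind8 and Ind15
carry four each; the European haplotype attaches one mutation away from
an Indian haplotype and the Israeli one two mutations away through a
median vector.

## TN93 distances

`tn93_distance()` evaluates the Tamura–Nei closed form with separate
purine and pyrimidine transition classes, with the gamma-rate
generalization ($-\log w \rightarrow a(w^{-1/a}-1)$, shape 0.3 by
default as in the source analysis). Base frequencies are estimated from
the pooled pair (the common convention; the source is silent), columns
with gaps or missing data are removed first (complete deletion), and
saturation raises a typed error rather than NaN. Group means average all
between-group pairs, with standard errors from a seeded bootstrap over
alignment sites (1000 replicates by default). The unit tests cross-check
the implementation against an independent library implementation of the
same model to 1e-9.

## The coalescent simulator

`simulate_coalescent()` draws a genealogy under a constant-size or
two-epoch (sudden-expansion) demography and drops Poisson mutations on
its branches. Time is measured in mutational units so that simulator τ is
directly comparable to fitted τ; for a constant population E[k] = θ and
E[S] = θ·a₁(n), which the test suite verifies by Monte Carlo. Mutations
are placed under the infinite-sites model on distinct positions of an
L-bp locus (matching the assumptions of D, Fs and the mismatch model); a
finite-sites option with recurrent hits exists for robustness checks.

The generator emulates: sample-size and θ regimes like the study's
(n of tens, θ of a few units), expansion footprints (negative D, excess
haplotypes, unimodal mismatch), and seeded reproducibility. It does not
emulate recombination, migration/structure, selection, rate heterogeneity
across sites, or sequencing artefacts — so passing calibration tests
shows the estimators behave correctly under their own assumptions, not
that real data meet those assumptions.

Calibration studies in the test suite use these fixed conditions, chosen
once as representative of the study scale: τ-recovery simulates n = 50
samples at τ = 5, θ₀ = 0.5 with θ₁ at the fitting ceiling 99 999 (100
replicates; the median |τ̂ − 5| must stay within 1); interval coverage
uses n = 30 with 100-replicate bootstraps; the type-I error of D uses
n = 30, θ = 5 with two independent batches of 1000 simulations (one to
calibrate null quantiles, one to test). Simulating instead with θ₁ near
the data scale (say 50) introduces a known downward model-mismatch bias
of about one unit in τ̂ — a property of fixing θ₁ during fitting, worth
remembering when interpreting fitted τ on real data.

## Numerical and design choices

* **Stirling numbers / Ewens probabilities** in log space; exact against
  integer enumeration for n ≤ 8 in the tests.
* **Expansion-curve evaluation** via a vectorized convolution with the
  geometric terms computed in log space (stable for θ₁ = 99 999 and
  hundreds of difference classes); tiny negative values from cancellation
  are clipped to zero.
* **Dating rounds up** to the next whole year, matching the published
  arithmetic.
* **Degenerate inputs** raise typed conditions
  (`mtexpand_undefined`, `mtexpand_degenerate`, `mtexpand_saturated`)
  rather than returning NaN: S = 0 for D; k = 0 or a single haplotype for
  Fs; single-class histograms for the expansion fit; saturated
  proportions for TN93.
* **Group sizes n = 51 vs 52**: the printed control-region locality
  counts sum to 52 Indian individuals while the published summary reports
  n = 51. The fixture preserves the printed counts; a documented
  `as_analyzed` flag removes one copy of the modal haplotype to match the
  published n. Statistics that depend on the difference (h in the third
  decimal) are treated as soft comparisons only.
* **p-value tails** are lower-tail for both D and Fs, recorded in the
  result row, since published P columns are uninterpretable without
  fixing this convention.

## Known limitations

Published tables are the only input for the fixture analyses, and they
under-determine some published values: the summary k (and hence π and the
printed D and Fs) for the Indian sample cannot be reproduced exactly from
the printed haplotype table under any single gap policy, so those are
checked as signs and magnitude bands rather than digit-for-digit. The
median-joining implementation prunes by degree rather than by full
shortest-path obsolescence, and does not implement the complete
quasi-median expansion for non-binary columns; both simplifications are
inconsequential for data of this shape but could matter for much denser
tables. The simulator is single-locus and neutral by construction.
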