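---
title: "Gene dynamics of haplodiploidy and the origin of eusociality: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene dynamics of haplodiploidy and the origin of eusociality: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplodyn)
```

## The question

Whether haplodiploidy predisposed the Hymenoptera to evolve eusociality is a
long-standing problem. The classic relatedness argument (full sisters share
3/4 of their genome) does not by itself favor helping, because brothers are
correspondingly less related and, at an even sex ratio, raising siblings and
raising offspring pay the same. `haplodyn` implements a gene-centric
alternative: track copies of an altruism allele through the actual subsocial
lifecycles ancestral to eusocial bees and wasps, and ask when helping
produces more copies in dispersing offspring than independent breeding
would. The decisive mechanism is transmission, not relatedness per se: a
haploid father passes a new allele to *every* daughter, so carrier-father
nests are saturated with potential helpers.

## The model

A single locus has a wild-type allele `A0` and an altruism allele `A1`,
conditionally expressed only in first-brood daughters — the only individuals
with an opportunity to help their mother. Mating is monogamous. Two
lifecycles are covered (both observed in halictine and allodapine bees and
polistine wasps):

* **univoltine** — a foundress produces two broods of `n` offspring; all
  offspring disperse, mate, and daughters enter diapause. A first-brood
  daughter expressing `A1` instead stays and helps, adding `b` offspring to
  the second brood.
* **partially bivoltine** — first-brood offspring disperse and breed within
  the season (a dispersing daughter produces `n2` offspring); helping
  daughters forgo that brood. The second generation plus the foundress'
  second brood form the autumn pool.

Expression (penetrance) of helping is 1 for heterozygous daughters under
dominance and 1/2 under codominance (probabilistic expression), and always 1
for `A1A1`. The codominant 1/2 rule is a reconstruction — it is the unique
simple penetrance that reproduces the codominant threshold `b > 2`, the
weighted copy count `5n/6 + nb/12`, and the ordering dominant > codominant
of the `R(b)` curves — and is flagged as such here.

### Invasion accounting

A single `A1` copy lands either in a foundress (`A0A1 x A0`, weight 2/3) or
in her mate (`A0A0 x A1`, weight 1/3) under haplodiploidy; the weights are
the sexes' shares of genome copies (equivalently their reproductive values).
Under diploidy there is one cross, `A0A1 x A0A0`. For each cross,
`season_account()` counts `A1` copies among dispersing offspring at season's
end, exactly and symbolically in `(n, b, n2)`; `weighted_invasion_summary()`
averages over crosses to give `x`, and the same account with expression
disabled gives the neutral baseline `x_neutral` (equal to `n` for the
univoltine lifecycle). The allele invades when `x > x_neutral`; the
threshold solves `x(b) = x_neutral(b)` exactly.

```{r}
cfg <- genetic_config("haplodiploid", "dominant", "univoltine")
su <- weighted_invasion_summary(cfg)
format(su$x)          # 2n/3 + nb/6
format(su$x_neutral)  # n
invasion_threshold(cfg)
```

The naive alternative — counting a pair's dispersing offspring without
regard to their genotypes — is retained as a negative control
(`naive_dispersal_condition()`, threshold `b > 1`): dispersing first-brood
daughters are biased toward non-carriers because carriers stayed to help,
so offspring counting misattributes copies.

### Sex-ratio adjustment

When a fraction `a` of first-brood daughters help, the pair's dispersing
first brood becomes male-biased. Fisherian selection for equal investment in
dispersing offspring is imposed through the first-brood sex ratio: the
female proportion becomes `f = 1/(2 - a)`, which restores the pair's
dispersing first brood to exactly 1:1 (`f(1 - a) = 1 - f`). The adjustment
is applied **per mated pair**, using that pair's expected helper fraction;
only the per-pair rule reproduces the adjusted thresholds (`b > 1.4`
univoltine, `b > 0.7 n2` bivoltine for haplodiploidy, against `b > 2` and
`b > n2` for diploidy — a 30% reduction). The neutral baseline uses `a = 0`
(`f = 1/2`): a neutral allele creates no helpers, so nothing is adjusted.
This is what keeps the diploid adjusted threshold at `b > 2`.

The adjustment benefits haplodiploidy disproportionately because of the
carrier-father cross: there `a = 1`, so `f = 1` and the entire first brood
consists of helper daughters. On average 5/9 of first-brood offspring are
altruist females under haplodiploidy versus 1/3 under diploidy
(`altruist_daughter_fraction()`).

### Fixation and substitution

The heterozygote carrier's relative fitness is `x / x_neutral`, so
`s = x/x_neutral - 1` (exact rational; `selection_coefficient()`). For a
new beneficial allele under weak selection the fixation probability is
`pi = 2s` regardless of ploidy or dominance; we cap it at 1
(`fixation_probability()`), the only reading under which the haplodiploid
advantage window `2 < b < 6` exists: the haplodiploid curve `(b-2)/3` caps
at `b = 5`, the diploid curve `(b-2)/4` at `b = 6`, and above 6 both sit at
1. For `s <= 0` the approximation returns 0; the true small neutral
fixation probability is measured by the stochastic module instead.

The substitution rate is `rho = c N mu pi` with `c` the mean genome copies
per individual (1.5 haplodiploid at an even sex ratio, 2 diploid). At
`b = 3`, `c pi` is identical for the two ploidies (1.5 x 1/3 = 2 x 1/4), so
the haplodiploid fixation advantage is exactly cancelled by the larger
mutational target of a diploid population — both give 2000 generations per
substitution at `N = 1e6`, `mu = 1e-9`.

## Deterministic time course

`run_timecourse()` iterates mated-pair genotype frequencies (6 pair types
haplodiploid, 9 diploid) over seasons in an infinite population. Pairs, not
gametes, are the state because dispersers carry genotype biases even though
mating is random. Design choices that were genuinely open:

* **Mating pools.** Univoltine: first-brood dispersers mate within the
  first-brood pool and second-brood dispersers within the second-brood
  pool; next spring's foundress pairs are the female-count-weighted mixture
  of diapausing mated females. Partially bivoltine: one panmictic autumn
  pool combines second-generation and second-brood individuals. This
  follows the lifecycles' timing (disperse, mate, diapause). At the
  rare-allele limit the thresholds are insensitive to the pooling, which is
  the surface validated against the exact accounting.
* **Random mating** is the product measure of a pool's female counts and
  male genotype frequencies.
* **`a` is deterministic per pair type** (the infinite-brood expectation),
  so `f` is too.
* **Allele frequency** is copy-weighted over newly formed foundress pairs
  (females 2 copies, males 1 or 2).

The validated surface is rare-allele growth: one season from the
introduction-weighted state, the growth `p1/p0` equals `x / x_neutral`
exactly in the limit, for all 16 combinations of ploidy, dominance,
lifecycle and adjustment. A finite perturbation `p0` carries an `O(p0)`
density-dependence (carrier pairs shift pool sizes), so
`rare_allele_growth()` Richardson-extrapolates from `p0` and `p0/2` by
default, returning the limiting growth at working precision;
`extrapolate = FALSE` gives the raw one-step ratio.
`empirical_threshold()` bisects this growth factor and recovers 1.4, 2 and
`0.7 n2` to the requested tolerance (default `1e-8` on `b`).

Numerical settings: trajectories run in doubles with stationarity tolerance
`1e-12` on `|dp|`, absorption declared at `p > 1 - 1e-9` (or below `1e-9`
for loss), and a default cap of `1e4` generations; all configurable.
Approach to fixation is geometrically slow (the residual wild-type allele
declines by a factor close to 1 per season), so comparisons of fixation
speed between ploidies use the generation at which `p` first exceeds 0.99.
With the adjustment on, the population-wide dispersing sex ratio is exactly
1:1 every generation; with it off, the dispersing pool grows progressively
male-biased as `p` rises.

## Stochastic simulator and synthetic data

The finite-population module is both the brute-force oracle and the
synthetic-data generator. Each spring holds exactly `N` foundress pairs;
broods are sampled at the genotype level with the exact Mendelian
probabilities (multinomial composition, binomial sex assignment, binomial
expression), so every expectation matches the deterministic model; the next
generation is resampled with replacement from the diapausing mated females
(the simplest Wright-Fisher-style regulation consistent with a fixed
population size `N`). Fractional expected brood sizes are realized by
stochastic rounding (floor plus Bernoulli remainder), preserving
expectations exactly. A single introduced copy is placed in a carrier pair
drawn with the 2/3 : 1/3 weights. Optional one-way mutation `A0 -> A1` is
applied per transmitted copy (default 0). All randomness flows from one
seed; trajectory datasets embed the full configuration and seed in their
header and are byte-identical across runs.

What the generator emulates — and what it does not: it reproduces the
model's assumed structure (monogamy, two broods, conditional helping,
per-pair sex-ratio adjustment, diapause, fixed `N`). It does not emulate
features of real sweat-bee or wasp populations such as overlapping
generations, nest failure, spatially structured mating, multiple mating, or
environmentally cued (rather than genetic) helping. Passing tests therefore
show internal consistency of the model's machinery, not realism of the
lifecycle assumptions.

Two calibration notes. First, the mean of `a1_copies` from
`simulate_pair_season()` converges on the exact season-account totals; the
tests assert agreement within four standard errors across randomized
scenarios. Second, the simulated fixation probability at `N = 1000`,
`b = 3` falls below `2s = 1/3` (about 0.25): the doubling `pi = 2s`
assumes Poisson-scale reproductive variance, while brood-level sampling
plus resampling regulation inflates the variance of a pair's copy output
(even exact Poisson branching at `s = 1/6` gives 0.31). The acceptance
test therefore requires the simulated value to lie below `2s` but within a
factor of two of it — a documented tolerance on an approximation, not on
the simulator.

Default study conditions used in tests: brood size `n = 4` (mean brood
sizes of four to five are reported for the relevant solitary and subsocial
carpenter bees, and three to seven for potter wasps), `b = 3` (between the
thresholds 2 and 6 where the fixation contrast is visible), `n2 = 4` for
the bivoltine lifecycle, populations of `N = 1000` pairs for fixation
experiments and `N = 10^4` for law-of-large-numbers checks against the
recursion (200 and 100 replicates respectively, chosen so Monte-Carlo
error is well below the tolerances asserted).

## The empirical statistic

The adjusted model predicts a female-biased *overall* first-brood sex ratio
in primitively eusocial species. The packaged 2x2 table of sweat-bee
species counts (social organization by first-brood bias) gives Pearson
`X^2 = 21.496` on 1 df, `p < 0.001`, computed **without** Yates continuity
correction — the uncorrected statistic is the only one consistent with the
published value, and the 2x2 independence reading is the only one
consistent with 1 df. `sample_tables()` generates synthetic tables for
type-I-error calibration (rejection rate near 5% under equal bias
probabilities) and parametric-bootstrap checks.

```{r}
chi_square_2x2(halictine_sexratio_counts())
```

## Exact arithmetic

Every probability, proportion and copy count in the invasion module is an
exact rational (`rational()`), and season accounts are sparse polynomials
in `n`, `b`, `n2` with rational coefficients (`qp_var()`, `qp_equal()`).
This is not cosmetic: the published thresholds are exact rationals
(`2`, `7/5`, `7 n2/10`), the `R(b)` curves are ratios of linear forms, and
the tests assert symbolic identity rather than numeric closeness. Floating
point appears only in the time-course and stochastic modules and at the
reporting boundary.

## Known limitations

* Recessive altruism alleles and penetrances other than {0, 1/2, 1} are out
  of scope, as are multi-locus genetics, non-monogamous mating and csd/fem
  sex-determination mechanics.
* The per-pair sex-ratio rule is imposed, not evolved: `f` tracks `a`
  instantly, standing in for frequency-dependent selection on a sex-ratio
  modifier.
* The recursion's mating-pool structure beyond the rare-allele limit is a
  reconstruction; equivalence with the source analyses is claimed only at
  the validated surfaces (thresholds, rare-allele growth, qualitative
  fixation-speed ordering).
* `pi = 2s` is a weak-selection approximation; at the `s` values used in
  examples it overstates the simulated fixation probability by roughly the
  reproductive-variance factor discussed above.
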