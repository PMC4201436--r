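---
title: "Models and methods behind pinepop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pinepop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pinepop)
```

pinepop implements the complete statistical toolkit of a multilocus
population study of a rare, low-diversity conifer: sequence diversity and
neutrality tests on phased nuclear loci, linkage disequilibrium and its
decay, AMOVA-based differentiation with permutation tests, chloroplast
microsatellite (cpSSR) haplotype analyses including the mismatch
sudden-expansion test, and coalescent approximate Bayesian computation (ABC)
over three single-population demographic models. This vignette explains the
models, the parameter conventions, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## Sequence statistics and site classification

Alignments are phased: each diploid individual contributes its two allele
sequences. Columns carrying a gap or `N` in any ingroup sequence are
excluded from every count (complete deletion). Classic diversity programs
differ in their deletion convention; complete deletion — the common default
and the deterministic choice — is used throughout.

Coding columns are classified codon-by-codon with Nei–Gojobori site
counting on a reference codon built from the majority base at each column
(ties broken alphabetically): the synonymous fraction of a codon position is
the fraction of its three possible single-base changes that preserve the
amino acid, with changes to stop codons counted as nonsynonymous. "Silent"
sites are noncoding columns plus the synonymous fractions of coding columns,
so the silent-site Watterson estimator `theta_ws` and the diversities
`pi_s`, `pi_a` use fractional site counts. Pairwise differences are weighted
by the same per-column class weights; this is a site-level approximation to
full pathway counting between codons, exact for noncoding columns and for
coding columns whose difference is a single base.

Within-population inbreeding (`F_IS = 1 - H_obs/H_exp`) treats the distinct
full-locus haplotypes as alleles — the natural choice for sequenced (rather
than SNP-genotyped) loci — with the unbiased within-population expected
heterozygosity, averaged over polymorphic locus-by-population cells and then
over populations. Across-locus averages of per-site rates are site-weighted
by default (`weighting = "arithmetic"` is available): per-site quantities
estimated from more sites deserve more weight, and the distinction is
inconsequential when locus lengths are similar.

## Neutrality tests

Tajima's D uses the 1989 variance constants. Fu & Li's D* and F* use the
starred (outgroup-free) formulas with the later-corrected constants that
standard software implements; singletons are counted on the folded spectrum.
Fu's Fs computes `S' = Pr(K >= k_obs | theta_pi)` from the Ewens sampling
distribution with unsigned Stirling numbers of the first kind evaluated in
log space (exact and overflow-free to n well beyond this study's 114
chromosomes). Fay & Wu's H is the standardized version: sites are polarized
against the single outgroup, sites where the outgroup carries a gap, `N` or
a third state are excluded (with one outgroup there is no parsimony
fallback), and the variance is the Zeng et al. (2006) normalization.

Significance comes from coalescent simulation conditioned on the observed
number of segregating sites (fixed-S): genealogies from the standard
coalescent with exactly `S` mutations placed on branches with probability
proportional to branch length. Fixed-S matches the common default of the
classic analysis programs and is deterministic given a seed. All tests are
two-tailed except Fu's Fs, which by convention is one-tailed toward negative
values; ties count as extreme. The test suite verifies that each test
rejects at close to its nominal 5% level under the fixed-S null. One
caveat worth knowing: Fu & Li's starred statistics are functions of the
singleton count alone once S is fixed, so at very small S their null takes
few distinct values and the ties-as-extreme convention makes them
conservative (rejection below nominal) — never anticonservative. The
calibration suite therefore conditions on S = 25; at S = 10, D* rejects at
roughly 1.5% instead of 5%.

The McDonald–Kreitman table classifies each coding change by mutating the
majority-base reference codon at the focal position; the test is reported
as not calculable whenever a margin of the 2x2 table is zero, the usual
outcome at low-polymorphism loci.

## Linkage disequilibrium

`r^2` is computed from phased haplotype counts at informative sites —
biallelic columns whose minor allele is carried by at least two chromosomes
(the threshold is configurable; "informative" has no universal cutoff in
this literature). Fisher exact tests get a Bonferroni correction whose
family is the total number of tested pairs across all loci. Kelly's ZnS, in
contrast, averages `r^2` over *all* pairs of segregating sites, because it
feeds the ABC summary vector; for loci with fewer than two segregating
sites it is defined as 0 and flagged, so that low-diversity simulated
datasets still yield complete summary vectors (rejection ABC cannot use
incomplete rows).

The decay of LD with distance is fitted by least squares to the Hill–Weir
drift-recombination expectation with the sample-size correction term, with
a single parameter `C_per_bp` (so `C = C_per_bp x distance`), pooling pairs
across loci — the pooled regression is what "overall decay across ten loci"
implies. The fit is a log-spaced grid search over `C_per_bp` in `[0, 10]`
followed by golden-section refinement; noiseless curves are recovered to
1e-4 and the zero-decay boundary is reported with a warning.

## Population structure

AMOVA treats pairwise difference counts (sequences) or repeat-distance
scores (SSRs) as squared Euclidean distances and extracts the standard
variance components; negative components are *not* truncated, so `F_ST` can
be slightly negative, as unbiased estimators require. Significance permutes
units among populations; populations with a single unit are excluded with a
warning. An optional population-to-region map adds the three-level
decomposition with `F_CT`; the simulated-annealing search over groupings
performed by other software is out of scope.

For cpSSR haplotypes the unordered/ordered pair of differentiation
estimators is `G_ST = 1 - hS/hT` from multilocus haplotype frequencies and
`R_ST`, its generalization with the sum of squared per-locus repeat
differences as the haplotype distance. Both use equal population weights
and plug-in diversities (`hS` the mean within-population diversity, `hT`
from mean haplotype frequencies). The exact small-sample variant used by
the original comparison program is version-dependent; the plug-in form has
the defining property that identical population frequency vectors give
exactly `G_ST = 0`, and under permutation of repeat scores among haplotype
labels the expectation of `R_ST` matches `G_ST`, which is precisely the
premise of the permutation test (`p = Pr(R_ST_perm >= R_ST_obs)`).

The Mantel test correlates off-diagonal pairwise `F_ST` with great-circle
(haversine) distances and permutes rows and columns of one matrix jointly;
with up to 7 populations all permutations are enumerated, making the
p-value exact (this study's 6 populations give 720).

## The coalescent engine

The simulator is a Hudson-style backward-in-time ancestral recombination
graph written in C++ (R's RNG, so `set.seed()` governs everything). Time is
measured in units of 4N0 generations; per-site `theta` and `rho` are scaled
by 4N0 and multiplied by locus length. Three demographic models are
supported:

* **SNM** — constant size; parameters `theta` and `rho` only.
* **GROWTH** — looking backward, size `N0 exp(-alpha t)` until `T0`, then
  the ancestral size `N1_rel x N0`, with `alpha = ln(1/N1_rel)/T0`
  (natural logarithm, the ms convention).
* **BOTTLENECK** — the same shrinking phase to `T0`, a constant bottleneck
  plateau `N1_rel x N0` on `[T0, T0 + Td]`, and size `N0` before. A
  constant plateau is assumed during the bottleneck; the alternative
  (gradual shrinkage) is not identifiable from the description this
  follows.

Waiting times under piecewise exponential/constant trajectories are drawn
by closed-form inversion of the integrated hazard segment by segment.
Mutations are laid down *online*: between events, a Poisson number of
infinite-sites mutations falls on the live ancestral material, each
carrying the descendant set of the segment it hits; material whose
descendant set reaches the full sample has found its local MRCA and is
removed, so no mutation can be placed above it. Recombination breakpoints
fall uniformly on each lineage's breakable span (ancestral extremes
inclusive of trapped material, as in ms); gene conversion is not modelled.
The engine's output is verified in the test suite against `E[S] = theta
a_n`, the `1/i` shape of the unfolded frequency spectrum, the negative-D
signature of growth, and — distributionally, by Kolmogorov–Smirnov on `S`
and `pi` — against msprime run at mapped-identical parameters under all
three models.

Chloroplast SSR loci evolve on a single shared genealogy (no chloroplast
recombination) under a symmetric stepwise model: each locus accumulates
Poisson(`theta_ssr` x branch length) steps of ±1 repeat. Repeat counts
below 1 after summation are reflected (`k -> 2 - k`); with the default
ancestral count of 10 this is essentially never triggered.

## ABC demographic inference

Reference tables draw parameters from uniform priors. The per-site `theta`
and `rho` ranges (1e-5–0.05 and 1e-5–0.1) are the standard ranges for conifer nuclear loci;
the demographic bounds are package configuration, chosen to span severe and
recent size changes while keeping genealogies resolvable: `N1_rel` in
[0.001, 1], `T0` and `Td` in [1e-5, 0.05] (4N0 units). These comfortably
contain the posterior scale typical of relict-conifer inference (`T0`
mode near 8.6e-4, upper quantile near 2.3e-2).

Each simulated dataset is summarized by the across-locus means of Watterson's
`theta_w`, Tajima's D, standardized Fay & Wu's H (ancestral states known in
simulation; outgroup-polarized for observed data) and Kelly's ZnS —
unweighted means, the standard choice in multilocus coalescent ABC. Loci
with undefined D or H contribute 0 and are counted in missingness flags, on
both the observed and simulated sides, so the two paths are exchangeable
(the test suite checks them against each other componentwise).

Rejection uses Euclidean distance on MAD-normalized summaries (zero-MAD
components are dropped with a warning) and keeps the `ceiling(p_delta x
rows)` closest rows; a pooled 9e5-row table at `P_delta = 0.001` keeps
exactly 900 points. Regression adjustment is the local-linear scheme:
weighted least squares of each log-transformed parameter on the centered
summaries with Epanechnikov weights at the acceptance radius, adjusted
draws back-transformed and clamped to the prior box; a singular design
falls back to unadjusted draws with a warning. Log transformation is used
for all parameters because all are strictly positive scale/time quantities.
Model choice fits a weighted multinomial logistic regression of the model
label on the normalized summaries within the accepted set and evaluates it
at the observation; plain rejection proportions are reported alongside as a
diagnostic. Posterior point estimates are kernel-density modes (Gaussian
kernel, Silverman's bandwidth) with weighted 2.5/97.5% quantiles;
posterior-predictive checks resample the posterior, re-simulate, and report
two-sided tail probabilities per summary.

Desk-scale defaults keep everything tractable on one CPU: reference tables
of 3e4 rows per model, 20 chromosomes, 10 loci of 600 bp. The validation
suite runs model recovery (datasets simulated under strong growth,
`N1_rel <= 0.05`, must select GROWTH in at least 70% of 50 trials),
95%-interval coverage of `N1_rel` (at least 90% of 20 trials), and
checks that posterior modes agree between `P_delta` 0.01 and 0.001 within
bootstrap Monte-Carlo error. The coverage study draws expansion times
across the range the growth posterior supports (`T0` in [1e-3, 2e-2]):
identifiability has a floor — an expansion more recent than `T0` of about
1e-3 leaves essentially no footprint in a 20-chromosome sample, the
likelihood goes flat in `N1_rel`, and the posterior reverts to the prior,
which then concentrates away from very small ancestral sizes. In that
regime no method could recover `N1_rel` from these summaries at this
sample size; interval coverage is a statement about the identifiable
regime. Full-scale runs (3e5–1e6 rows, 114
chromosomes, real locus lengths) use the same functions with larger
arguments.

Scaled estimates convert to natural units via `Ne = theta_ws/(4 mu g)`
(with `mu` the per-year mutation rate and `g` the generation time in
years), `years = T x 1e-3 x 4 Ne g` for times reported in 4N0-generation
units scaled by 1e-3, and `N1 = N1_rel x Ne` individuals. Report
generation rounds `Ne` to three significant figures before converting, the
reporting precision of such studies.

## Mismatch sudden-expansion test

cpSSR haplotypes are binary-coded per locus (repeat number `k` over the
observed range becomes `k - kmin` ones and `kmax - k` zeros), which makes
Hamming distance equal the summed absolute repeat difference — an identity
the test suite asserts on random tables. The observed mismatch distribution
is fitted by the sudden-expansion model with expected frequencies computed
from the exact closed form — the equilibrium geometric distribution at
`theta1` truncated by the expansion plus the `theta0` equilibrium convolved
with Poisson(`tau`) mutations — evaluated with `dpois`/`ppois` for
numerical stability. The fitter is a grid search over (`tau`, `theta0`)
with `theta1` tied to `1000 x theta0` (capped; the post-expansion size is
weakly identified, so it is fixed large by default and can be freed), plus
Nelder–Mead refinement in log space. Significance is a parametric
bootstrap: samples are simulated under the *fitted* model through the
coalescent engine (two-epoch trajectory in mutational units), each refit
with the same fitter, and `p_SSD = Pr(SSD_sim > SSD_obs)`; raggedness is
treated identically. The raggedness index pads the frequency vector with
zeros on both sides before summing squared successive differences, so a
point mass scores exactly 2 and a flat k-class vector `2/k^2`. Bootstrap
p-values are verified to be approximately uniform under the fitted model.

## The synthetic-data generator

Studies of this design rarely deposit their raw sequence data, so the
generator manufactures complete study-shaped datasets with known truth:
10 loci of 494–1252 bp totalling 8950 bp, roughly half coding, 57 diploid
individuals in 6 populations of sizes 9/13/12/3/10/10 across 3 regions at
realistic sampling coordinates within a 50-km span, an outgroup at 0.02 substitutions/site
(the order of magnitude for a split in the 14–27 My range at conifer
nuclear rates), and 7 cpSSR loci. The default sequence model is exponential
growth at posterior-mode parameter values representative of this system (`theta` 0.0299, `rho`
0.0424 per site, `N1_rel` 0.0318, `T0` 8.6e-4), which yields present-day
diversity in the observed range (`theta_w` about 0.001).

Population structure is induced after the panmictic coalescent rather than
inside it, because the ABC of this design treats the species as one unit
while the F-statistics do not. Within each population, chromosome `j` is a
copy of a uniformly chosen earlier chromosome with probability
`(j-1)/(beta + j - 1)` where `beta = (1 - phi)/phi` (a Hoppe urn), making
any two same-population chromosomes copies with probability exactly `phi`
and hence the expected `F_ST` equal the target (default 0.05). Each locus
draws its own urn — genealogies are independent across loci even though the
structure is shared — which is what keeps the realized multilocus `F_ST`
concentrated around the target (mean ~0.05 over seeds, single-seed spread
roughly 0.03–0.10: with ten low-diversity loci the estimator itself is that
noisy, as region-level estimates in such datasets show). Inside exons,
nonsynonymous mutations are retained with probability 1/4, producing the
~4:1 silent-to-nonsynonymous diversity ratio.

The cpSSR generator uses a post-expansion genealogy (`N1_rel` 0.05, growth
starting 0.8 units back) with `theta_ssr = 1.8`, calibrated once so that
per-locus allele counts land in {3, 4} for about 80% of simulated loci and
combined haplotype diversity averages ~0.91. Because all seven loci share
one genealogy, seed-to-seed variance in tree length caps how tightly allele
counts concentrate; roughly a fifth of simulated loci fall outside {3, 4}
under any calibration we scanned.

What the generator does *not* emulate: indels and alignment error,
recombination hotspots, selection at linked sites, mutation-rate variation
among loci beyond length differences, genotyping or phasing error, and any
spatial pattern beyond the single `F_ST` level (no isolation by distance is
built in). Passing tests therefore demonstrate correctness of the
statistical machinery under the stated models, not robustness to these
real-data complications.

## Reproducibility and problem sizes

Every stochastic function takes an explicit seed; the pipeline derives a
named substream per stage from one master seed, so stages rerun
independently and bit-identically. The validation suite runs at desk scale:
5000 replicates for simulator expectations, 400 per model for the msprime
cross-check, 1000 datasets for null calibrations, a 3e4-row-per-model
reference table with 50 selection and 20 coverage trials for ABC, and 200
runs of 100 bootstrap replicates for mismatch calibration — sizes chosen so
the whole suite completes in minutes on a single core while keeping
Monte-Carlo error well inside the asserted bands.

## A worked example

```{r example, eval = FALSE}
fx <- generate_sequence_study(seed = 1)
ssr <- generate_ssr_study(seed = 1, individuals = fx$popmap$assignments$individual)
cfg <- study_config(fx$loci, fx$popmap, ssr = ssr,
                    permutations = 1000, coalescent_reps = 1000,
                    mismatch_reps = 1000, abc_sims_per_model = 30000,
                    abc_n = 20, abc_L = rep(600L, 10), seed = 1)
res <- run_all(cfg)
cat(make_report(res), sep = "\n")
```

## Known limitations

The site-weighted difference classification approximates pathway counting
for multi-hit codons; the single-outgroup polarization cannot correct for
ancestral-state misidentification; the ARG is exact but slows at the upper
end of the `rho` prior, which bounds practical full-scale table sizes; the
mismatch bootstrap inherits the usual conservatism of double-fit parametric
bootstraps at very small `tau`; and the urn-based structure model produces
exchangeable populations, so it cannot represent hierarchical or clinal
structure beyond the region labels it carries.
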