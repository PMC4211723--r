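---
title: "Genotype-phenotype methods: heterozygosity-fitness correlations and migration-timing genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-phenotype methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hfcmig` implements a complete genotype-phenotype analysis chain for a wild
cervid population: microsatellite diversity statistics, pairwise relatedness,
matrix permutation tests linking relatedness to migration phenology,
Bayesian hierarchical regressions linking heterozygosity to body condition,
and GPS-track phenology extraction — together with a seeded synthetic-data
generator so the entire chain runs, and every claim is testable, without
field data. This vignette records the models, the defaults, and the design
choices that were genuinely open.

## The scientific questions

Two questions drive the chain. First, is migration timing heritable-ish at
fine scale: do related females migrate at similar times, and does the
mitochondrial haplogroup shift migration dates? Second, is body condition
(mass, percent ingesta-free fat — a fitness proxy in deer) correlated with
nuclear heterozygosity, either genome-wide (multilocus heterozygosity, MLH)
or at single loci (SLH), the classic heterozygosity-fitness-correlation
(HFC) framework?

## Diversity statistics

* **MLH / SLH.** SLH is the per-locus 0/1 heterozygosity indicator; MLH is
  the mean of an individual's non-missing SLH values. Missing calls (any of
  `0`, `000`, empty, `NA` on input) never enter the average: MLH
  renormalises per individual over typed loci, the field convention for
  panels with a few percent missing data.
* **Hardy-Weinberg.** A conditional exact test on the observed allele
  counts (Levene's distribution). All genotype arrays are enumerated when
  there are at most `1e5` of them; beyond that the test switches to
  Monte-Carlo re-pairings of the observed gene copies (`1e4` draws by
  default). The p-value is the probability mass of arrays no more probable
  than the observed one.
* **F_IS.** Weir & Cockerham (1984) within-population f, combining loci by
  summing the b and c variance components before forming the ratio —
  the default estimator of the standard tools in this field; the
  all-heterozygote limiting case (f = -1) is used as an exact test anchor.
* **g2 identity disequilibrium.** Whether MLH can proxy inbreeding at all
  depends on variance in inbreeding among individuals, measured by the g2
  statistic: the ratio of the typed-cell-weighted mean cross-locus product
  of heterozygosity indicators *within* individuals to the analogous
  *cross-individual* product, minus one (the covariance-ratio form of the
  David et al. 2007 multilocus estimator, with per-cell missingness
  weights). Zero means no inbreeding variance. Significance comes from
  permuting each locus's SLH column independently across individuals (1000
  permutations by default), which destroys among-locus covariance while
  preserving each locus's heterozygosity and missingness pattern;
  p = (1 + #{g2_perm >= g2_obs}) / (n_perm + 1).

## Relatedness

Pairwise relatedness uses the Queller & Goodnight (1989) coefficient with
reference allele frequencies from the full sample, the focal dyad included.
Per-locus numerators and denominators are summed before division (ratio of
sums), matching the multilocus behaviour of the standard implementations,
and the two directed estimates of a dyad are averaged. Both choices are
conventions, not universal standards, and are flagged as such here.
Dyads sharing no typed locus are NA; dyads sharing fewer than 5 loci are
flagged but retained. Because the estimator is centred on sample
frequencies, the mean off-diagonal r in an unstructured sample is ~0, and
parent-offspring / half-sib dyads have expectations 0.5 / 0.25 — the
package's pedigree-simulation tests check exactly these.

A deliberate non-goal: the simulated-annealing coancestry reconstruction
used as a second relatedness metric in some analyses is not reimplemented.
The Mantel machinery accepts any externally supplied square matrix in the
shared matrix-CSV format (ids in first row/column, NA diagonal), so such a
matrix can be plugged in.

## Mantel machinery

`mantel_r` is the Pearson correlation over the n(n-1)/2 unordered dyads,
excluding masked (NA) dyads pairwise. The permutation null jointly permutes
rows and columns of one matrix; the p-value is two-sided by |r|,
(1 + #{|r_perm| >= |r_obs|}) / (n_perm + 1), with 10000 permutations by
default. The partial test residualises both matrices element-wise on the
conditioning matrix (Smouse-Long-Sokal) and permutes the residualised
matrix; near-zero residual variance (collinear conditioning) is an error.

Confidence limits were an open design point: implementations differ in
how (or whether) they attach CLs to Mantel r. The package's convention is
an id-level bootstrap: resample individuals with replacement, take the
induced submatrix, drop dyads formed by two copies of the same individual,
recompute r; report percentile 2.5/97.5 bounds over 1000 draws. This
resamples the exchangeable units (animals, not dyads) and is documented as
the package's own convention — numerical agreement with other CL methods is
not expected.

## Bayesian regression suite

All models are fitted by Gibbs sampling in JAGS via `rjags`, the standard
engine for this model family. The contract is convergence-based rather than
mechanism-based: any run shape is fine provided split R-hat < 1.05 (and the
fit records effective sample sizes); defaults are 4 chains x 10000
iterations with 25% burn-in. Every fit is a pure function of (data, config,
seed): chains get seeded RNG streams, and summaries reproduce bit-identically.

* **Migration timing** (one record per animal): y_i ~ NegBin(mu_i, r),
  log mu_i = x_i'beta, on day counts corrected to the earliest migrant.
  Covariates: standardized age, winter-range dummies (NM reference),
  haplogroup dummies (haplogroup 1 reference).
* **Mass** (repeat captures): log(mass_ij) = x_ij'beta + b_i + eps_ij, with
  b_i ~ N(0, sigma_b^2) per individual, linear or quadratic standardized
  age, compared by DIC.
* **Fat**: fat_ij ~ Beta(mu_ij phi, (1-mu_ij) phi), logit mu_ij = x_ij'beta
  + b_i; covariates are the 17 SLH indicators, standardized age, a
  March-capture indicator, and winter-range dummies. Percent input is
  divided by 100; exact 0/1 values (none occur in simulation) would be
  pulled inside (0,1) by (y(n-1)+0.5)/n.

**Priors.** These are the package's own defaults, chosen weak at the scale
of the data rather than copied from any reference analysis:
beta ~ N(0, 10^2), NB dispersion r ~ Gamma(0.1, 0.1), beta precision phi ~
Gamma(0.1, 0.1), sigma_b and sigma_e ~ half-Cauchy(5). All are weak at the
scale of the data and configurable.

**Standardization.** Continuous age is standardized as (x - mean) / (2 SD)
so its coefficient is comparable with the binary covariates' (Gelman-Hill
convention). The population SD (denominator n) is used — the two-point case
{2, 6} maps to {-0.5, +0.5} — and the centering constants ride along as
attributes so the transform inverts exactly.

**Inference rule.** Effects are read from sign probabilities: a covariate is
"flagged" when at least 0.95 of the posterior lies on one side of 0. No
multiple-testing correction is applied (deliberately, matching the HFC
screening practice); instead the guard is the **shrinkage refit**: the same
likelihood refitted with independent N(0, sd^2) priors on all non-intercept
coefficients, with sd taken (under `"auto"`) as the SD of the original
fit's non-intercept median coefficients. Real effects survive the penalty;
borderline flags do not. The refit returns a before/after flag table.

**DIC.** DIC = mean deviance + pD with pD = var(deviance)/2, the single-run
variance form; the Spiegelhalter plug-in (mean deviance minus deviance at
posterior means) is also reported. A caution learned while building the
test suite: with a per-individual random intercept and a covariate constant
within individual (age here), the intercepts absorb the covariate's signal
and conditional-deviance DIC separates nested fixed-effect terms only
weakly and noisily — the variance-form pD can swing by tens of units at
modest chain lengths. The package therefore demonstrates DIC model
selection on fixed-effects designs, and DIC values for hierarchical fits
should be read as indicative, not decisive. (This mirrors the "slightly
better" language such comparisons usually earn in field studies.)

**Sampler detail.** Non-intercept covariates are centred internally before
sampling and the intercept draws are transformed back afterwards. This is a
pure reparameterisation — the reported posterior is that of the uncentred
design — but it decorrelates the intercept from the dummy covariates and
roughly doubles effective sample sizes per iteration for the fat model's 23
coefficients.

**Predicted day shift.** For the timing model,
exp(median intercept) - exp(median intercept + median coefficient) converts
a haplogroup coefficient into days at reference covariate values, rounded
to the nearest day; the unrounded value and the full posterior of the
difference are returned alongside.

## Migration phenology from GPS tracks

Migration is demarcated as travel between seasonal home ranges, each a
minimum convex polygon (MCP). Field demarcations of migration are often
partly manual GIS work, so the automated rule is a stated convention,
validated against synthetic ground truth:

* the origin MCP is the convex hull of fixes before the season window
  (spring: Mar 1 - Jul 15; fall: Sep 1 - Dec 15 — windows bracketing the
  field-observed ranges, configurable);
* initiation is the last fix inside the origin MCP after which no
  same-season fix re-enters it ("directed movement, without return" — a
  brief excursion that returns is not migration);
* termination is found in two passes: the first entry into the hull of the
  post-window fixes anchors the destination residency, the destination MCP
  is rebuilt from every fix from that entry onward, and termination is the
  first fix inside it with all later same-season fixes remaining inside.
  The second pass exists because a residency hull built from post-window
  fixes alone underestimates the range's scatter, and a single late outlier
  would otherwise defer the detected arrival by weeks;
* boundary fixes count as inside (the hull is inflated by a relative 1e-9
  before the point-in-polygon test); coordinates must be planar projected
  meters — nothing is reprojected;
* an animal whose track never permanently leaves the origin MCP is flagged
  resident and excluded from that season's analyses.

Range centroids (for the partial Mantel conditioning matrices) are mean fix
locations over the residency periods. Dates are Julian day-of-year
integers; extraction is insensitive to fix-rate thinning by a factor of 2
within +-1 day on smooth tracks, which covers the three collar schedules
(30 min / 60 min / 5 h).

## The synthetic-data generator

The generator's defaults *are* the study conditions; they are fixed once and
not tuned per analysis:

* 134 females, 17 microsatellite loci, 99% completeness, four winter-range
  groups of 30/30/44/30 (NM/NR/RG/SM), 2 mtDNA haplogroups at 60/40,
  ages uniform on 1-11;
* allele frequencies per locus from a flat Dirichlet over 8 alleles;
  genotypes by Mendelian transmission from founder gametes;
* 90% of each group arranged into full-sib families of 6 (shared dam,
  sire, matrilineal haplogroup) — these create the related dyads the Mantel
  tests need. The family density and the shared timing effect below were
  calibrated jointly so that the expected Mantel correlation between
  relatedness and |Δ fall days| is about -0.03, the order of magnitude a
  fine-scale field study reports; sparser structure leaves the expected r
  indistinguishable from its ~0.02 realization noise at n = 95, i.e. a
  generator that cannot exhibit the signal it plants;
* 20% of matings are full-sib matings, giving pedigree inbreeding f = 0.25
  to the offspring. The resulting variance in inbreeding is
  0.2 x 0.8 x 0.25^2 = 0.01, so the expected g2 is ~0.01 — weak identity
  disequilibrium, the regime the analysis is designed for (measured mean g2
  over 30 generator seeds: 0.011);
* capture records 102 December / 79 March with 47 animals captured twice;
  104 animals with spring and 95 with fall migration data;
* fall termination day counts are negative-binomial (dispersion 10) with
  log-mean intercept 2.932, age -0.095, range effects 0.1768/-0.270/-0.440,
  haplogroup-2 shift -0.350, plus the shared per-family N(0, 0.30^2)
  effect — field-reported posterior medians serve as the generator's truth,
  and the family effect produces the relatedness-timing covariance. Fall
  initiation is termination minus a short Poisson transit; spring
  initiation is an analogous count with no haplogroup shift;
* fat is beta-distributed (precision phi = 100, chosen so that fat with
  mean ~0.10 has SD ~0.03, the scale of field fat measurements) with logit
  mean: intercept -2.15, age -0.05, March -0.52, range effects
  -0.10/-0.11/-0.06, planted SLH effects -0.24 (locus `loc02`) and +0.18
  (locus `loc12`), all other loci exactly 0, and a per-individual N(0,
  0.15^2) intercept; mass is log-normal with a quadratic age effect;
* GPS tracks: residency is a small deterministic micro-movement ring
  (radius 100 m — collared animals are never literally stationary, and a
  hull needs extent) plus N(0, 50 m) GPS jitter; transit is linear from
  winter to summer centre (30 km) between noon of the true initiation and
  termination days; each animal gets one of the three collar schedules.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: genotyping error and null alleles; linkage
between loci; population structure beyond family clusters (no isolation by
distance); behavioural stopovers, reverse migration, collar gaps, or
fix-success dependence on habitat; environmental drivers of timing (snow,
plant phenology) — the family effect is a statistical stand-in for whatever
mixture of learning and genetics produces timing similarity among
relatives; and selection on condition. Recovery of a planted effect here
demonstrates the estimators and the inference rule, not the ecology.

## Problem sizes in the checks

The test suite and the acceptance script rerun the chain at the scale the
analyses themselves use: 134 animals / 181 records for the fat screen (50
and 20 replicates respectively), 95 animals for the timing models, 200
dyads per pedigree class for the relatedness oracle, 200 null replicates
for the type-I-error calibrations, and 30-40 synthetic tracks for the
phenology closed loop. Replicate fits use single short chains (1400
iterations, 400 burn-in); single-fit reports in the analysis scripts use
longer multi-chain runs. These sizes were chosen so the whole suite
completes in minutes while leaving the binomial noise of each calibration
check well inside its acceptance band.

A side effect of the family-dense default worth knowing: with ~20 large
full-sib families per population, some loci genuinely depart from
Hardy-Weinberg proportions in any given realization (the effective founder
pool per group is small), so an HWE screen on default synthetic data will
flag a few loci. A field population with diffuse kinship would look
cleaner; configs with `family_fraction = 0` restore clean HWE at the cost
of the relatedness-timing signal.

## Known limitations

* The g2 estimator is the covariance-ratio form with missingness weights;
  the estimator's specialised small-sample correction terms for very small
  microsatellite panels are not reproduced, which matters only for panels
  far smaller than 10 loci.
* Bootstrap CLs for Mantel r are a package convention (see above).
* DIC for hierarchical fits: see the caution under DIC.
* The MCP demarcation assumes a single directed transit per season; animals
  with multi-stage migrations would need the season windows adjusted.
* Sign-probability screening is exactly that — a screen; the shrinkage
  refit reduces, but does not eliminate, the false-positive risk inherent
  in 17 single-locus tests.
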