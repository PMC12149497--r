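---
title: "Feeding-pattern phenotypes and their genetic analysis: methods"
author: "feedAUC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feeding-pattern phenotypes and their genetic analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feedAUC)
```

# The phenotype

Automated roughage-intake feeders record every visit a cow makes: entry
and exit timestamps and the feed weight before and after, so each visit
yields an intake (kg as-fed) and a duration (s). Classical feeding
behaviour traits (visits per day, intake per visit, feeding rate) ignore
*when* during the day a cow eats. The phenotype implemented here
captures the within-day trajectory: for each cow-day, every visit's
intake is expressed as a proportion of that cow's daily total, the
proportions are accumulated over the day, and the resulting
non-decreasing curve — anchored at (0, 0) and (86,400 s, 1) — is
integrated by the trapezoid rule. The area under this curve (AUC, in
seconds) is high when intake is concentrated soon after fresh feed
delivery and low when it is deferred. A cow eating equal amounts at
equally spaced visits over 24 h has AUC exactly 43,200 s (half a day),
which the test suite asserts.

Time is measured from **Time 0**: the first feeder visit by any cow in
the pen after the lockout that precedes fresh feed delivery. With a
delivery schedule, `assignDayWindows()` takes the earliest entry at or
after the delivery clock time; without one, it infers Time 0 as the
visit ending the longest pen-wide silence inside a nominal delivery
window (default 10:00–12:00) — the lockout is the only interval in
which no cow can eat. Feeding days are half-open windows
`[time0, next time0)`; visits are assigned by entry time, and each
visit's curve abscissa is its **exit** offset, because the intake is
only realized (weighed) at exit. The integration horizon is fixed at
86,400 s regardless of the actual gap between consecutive Time 0
values, which keeps AUC values comparable across days and makes the
uniform construction exact.

Two per-cow phenotypes summarise the daily AUCs over the experimental
period: their arithmetic mean (the feeding-pattern phenotype) and the
natural log of their sample variance (n − 1 denominator), the
*consistency* phenotype log-Var-dAUC — logged because the genetic model
assumes Gaussian phenotypes and raw variances are strongly skewed.

## Cleaning rules and their boundaries

Visit level: intake must lie in (0, 20] kg and duration in [5, 3000] s.
The sources state the *removal* conditions ("≤ 0 or > 20", "< 5 or
> 3000"); we read the boundaries literally, so exactly 20 kg and
exactly 3000 s are retained. Day level: at least 5 visits and daily
intake in (12, 115] kg. Per cow, days whose AUC deviates more than 3.5
sample SDs from the cow's own mean AUC are removed in a **single
pass** (mean and SD computed once over all her days, not iterated).
Cows need `minDays` retained days (default 20, configurable; herds
recorded for several weeks motivate the default) and at least two days
for a defined variance; cows whose days are all identical are flagged
and excluded from the consistency analysis. Cleaning reports always
reconcile: records read = retained + removed, with removals attributed
to the first matching rule (intake before duration).

# Feed-efficiency traits

Secreted milk energy is computed weekly,
`MilkE = (0.0929 fat% + 0.0563 protein% + 0.0395 lactose%) × yield`,
then averaged per cow. Body weight series are completed by per-cow OLS
of BW on trial day; metabolic BW is the mean of daily BW^0.75 (the
literal "average BW^0.75", not mean BW raised to 0.75 — the difference
is below 0.1% at realistic within-cow variation, and the alternative is
a one-line change); ΔBW is the regression-line difference between trial
end and start, which is robust to measurement noise in the raw first
and last weights. Residual feed intake is the OLS residual of
`DMI ~ DIM class + lactation + cohort + b1 MilkE + b2 mBW + b3 ΔBW`
with reference-level coding and an explicit intercept; residuals are
invariant to the coding. The printed 16-day DIM classes
(50–66, …, 169–185, > 186) leave day 186 unassigned; we place it in the
top class. RFI by construction has mean zero and is orthogonal to all
regressors, which the tests assert.

# The genetic model

Heritabilities and genetic correlations come from a Bayesian animal
model: `y = Xb + u + e` with `u ~ N(0, A σ²a)` (bivariate:
`u ~ N(0, G0 ⊗ A)`, `e ~ N(0, R0 ⊗ I)`), where A is the numerator
relationship matrix of the pedigree traced five generations back from
the phenotyped cows. A is built by the tabular recursion, its sparse
inverse by Henderson's rules with exact inbreeding coefficients
(F = diag(A) − 1; founders 0), and the two constructions are verified
against each other (`A⁻¹A = I`) in property tests.

Priors: flat for fixed effects; scaled inverse chi-square for
single-trait variances with ν = −2 and scale 0 (flat on the variance
scale); and for the bivariate (co)variance matrices G0 and R0, inverse
Wishart with ν = dim + 2 = 4 degrees of freedom and prior scale equal
to half the phenotypic variance of each trait on the diagonal — about
one pseudo-observation per trait. The often-quoted "uninformative"
alternative (minimal degrees of freedom with a near-zero scale) is
deliberately **not** the default: its density has a spike at singular
G0 that a near-zero scale cannot penalise, and with a weakly identified
genetic variance (a low-heritability trait at moderate herd size) it
collapses that variance toward zero — in our checks the bivariate
posterior under such a prior sat at half the univariate flat-prior
estimate on identical data, stable across chain lengths, so the
distortion is the prior, not mixing. All hyperparameters are arguments.
RFI enters genetic models with an intercept only, since its phenotype
is already adjusted for lactation, DIM and cohort.

## Sampler design

The textbook Gibbs sampler for this model re-factorises the mixed-model
equations at every iteration because the variance ratio changes. We use
an exact reparameterisation instead: the breeding values of animals
without records are integrated out analytically (the marginal
covariance of the phenotyped animals' values is the corresponding
submatrix of A), and that submatrix is eigendecomposed **once** per
chain. In the rotated basis the genetic full conditionals factor into
independent scalar (univariate) or 2×2 (bivariate) normal draws, fixed
effects are drawn jointly from a small normal system, and the variance
draws are untouched (scaled inverse chi-square / inverse Wishart on the
usual quadratic forms). The posterior is identical to the sparse-MME
formulation; the cost per iteration drops to O(n·p), which is what
makes chains of 40,000+ iterations at ~1,200 animals run in well under
a minute. The sampler was validated against a two-dimensional
grid-integration oracle of the marginal posterior on a small herd
(posterior means agree to Monte Carlo error) and against the
generalized-least-squares solution for fixed effects at known
variances.

Chain defaults are 100,000 iterations, 20,000 burn-in, thinning 10 for
bivariate chains and none for univariate ones (thinning univariate
chains is optional). Posterior summaries report the mean, SD and the
90% highest-posterior-density interval (shortest sorted window);
heritability `σ²a/(σ²a+σ²e)` and genetic correlation
`g12/√(g11·g22)` are computed per retained sample and then summarised
(the alternative — ratios of posterior means — agrees to two decimals
in all runs we checked). Convergence diagnostics (Geweke,
Heidelberger–Welch, Gelman–Rubin across chains) are delegated to the
coda package behind `chainDiagnostics()`; our HPD implementation is
cross-checked against coda's.

# The synthetic-data generator

No public accession of the feeder data exists, so every downstream
stage is exercised on synthetic data whose defaults reproduce the
study conditions: twice-daily delivery (11:00, 17:00) with a 30-minute
lockout, ~31 visits and ~43.8 kg as-fed per cow-day, daily AUC targets
spanning roughly 48,700–66,100 s around a herd mean of 56,345 s, mean
DMI 24.8 kg, true-RFI SD 1.63 kg, and Table-scale variance components
as simulation truths.

Within-day visit times follow an exponential consumption intensity
anchored at each delivery: intensity `exp(−θ · a(t))` with `a(t)` the
time since the most recent delivery, zero inside lockouts. Positive θ
produces the post-delivery feeding peak; θ = 0 is uniform; negative θ
defers intake. θ is a *monotone earliness link*: the generator
bisects on θ until the **pipeline-computed** AUC of the final, emitted
visits (after rounding and overlap repair) matches the requested
target within ±200 s, erroring if the target is unattainable. Visit
intakes are a Dirichlet split of the daily total with dominant
post-delivery meals, floored and capped so every visit passes the
visit filters by construction; durations derive from a fixed eating
rate. The first visit of each day starts at the moment of delivery, so
the Time 0 the pipeline infers coincides with the delivery — a
deliberate anchor that keeps the round trip exact. Fault injection
(filter-violating visits) is opt-in and off by default. The generator
does not model pen social dominance, weather, diet composition, or the
within-day microstructure of real meal bouts beyond the
delivery-anchored peaks — passing round-trip tests therefore shows the
pipeline arithmetic is right, not that real cows behave like the
generator.

Breeding values descend a simulated pedigree: founders are multivariate
normal with the trait (co)variances, non-founders are parent averages
plus Mendelian-sampling deviations with variance
`0.5(1 − 0.5(F_s + F_d))·σ²a`, using exact tabular-method inbreeding,
so replicate covariances match `A σ²a` (verified against the 6-animal
tabular A). Phenotypes add drawn lactation/DIM-class/cohort effects
and Gaussian residuals, with optional residual correlation between
traits.

## Recovery-study designs

`simulateHeritabilityStudy()` and `simulateCorrelationStudy()` freeze
the herd designs used for parameter recovery: a demographically stable
five-generation herd under hierarchical mating with ten AI sires per
generation (paternal half-sib families of about twenty daughters) and
the females of generations 2–5 phenotyped — about 1,200 cows from 600
founders for single-trait studies and about 800 from 400 founders for
trait pairs. Phenotyping across generations mirrors a research herd
recorded over many years, keeps many founder lineages represented and
provides dam–daughter links, and the large half-sib families carry
most of the information about genetic (co)variances. In piloting,
narrower designs (phenotypes confined to the youngest generations of a
small founder base) let genetic drift dominate the realized genetic
variance, leaving the low-heritability consistency trait barely
identified at these herd sizes, while weak-family designs made the
genetic correlation far noisier; the design was settled by replicate
simulation before any reported run was fixed. Residual correlations
for the trait pairs are not reported; 0.3 (consistency × DMI) and −0.1
(AUC × milk energy) are fixed once as modest, sign-plausible values.
The default bivariate prior (degrees of freedom 4, heritability-1/3
scale split) was likewise chosen by replicate calibration: it is the
weakest of the candidate defaults whose recovery of known truths was
approximately unbiased for both high- and low-heritability traits. Problem sizes
for the shipped recovery runs are 40,000 iterations (8,000 burn-in)
univariate and 30,000 (6,000, thin 10) bivariate — at these sizes a
full recovery study runs in about a minute on one core, and posterior
means are indistinguishable from chains four times longer in our
checks.

# Numerical choices and edge cases

* Zero-variance traits simulate exact zeros (no jitter).
* Eigenvalues of the relationship submatrix are floored at 1e−8; the
  matrix is positive-definite in exact arithmetic.
* `trapezoidAUC()` rejects unordered offsets; duplicate offsets are
  legal (zero-width segments).
* Midnight rollover: a visit whose exit clock time precedes its entry
  clock time exits on the next calendar date.
* A pen-date with no visits after delivery yields a skipped window and
  a warning, not an error.
* Degenerate Gelman–Rubin input (identical chains) reports PSRF 1
  rather than coda's 0/0.
* All generators and samplers take explicit integer seeds; derived
  sub-seeds stay far below 2³¹.

# Known limitations

Single records per cow (no permanent-environment effect), at most two
traits per model, pedigree relationships only (no genomic matrix), and
complete-case bivariate analyses (cows missing one trait are dropped;
data augmentation is documented as future work, not implemented). The
visit-time model is a stand-in: real within-day microstructure (meal
bouts, social displacement) is richer than a two-peak exponential
intensity.
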