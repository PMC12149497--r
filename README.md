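# feedAUC

Feeding-pattern phenotyping and pedigree-based genetic analysis for
lactating dairy cows recorded by automated feeders.

Electronic roughage-intake feeders log every visit a cow makes — entry
and exit times and the feed weight before and after. `feedAUC` turns
those visit logs into a within-day *feeding-pattern* phenotype: each
visit's intake is expressed as a proportion of the cow's daily total,
the proportions are accumulated from the time of first fresh-feed
delivery (Time 0), and the cumulative curve, anchored at (0, 0) and
(86,400 s, 1), is integrated by the trapezoid rule. The area under the
curve (**AUC**, seconds) is high for cows that eat soon after delivery;
a perfectly uniform eater scores exactly 43,200 s. Per cow, the package
derives the mean daily AUC and its day-to-day consistency
(**log-Var-dAUC**, the natural log of the variance of daily AUC), plus
the standard feed-efficiency traits: dry matter intake (DMI), secreted
milk energy `MilkE = (0.0929 fat% + 0.0563 protein% + 0.0395 lactose%) × yield`,
metabolic body weight (mean BW^0.75), body-weight change, and residual
feed intake (RFI) — the residual of
`DMI = DIM + Lact + Cohort + b1·MilkE + b2·mBW + b3·ΔBW + e`.

Genetic parameters come from a Bayesian animal model
`y = Xb + u + e`, `u ~ N(0, A σ²a)` (two traits:
`u ~ N(0, G0 ⊗ A)`, `e ~ N(0, R0 ⊗ I)`), with A the numerator
relationship matrix traced five generations back, built by the tabular
method and inverted sparsely by Henderson's rules with inbreeding.
Univariate and bivariate Gibbs samplers return posterior means, SDs and
90% highest-posterior-density intervals for variance components,
heritabilities `h² = σ²a/(σ²a+σ²e)` and genetic correlations
`g12/√(g11·g22)`, with Geweke / Heidelberger–Welch / Gelman–Rubin
diagnostics via coda. A synthetic-data generator (pedigrees, breeding
values, calibrated feeder event streams, milk/BW/DMI records) makes the
whole pipeline testable without proprietary feeder data.

## Worked example

```r
library(feedAUC)

# a self-contained synthetic herd: visit log, pedigree, milk, BW, DMI
paths <- makeDemoData(tempfile("demo"), scale = "small", seed = 5)

visits <- readVisits(paths[["visits"]])
fv <- filterVisits(visits)                         # (0,20] kg, [5,3000] s
aw <- assignDayWindows(fv$visits)                  # Time 0 per pen-date
days <- dailyCurves(aw)                            # one AUC per cow-day
days <- filterDays(days)$days                      # >=5 visits, (12,115] kg
days <- removeOutlierDays(days)$days               # 3.5 SD rule
pheno <- summarizeCows(days, minDays = 4)
head(pheno, 3)
#>    cow_id n_days auc_mean  var_dauc log_var_dauc
#> 1 cow0001      8 59170.99  738541.2     13.51243
#> 2 cow0002      8 54358.10 2938941.5     14.89356
#> 3 cow0003      8 58825.33  984842.3     13.80024
```

Each row is one cow: `auc_mean` is her feeding-pattern phenotype in
seconds (59,171 ≈ cow0001 front-loads intake well beyond a uniform
eater's 43,200), and `log_var_dauc` her consistency — cow0001 is the
more repeatable eater of the first two. A single cow-day is easy to
inspect:

```r
cc <- cumulativeCurve(offsets = c(1800, 7200, 21600, 50000),
                      intakes = c(12, 10, 12, 9.8))
cc$auc
#> [1] 73170.78
```

Heritability on simulated data at the herd scale of the study system:

```r
st <- simulateHeritabilityStudy("auc", seed = 1)   # ~1,200 cows, 5 generations
ch <- gibbsUnivariate(st$y, st$X, st$ped, st$idx,
                      nIter = 40000, burnIn = 8000, seed = 8)
summarizeChain(ch)
#>   parameter         mean           sd    hpd_lower    hpd_upper
#> 1  sigma2_a 1.527087e+06 2.650621e+05 1.070267e+06 1.936408e+06
#> 2  sigma2_e 2.260643e+06 1.978666e+05 1.938928e+06 2.587786e+06
#> 3        h2 4.018830e-01 5.880061e-02 3.030970e-01 4.961700e-01
```

The posterior-mean heritability (0.40 here) recovers the generating
value 0.352 within about one posterior SD, and the 90%
highest-posterior-density interval covers it.

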