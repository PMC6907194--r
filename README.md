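# grmdim

Genomic prediction by GBLUP works from the genomic relationship matrix
(GRM), whose information content is bounded by the number of independent
chromosome segments, `Me ~ f(Ne, L)` (effective population size, genome
length in Morgan). The spectrum of the GRM is extremely uneven — a handful
of large eigenvalues explains a large share of the genomic variance — and
this has direct consequences for how prediction accuracy grows with data.
`grmdim` is an R package for studying those consequences by simulation:
it generates structured breeding populations with known true breeding
values (TBV), builds the GRM three ways, solves GBLUP, and quantifies
accuracy both as a realized correlation and through prediction error
variances (PEV). It is aimed at quantitative geneticists working on
genomic evaluation and at anyone who wants a self-contained, reproducible
testbed for reduced-rank genomic models.

## The model

Phenotypes follow the animal model

```
y = 1 mu + u + e,   var(u) = G sigma_u^2,   var(e) = I sigma_e^2
```

with `G = ZZ' / (2 sum_j p_j (1 - p_j))` (VanRaden), `Z` the allele
counts centered by twice the observed allele frequency. Three
relationship options enter Henderson's mixed-model equations:

* **standard** — `G + 0.01 I`, inverted densely;
* **eig** — the rank-`r` truncation `G_eig = U D_r U'` keeping the `r`
  largest eigenvalues, blended and inverted analytically;
* **apy** — the "algorithm for proven and young" sparse inverse, which
  only inverts a core block densely and treats noncore animals by
  recursion, `M_nn = diag{ g_ii - g_ic Gcc^-1 g_ci }`.

Validation uses (a) the realized accuracy `cor(GEBV, TBV)` on
unphenotyped last-generation animals and (b) PEV-based accuracy
`acc_i = sqrt(1 - PEV_i / (sigma_u^2 g_ii))`, converted to effective
genomic record counts `d_g = alpha acc^2/(1 - acc^2) - d_p`
(`alpha = sigma_e^2/sigma_u^2`) and to the population-level
approximation `sqrt(1 - alpha/(alpha + mean(d_g)))`. PEV can be computed
by direct inversion of the coefficient matrix or through the eigenbasis
of the training GRM; the two routes are algebraically identical at full
rank.

## Worked example

A small population (600 genotyped animals, 1500 SNPs, Ne ~ 39, L = 10
Morgan), simulated, fitted and validated:

```r
library(grmdim)

sc <- desk_scenario(n_genotyped = 600, n_snp = 1500, n_qtl = 150,
                    n_dams_per_gen = 150, hist_size_start = 200,
                    hist_size_bottleneck = 60, hist_size_end = 600,
                    n_hist_generations = 60, seed = 2024)
pop <- simulate_population(sc)
#> <sim_population> 2000 animals over 10 recent generations
#>   genotyped: 600 (400 training, 200 validation), markers: 1469 (31 dropped)
#>   h2 = 0.6, sigma_u2 = 22.52, sigma_e2 = 15.01, alpha = 0.6667

grm <- grm_eigen(build_grm(pop$genotypes))
variance_explained_profile(grm, c(0.10, 0.50, 0.90))
#>   threshold n_eigenvalues fraction_explained
#> 1       0.1             3              0.104
#> 2       0.5            37              0.502
#> 3       0.9           206              0.901
```

Three eigenvalues out of 600 already explain 10% of the genomic
variance. Fitting GBLUP with the standard blended GRM and validating on
the unphenotyped last generation:

```r
arch <- pop$architecture
fit <- gblup(training_phenotypes(pop), grm_inverse(grm, "standard"),
             sigma_u2 = arch$sigma_u2, sigma_e2 = arch$sigma_e2)
realized_accuracy(fit, pop)
#> 0.78

pev_population_accuracy(pop, grm)$accuracy
#> 0.765
```

The PEV-based population accuracy (computed on the training set only,
validation animals excluded from the equations) lands slightly below the
realized accuracy, as expected for this approximation. Sweeping GRM
options and thresholds over replicates is one call
(`run_study(study_design(...))`, plotted with `autoplot()`), and
`me_formulas(effective_size(10, 150), 10)` gives the classical segment
counts for comparison.

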