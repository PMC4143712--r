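# lbltvc

Haplotype association testing for **longitudinal binary traits** with
**age-varying effects**, for cohorts of unrelated individuals examined up
to four times (the motivating application is hypertension with smoking,
age and sex recorded at each examination).

For a block of SNPs (typically 5, chosen around single-SNP prescreen
anchors), the model treats phase as latent, expands each non-reference
haplotype's per-copy log-odds effect in a cubic B-spline over age,

    log θ(t) = β0 + Σ_h X_h Σ_l β_hl B_l(t) + βE X_E(t) + Σ_h βE,h X_Eh(t) + βs X_s,

and places double-exponential (Bayesian LASSO) shrinkage priors on all
regression coefficients except the intercept, with a shared intensity
under a Gamma(20, 20) hyperprior — the shrinkage is what makes effects of
*rare* haplotypes (frequency < 0.05) estimable without pooling them.
Diplotype probabilities follow a frequency model with an inbreeding
coefficient d (d = 0 is Hardy–Weinberg); starting frequencies come from a
Hardy–Weinberg EM fit. Estimation is by MCMC (compiled sampler: Gibbs for
latent diplotypes and the intensity, random-walk Metropolis elsewhere),
and inference is per-haplotype odds-ratio curves over an age grid with
95% credible intervals, a haplotype being significant where its interval
strictly excludes 1.

The package also contains the single-SNP logistic prescreen used to pick
5-SNP blocks, and a synthetic-data generator plus drivers that measure
type-I error and power of the whole pipeline.

See `vignettes/lbltvc-methods.Rmd` for the full model, priors, numerical
choices and limitations.

## Worked example

Simulate a cohort with the default study design — 250 individuals, 4
exams each, a 5-SNP block with 5 common and 2 rare haplotypes, the
causal common haplotype `GGTCC` following a late-onset odds-ratio curve
(protective in young adulthood, peak OR ≈ 2.5 at ages 65–70), and a
smoking-by-`GGTCC` interaction of log 2 — then fit:

```r
library(lbltvc)
sc  <- sim_scenario(n = 250)
dat <- simulate_dataset(sc, seed = 42)
cohort <- join_cohort(dat$genotypes, dat$phenotypes)
fit <- lbl_tvc(cohort, config = lbl_config(n_iter = 20000, burnin = 4000,
                                           thin = 8, seed = 1))
print(fit)
#> Time-varying haplotype association fit (logistic Bayesian LASSO)
#>   250 individuals, 1000 examination records
#>   7 haplotypes (reference ACGCC; 2 rare, frequency < 0.05)
#>   2000 stored posterior draws
#>   significant haplotypes (95% CI excludes OR = 1 at >= 1 grid age): GGTCC

or_curve(fit, "GGTCC")
#> OR(t) for haplotype GGTCC (posterior median and 95% credible bounds)
#>  age    or  mean  lower upper significant
#>   25 0.145 0.177 0.0329 0.486        TRUE
#>   ...
#>   55 1.580 1.620 1.0300 2.450        TRUE
#>   60 2.010 2.070 1.2600 3.250        TRUE
#>   65 2.230 2.310 1.3900 3.640        TRUE
#>   70 2.220 2.280 1.3900 3.560        TRUE
#>   ...
#>   95 0.818 0.891 0.1730 2.110       FALSE
```

The fitted curve recovers the generating one: protective and significant
below age 45, crossing 1 near 50, significantly harmful across ages
55–80 with a posterior-median peak OR of 2.2 at 65 (truth 2.52), and
indistinguishable from the null at the extreme ages where data are thin.
The interaction is recovered too (`summary(fit)$scalar_effects`):

```
         effect        or     lower    upper significant
        smoking 1.1387485 0.7374103 1.956348       FALSE
  smoking:GGTCC 2.1408979 1.1701666 4.036596        TRUE
```

`plot(fit)` draws the curve with dotted 95% bounds; `report_tables(fit,
"out/")` writes the age-grid OR table (15 rows per haplotype, ages 25–95
by 5), per-haplotype curve CSVs, plots and a run manifest. For real
data, start from `read_genotypes()` / `read_phenotypes()`, and use
`prescreen_snps()` + `select_anchors()` + `build_block()` to choose the
block. A thin CLI over the same functions lives in `inst/cli/lbltvc.R`
(`run`, `prescreen`, `simulate`, `power` subcommands).

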