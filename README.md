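# polyrisk

Quantitative tools for asking whether a panel of genetic markers is
actually useful for predicting disease — not just statistically
associated with it.

`polyrisk` is aimed at statistical geneticists and biostatisticians who
design or evaluate polygenic prediction panels. It models a disease trait
`D` with prior (prevalence) `K` and `n` susceptibility loci, each reduced
to a binary carrier state with predisposing-genotype frequency `g0` in
controls and relative risk `rr`. Under conditional independence given `D`
the model is Naive Bayes, and the posterior probability of disease (PPD)
for a multilocus profile is

    PPD = K * prod_i P(Gi | D=1) /
          [ K * prod_i P(Gi | D=1) + (1-K) * prod_i P(Gi | D=0) ]

The package computes, exactly:

* **PPD** for genotype profiles and the **exact population distribution**
  of PPD under parameterised architectures (binomial carrier-count
  arithmetic for exchangeable models; exact log-likelihood-ratio
  convolution, or a 4096-bin dynamic-programming grid, for heterogeneous
  ones), over a stated population (`marginal_independent`, `mixture`, or
  `control`);
* **actionability fractions** at clinical thresholds: C1 = P(PPD > τ_pos),
  C2 = P(PPD < τ_neg), with sweeps over relative risk, prior, and locus
  count;
* **prognostic-utility metrics**: exact and Mann–Whitney AUC, ROC curves,
  PPV/NPV and their average, net reclassification improvement, and the
  Kullback–Leibler divergence between posterior and prior (two labelled
  variants);
* **genetic risk scores** `GRS = sum_i w_i R_i`, quantile risk
  stratification, fold-risk ratios, and case-control intercept
  calibration to population prevalence;
* a **categorical Naive Bayes classifier** (binary or multi-class, missing
  genotypes allowed) with stratified k-fold cross-validation and
  one-vs-rest AUC;
* a **seeded cohort simulator** generating data with exactly the
  statistical structure the models assume.

See `vignettes/polyrisk-methods.Rmd` for the model, the numerical
choices, and what the simulator does and does not emulate.

## Worked example

A highly polygenic architecture — 1000 loci, predisposing-genotype
frequency 10% in controls, per-locus relative risk 1.45, disease
prevalence 20%:

```r
library(polyrisk)

m <- exchangeable_model(n = 1000, g0 = 0.10, rr = 1.45, prior = 0.20)
d <- ppd_distribution(m)
threshold_fractions(d, tau_pos = 0.95, tau_neg = 0.05)
#> <threshold_report> C1 [PPD>0.95]: 0.01279  C2 [PPD<0.05]: 0.8068  neither: 0.1804
```

Read: at this effect size the panel confidently *rules out* disease for
81% of the population (posterior below 0.05), but pushes only 1.3% above
the 0.95 rule-in threshold — ruling in from common variants of small
effect is hard even with 1000 of them. The divergence of posterior from
prior across the population:

```r
kl_divergence(d)          # population-expected Bernoulli KL
#> [1] 0.224911             # nats; 0 would mean the panel moves nobody
```

Risk stratification on a simulated case-control cohort under a moderate
20-locus architecture:

```r
m20 <- exchangeable_model(n = 20, g0 = 0.20, rr = 1.5, prior = 0.20)
co <- simulate_case_control(m20, n_case = 1000, n_control = 1000, seed = 42)
bins <- quantile_bins(grs(co$genotypes), q = 5)
bin_risk_ratios(bins, as.integer(co$labels == "case"))
#>   bin   n cases   risk     ratio
#> 1   1 400    36 0.0900  1.000000
#> 2   2 400   152 0.3800  4.222222
#> 3   3 400   200 0.5000  5.555556
#> 4   4 400   247 0.6175  6.861111
#> 5   5 400   365 0.9125 10.138889
```

The top GRS quintile carries about a 10-fold higher case frequency than
the bottom quintile in this (enriched, 1:1 case-control) sample.

## Command line

A thin subcommand front-end over the same functions is installed at
`system.file("cli", "polyrisk", package = "polyrisk")`:

```sh
polyrisk sweep-rr --n 1000 --g0 0.10 --prior 0.20 \
    --rr-min 1.02 --rr-max 1.80 --step 0.02 --out sweep.tsv
polyrisk ppd-density --n 500 --g0 0.05 --prior 0.20 --rr 2.0 --out density.tsv
```

Outputs are full-precision TSV with provenance comment lines; exit codes
distinguish usage errors (2), unreadable/malformed input (3), and
out-of-range parameters (4).

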