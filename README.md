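# scenabc

Coalescent scenario simulation and approximate Bayesian computation for
joint mtDNA + microsatellite data, plus avian tetrahedral color-space
analysis of reflectance spectra.

## What this is for

`scenabc` targets a common phylogeographic study design: several
geographically structured population groups (the motivating system is a
Mesoamerican cloud-forest hummingbird sampled in four mountain-range
groups, TMVB / SMO / SMS / CHIS, split by the Isthmus of Tehuantepec)
typed for a concatenated mitochondrial alignment and a panel of diploid
microsatellites, plus reflectance spectra of an ornamental plumage patch.
The package lets you:

1. compute the full battery of population-genetic summary statistics —
   haplotype and nucleotide diversity, Tajima's *D* and Fu's *Fs* with
   simulation p-values, mismatch distributions with sudden-expansion fits
   (SSD, Harpending's raggedness), hierarchical AMOVA with
   Φ-statistics and permutation tests, pairwise Weir–Cockerham θ and
   *N*<sub>ST</sub>, microsatellite diversity with rarefied allelic
   richness;
2. simulate the data backward in time under three competing divergence
   scenarios (two pure isolation-split orders and one isolation-with-
   admixture history) with HKY sequence mutation and a generalized
   stepwise model for microsatellites;
3. run ABC model choice (rejection + multinomial logistic regression on
   discriminant axes, with 95% CIs), local-linear parameter estimation,
   pseudo-observed-dataset (POD) Type I/II error rates, and
   posterior-predictive model checking on a PCA of the summary space;
4. place gorget reflectance spectra in avian tetrahedral color space
   (quantum catches, hue angles θ/φ, chroma `r_vec`, `r_max`,
   `r_achieved`) and measure color-volume overlap between groups via 3-D
   convex hulls;
5. generate fully synthetic, truth-annotated fixtures emulating the study
   layout, so the entire pipeline is testable offline.

The core inference is standard ABC: a reference table of
(scenario, parameters θ ~ prior, summary vector *S*) rows; rejection keeps
the δ fraction of rows closest to the observed vector in
MAD-standardized Euclidean distance; scenario posteriors come from a
weighted multinomial logistic regression evaluated at the observed point;
parameter posteriors from Beaumont-style weighted local-linear adjustment
on a logit transform to the prior range.

## Worked example

Generate a synthetic study (scenario Sc1 truth), compute its statistics,
and run scaled ABC model choice:

```r
library(scenabc)

truth <- c(N_TMVB = 2000, N_SMO = 2000, N_SMS = 2000, N_CHIS = 2000,
           N5 = 5000, N6 = 5000, N7 = 20000, t1 = 500, t2 = 20000,
           t3 = 40000, r = 0.5, mu_seq = 8e-8, mu_ms = 5e-3, P_gsm = 0.2)
fx <- make_popgen_fixture(scenario = "Sc1", params = truth, config = "small",
                          rng_seed = 42, outdir = tempfile(), n_msat = 4)
ds <- assemble_dataset(read_alignment(fx$files["fasta"]),
                       read_genepop(fx$files["genepop"])$genotypes,
                       fx$files["map"])
groups <- c("TMVB", "SMO", "SMS", "CHIS")

pairwise_differentiation(ds, "TMVB", "SMO")[c("phi_st_seq", "N_ST")]
#> $phi_st_seq
#> [1] 0.1011713
#> $N_ST
#> [1] 0.3164945
pairwise_differentiation(ds, "SMO", "SMS")[c("phi_st_seq", "N_ST")]
#> $phi_st_seq
#> [1] 1
#> $N_ST
#> [1] 1
```

Under the Sc1 truth (TMVB and SMO split only 500 generations ago, SMS
20000 generations ago) the sister pair TMVB–SMO is barely differentiated
(sequence Phi_ST 0.10, N_ST 0.32) while SMO–SMS is fixed (both 1.0) — the
pattern the ABC summary vector feeds on:

```r
tab <- build_reference_table(lapply(c("Sc1", "Sc2", "Sc3"), scenario_preset),
                             n_per_scenario = 800, prior = prior_spec(),
                             config = config_preset("small"), n_msat = 4,
                             rng_seed = 7)
mc <- model_choice(tab, summary_vector(ds, groups), delta = 0.05)
mc
#> ABC model choice (logistic, 120 accepted)
#>     direct logistic             ci95
#> Sc1 0.4489   0.9862 [0.9605, 1.0000]
#> Sc2 0.3048   0.0023 [0.0000, 0.0076]
#> Sc3 0.2463   0.0115 [0.0000, 0.0353]
selected_scenario(mc)
#> [1] "Sc1"
```

The model-choice table gives each scenario's posterior probability by
simple vote share (`direct`) and by logistic regression on discriminant
axes (`logistic`, with 95% CI); the generating scenario Sc1 is correctly
preferred.

Color-space example:

```r
sfx <- make_spectra_fixture(n_per_group = 10, rng_seed = 1,
                            outdir = tempfile())
specs <- read_spectra(sfx$files["spectra"])
cp <- spectrum_to_color(specs[[1]])
round(c(X = cp$X, Y = cp$Y, Z = cp$Z, r_achieved = cp$r_achieved), 4)
#>          X          Y          Z r_achieved 
#>     0.0864    -0.1642    -0.0124     0.6026 
```

A full run (statistics → reference table → model choice → estimation →
checks → color) is driven by one JSON config:

```r
run_full_analysis("run.json")
```

and a thin CLI wraps the same stages
(`inst/cli/scenabc run --config run.json`, `... stats`, `... refbuild`,
`... choose`, `... fixture`, `... color`).

## Layout

- `R/popdata.R` — FASTA / GenePop / map I/O, validated containers
- `R/tn93.R`, `R/sumstats-*.R` — distances and all summary statistics
- `R/rates.R`, `R/coalsim.R`, `R/reftable.R` — rate arithmetic,
  structured coalescent, mutation models, reference tables
- `R/abc.R` — rejection, model choice, estimation, PODs, model checking
- `R/colorspec.R` — spectra, tetrahedral color space, hull overlap
- `R/synthdata.R`, `R/pipeline.R` — fixtures and orchestration
- `tests/testthat/` — unit, property and acceptance suites with
  independent brute-force oracles
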