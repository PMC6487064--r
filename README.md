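# gfblupkit

Genomic and genomic-feature BLUP for multi-population prediction of dairy
traits.

## What it is for

Breeding programs predict genomic breeding values (GBVs) for traits that
are expensive to phenotype — milk fatty-acid composition being the model
case — from small national reference populations. Two remedies are
implemented here as a tested, reusable pipeline:

* **combined references**: pooling several related populations into one
  reference set, on the common post-QC SNPs;
* **genomic features (GFBLUP)**: giving chromosomes known to carry major
  QTL their own random effect, so their signal escapes genome-wide
  shrinkage.

The package covers the full path: SNP quality control per population,
VanRaden (method 1) genomic relationship matrices (whole-genome and
partitioned), average-information REML, mixed-model prediction for masked
validation animals, relationship-aware cross-validation with
heritability-scaled reliabilities, binwise linkage-disequilibrium
summaries, and a multi-population half-sib simulator so everything can be
exercised without external data.

## The model

Traditional GBLUP for cow *l* in parity *i*, herd *j* at *DIM_k* days in
milk:

    y_ijkl = mu + parity_i + herd_j + b1*DIM_k + b2*exp(-0.05*DIM_k) + g_l + e_ijkl

with g ~ N(0, G sigma_a^2), e ~ N(0, I sigma_e^2) and
G = (M - P)(M - P)' / (2 Σ p_j (1 - p_j)). GFBLUP splits g into one effect
per feature chromosome plus the rest of the genome,
g = Σ_f g_f, g_f ~ N(0, G_f sigma_f^2); heritability uses
sigma_total^2 = Σ_f sigma_f^2 and each feature's variance share is
sigma_f^2 / sigma_total^2 × 100. Prediction reliability is
cor(GBV, y_corrected)^2 / h^2, where corrected phenotypes subtract the
fixed-effect part of a single-population GBLUP fit.

## Worked example

```r
library(gfblupkit)

cfg <- sim_config(seed = 2026)          # 3 populations (250/200/500 cows),
d   <- simulate_dataset(cfg)            # 5 chromosomes x 600 SNPs,
print(d$geno)                           # features chr1-chr3 = 60% of variance
#> genotype_matrix: 950 individuals x 3000 SNPs; 5 chromosomes; 3 population(s); 0 missing entries

spec <- scenario_spec("combined_gfblup", target_population = "pop1",
                      feature_chromosomes = c("chr1", "chr2", "chr3"),
                      seed = 2026)
res <- run_scenario(spec, d$geno, d$phenotypes, n_val = 30, n_reps = 5)
print(res)
#> scenario_result: combined_gfblup | target pop1 | trait trait
#>   h2 = 0.341 | mean reliability = 0.133 over 5 replicates
print(res$variance_proportions)
#>   component  variance proportion_pct
#> 1      chr1 0.1585010       21.47921
#> 2      chr2 0.2119664       28.72455
#> 3      chr3 0.1180028       15.99111
#> 4      rest 0.2494574       33.80513
print(res$reliability)
#> reliability_report: 5 replicate(s); mean reliability 0.133; mean r 0.183 (MAD 0.105); mean slope 0.898
```

Reading the output: the three feature chromosomes were simulated to carry
30/20/10% of the genetic variance; REML attributes 21/29/16% to them on
this seed (the remainder to the rest of the genome) and estimates
h² = 0.34 against a target of 0.40. The validation reliability of 0.13 is
the squared GBV-phenotype correlation of the masked sire-group holdout
cows scaled by h²; the MAD line reports the replicate-to-replicate spread
of the correlations, and a regression slope near 1 means the predictions
are not over- or under-dispersed.

Lower-level entry points: `qc_filter()`, `intersect_common_snps()`,
`vanraden_grm()`, `feature_grms()`, `reml_fit()`, `blup_solve()`,
`make_validation_plan()`, `prediction_reliability()`, `pairwise_r2()`,
`binwise_mean_ld()`, `read_genotypes()` (PLINK text and VCF),
`write_plink()`. See the vignette in `vignettes/gfblupkit-methods.Rmd` for
the science and the design decisions.

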