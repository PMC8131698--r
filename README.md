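# clonarch

Clonal-architecture analysis for chronic myelomonocytic leukemia (CMML)
progression, for hematology genomics groups analyzing targeted / whole-exome
sequencing summaries of CMML and its transformation to secondary AML.

CMML splits by white blood cell count (WBC ≥ 13×10⁹/L) into proliferative
(pCMML) and dysplastic (dCMML) subtypes with different outcomes, and
progression is driven by expanding driver-mutation clones — especially
oncogenic RAS-pathway clones (*NRAS*, *KRAS*, *CBL*, *PTPN11*). The package
implements the statistical core of that analysis:

* **Somatic classification with a contaminated normal.** CD3⁺ "germline"
  fractions carry tumor cells, so somatic status is decided by a two-sided
  Fisher exact test on the tumor/normal allele-count table
  [[alt_T, ref_T], [alt_N, ref_N]], somatic iff p < 10⁻⁴ — plus read-support
  (≥5 reads, VAF ≥5%), population-frequency (ExAC-style AF ≤ 0.001),
  panel-of-normals, and COSMIC/effect-class driver-annotation filters.
* **Driver timing.** Across paired chronic-phase (CP) / transformation (LT)
  samples, drivers partition as 1d = CP∩LT (primary), 2d = LT\CP (gained),
  3d = CP\LT (eliminated subclones), with an exact binomial test for the
  eliminated-vs-progressive contrast.
* **VAF clonality.** Per-patient maximum RAS-pathway VAF, ROC against the
  subtype label (AUC = Mann–Whitney pair statistic), Youden-J optimal
  cutoffs, inclusive thresholding (clonal iff VAF ≥ cutoff), and exact
  Fisher / rank-sum phenotype associations.
* **Clone ordering from single colonies.** Containment partial order over
  colony genotype sets under the infinite-sites assumption, with conflict
  reporting and fishplot-ready prevalences.
* **Native survival statistics.** Kaplan–Meier (median = smallest t with
  S(t) ≤ 0.5), log-rank with hypergeometric variance, Cox partial likelihood
  (Breslow ties, Newton with step halving), and L1-regularized logistic
  regression (coordinate descent, cross-validated λ, odds ratios exp(β)).
* **ChIP-qPCR arithmetic.** Fold enrichment 2^−(Ct_IP − Ct_IgG) with
  replicate summaries (mean ± SEM).
* **A seeded synthetic-data generator** with complete ground truth —
  bimodal clonal/subclonal Beta VAF mixture (means 0.40 / 0.10), ~100×
  depth, tumor-in-normal contamination fraction ρ, WBC-defined subtypes,
  subtype-specific exponential survival — so every stage is testable
  without access-restricted patient data.

## Worked example

```r
library(clonarch)

cfg <- sim_config(seed = 42, n_patients = 300)
sim <- simulate_cohort(cfg)

# somatic classification against a 5%-contaminated normal
v <- simulate_tumor_normal_counts(cfg, sim$truth$variants$true_vaf,
                                  annotations = data.frame(gene = sim$truth$variants$gene))
run_filter_chain(v)
#> clonarch filter chain: 645 variants in, 571 somatic survivors
#>           stage n_in n_excluded
#>         support  645         13
#>          pop_af  632          0
#>             pon  632          0
#>  fisher_somatic  632         61

# VAF clonality: max RAS-pathway VAF vs the pCMML/dCMML label
roc_curve(cohort_pathway_vaf(sim$cohort), sim$cohort$subtype == "pCMML")
#> ROC: 81 positives vs 36 negatives; AUC = 0.8172; youden threshold = 0.303

# survival by subtype
logrank_test(sim$cohort$survival_time, sim$cohort$event, sim$cohort$subtype)
#> log-rank: chisq = 19.3582 on 1 df, p = 1.084e-05
#>  group observed  expected
#>  dCMML       87 118.67708
#>  pCMML      130  98.32292

# eliminated vs progressive subclones, counts 19 vs 38
eliminated_vs_progressive_test(19, 38)
#> [1] 0.008174052

# clone ordering from single-colony genotypes
col <- simulate_colonies(c("TET2", "SRSF2", "NRAS"), 60,
                         c(0.1, 0.3, 0.3, 0.3), seed = 46)
infer_clone_order(col$genotypes)
#> clone trajectory over 60 colonies (linear)
#>  clone parent       mutations n_mutations count prevalence
#>      1     NA              WT           0     6       0.10
#>      2      1            TET2           1    21       0.35
#>      3      2      TET2+SRSF2          2    18       0.30
#>      4      3 TET2+SRSF2+NRAS          3    15       0.25
```

The 13 support exclusions are subclonal variants dropping below 5 reads /
5% VAF at 100× depth; the 61 Fisher exclusions are mutations whose tumor
and contaminated-normal counts are statistically compatible. The ROC
threshold 0.303 is this cohort's Youden cutoff for calling a RAS-pathway
mutation clonal; the log-rank test recovers the planted survival
disadvantage of pCMML; the binomial p (0.0082, i.e. 0.01 at two decimals)
is the lower-tail probability that at most 19 of 57 drivers fall in
eliminated subclones under a fair-coin null.

An end-to-end run (simulate → filter → timing → clonality → colonies →
stats, with a digest manifest) is:

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "clonarch"),
             out_dir = "demo_run")
```

or from a shell, via the bundled thin CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "clonarch.R", package = "clonarch"))')" \
  run --config inst/extdata/demo_config.yaml --out-dir demo_run --seed 7
```

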