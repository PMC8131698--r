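---
title: "Clonal architecture analysis of CMML progression: methods and design"
author: "clonarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal architecture analysis of CMML progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonarch)
```

## Scope and rationale

Chronic myelomonocytic leukemia (CMML) splits into a proliferative subtype
(pCMML, white blood cell count ≥ 13×10⁹/L) and a dysplastic subtype (dCMML),
with markedly different outcomes. Progression to secondary AML is driven by
the expansion of mutant clones — notably oncogenic RAS-pathway clones — and
the questions a clonal-architecture analysis must answer are statistical:
which variants are somatic when the matched "normal" is itself contaminated
with tumor cells; which drivers are primary versus gained or lost at
transformation; at what allele frequency a RAS mutation behaves clonally;
and in what order mutations were acquired. `clonarch` implements each of
those steps as a tested, seeded, reusable component, together with a
synthetic-data generator that provides complete ground truth. Patient-level
sequencing data of this kind is access-restricted, so the package's
validation strategy is simulation against known truth plus the cohort-level
counts that published tables make reproducible.

## Somatic classification against a contaminated normal

CD3-positive cells used as germline reference in myeloid neoplasms carry a
tumor-cell admixture, so subtracting "normal" variants would erase true
somatic calls. The package instead models the decision as a contingency
test: for each variant, the 2×2 table of alt/ref read counts in tumor and
normal is scored with a two-sided Fisher exact test
(`fisher_somatic_test()`), and a variant is somatic when p < 10⁻⁴. The
two-sided p uses the minimum-likelihood convention — the sum over all tables
with the observed margins whose probability does not exceed the observed
table's — computed by direct hypergeometric enumeration. The paper trail for
sidedness is ambiguous in this field; two-sided is the conservative choice,
and the implementation is pinned against a factorial-enumeration oracle and
`stats::fisher.test` in the test suite.

Around that rule sits the standard filter chain (`run_filter_chain()`):

* **Read support.** Alternative alleles with fewer than 5 reads and/or a
  VAF below 5% are excluded. Both are read as strict inequalities, so the
  printed boundary values (exactly 5 reads, VAF exactly 0.05) pass.
* **Population frequency.** Polymorphisms with population allele frequency
  strictly above 0.001 are excluded. A missing frequency is treated as 0
  with a warning — silently dropping novel somatic variants would bias the
  chain, and the warning keeps the decision auditable.
* **Panel of normals.** Variants recurrent in a 50-sample PON are excluded.
  The membership threshold is a design choice: a variant fails at ≥ 2 PON
  hits, tolerating singletons as isolated artifacts; it is configurable.
* **Driver annotation.** A COSMIC report is required for putative drivers;
  in tumor suppressor genes the effect class must additionally be stop-gain,
  frameshift indel, splice-site, or probably damaging nonsynonymous.

Flags are monotone — a later stage never clears an earlier verdict — which
makes the chain idempotent; exclusions are attributed to the first failing
stage.

## Driver timing across paired samples

For a patient sampled at chronic phase (CP) and at leukemic transformation
(LT), drivers partition into primary drivers present at both timepoints
(1d = CP ∩ LT), secondary drivers gained at transformation (2d = LT \ CP),
and drivers lost at transformation, marking eliminated subclones
(3d = CP \ LT). `categorize_drivers()` applies these set identities; the
variant key is gene-level by default (matching how two-timepoint driver
tables are reported) with arbitrary key columns supported for
variant-resolution matching. The eliminated-vs-progressive contrast is an
exact binomial test with null proportion ½; the default is the lower tail
(`alternative = "less"`), which is the directional question — do eliminated
subclones carry *fewer* drivers? — and which reproduces the published
rounding of the 19-vs-38 contrast; the two-sided minimum-likelihood variant
is exposed alongside.

## VAF clonality and ROC thresholds

A heterozygous founding-clone mutation sits near VAF 0.5; subclonal events
sit lower. Per patient the score is the *maximum* VAF across the oncogenic
RAS pathway genes (NRAS, KRAS, CBL, PTPN11) — `max_pathway_vaf()` /
`cohort_pathway_vaf()` — and `roc_curve()` evaluates that score against the
pCMML/dCMML label. The AUC is the Mann–Whitney pair statistic with ties
counted ½, and the operating threshold maximizes Youden's J = TPR − FPR
(an accuracy criterion is also available), reporting the smallest score
achieving the maximum so the rule `vaf ≥ threshold` is inclusive — matching
the ≥ 0.3 (NRAS) and ≥ 0.19 (RAS pathway) conventions. Whether wild-type
patients enter the ROC at score 0 or are excluded is not standardized;
both modes are exposed (`wildtype_as_zero`), with exclusion as default.

## Clone ordering from single colonies

Single-colony Sanger genotypes give direct, if noisy, phylogenetic
information. Under the infinite-sites assumption (each mutation acquired
once, never lost), the colonies carrying a later mutation must be a subset
of those carrying an earlier one. `infer_clone_order()` builds that
containment partial order; identical colony sets merge into one acquisition
step (their order is unidentifiable), incomparable disjoint sets become
sibling branches, and incomparable *overlapping* sets — true infinite-sites
violations — are reported as conflicts rather than silently resolved. A
containment tolerance (default 0, strict) absorbs Sanger dropout when set
to, say, 0.05. Colonies are then assigned to the best-matching clone
genotype (ties resolved toward the ancestral clone) and per-clone
prevalences are emitted in fishplot-ready form.

## Native survival and association statistics

The survival layer is implemented natively and cross-checked in the test
suite against `survival` and `glmnet` as independent oracles:

* `km_estimate()` — product-limit estimator; the median is the smallest
  time with S(t) ≤ 0.5 (the JMP convention used in this field's clinical
  analyses), undefined when the curve never reaches 0.5.
* `logrank_test()` — observed-minus-expected with hypergeometric variance
  at each distinct event time; k-group version via the quadratic form over
  k−1 groups.
* `cox_fit()` — Newton maximization of the Breslow partial likelihood with
  step halving; convergence at gradient norm < 1e-8; separation is detected
  from diverging coefficients and surfaced as a warning. The score test at
  β = 0 is reported and equals the log-rank statistic for a single binary
  covariate — a consistency check the tests assert.
* `l1_logistic()` — coordinate descent on the IRLS quadratic approximation
  with an unpenalized intercept and internally standardized predictors;
  λ chosen by 10-fold cross-validated deviance with the one-standard-error
  rule (fold assignment seed-controlled); odds ratios are exp(β) of the
  selected coefficients. Event coding throughout: 1 = event, 0 = censored.

ChIP-qPCR arithmetic (`fold_enrichment()`) converts immunoprecipitation and
IgG-control Ct values to fold enrichment 2^−ΔCt difference; replicate Cts are
averaged per condition before the subtraction by default (standard
practice), with per-replicate folds available as an option.

## The synthetic-data generator

`sim_config()` fixes the generative conditions; the defaults are the study
conditions the generator emulates, chosen once:

* **VAF mixture.** Clonal Beta(mean 0.40, concentration 50) and subclonal
  Beta(mean 0.10, concentration 50), reproducing the bimodal RAS-pathway VAF
  spectrum; RAS-pathway mutations are clonal with probability 0.85 in pCMML
  and 0.15 in dCMML, while TET2/SRSF2/ASXL1-class drivers are predominantly
  clonal (0.95) in both subtypes.
* **Gene panel.** Per-subtype mutation probabilities follow the published
  cohort frequencies (NRAS 30% vs 8%, ASXL1 60% vs 42%, TET2 43% vs 54%,
  JAK2 12% vs 5%), with the remaining RAS genes set so the combined pathway
  frequency lands near 46% vs 25%.
* **Subtype and WBC.** A latent subtype (prior 0.5) selects a log-normal
  WBC (medians 30 and 8 ×10⁹/L, sdlog 0.4); the final label is re-derived
  from the defining WBC ≥ 13 rule, so labels are always rule-consistent and
  the lognormal tails provide realistic label noise.
* **Read counts.** Depth ~ Poisson(100), floored at 1. The "normal"
  compartment is a ρ-mixture of tumor and germline cells: somatic variants
  appear in the normal at allele fraction ρ·v, germline variants at v, and
  a per-base error ε (default 0.001) corrupts both. No quantitative
  contamination estimate exists for CD3⁺ normals, so the default ρ = 0.05
  and the benchmark range 0–0.3 are package choices.
* **Survival.** Exponential event times with independent exponential
  censoring (rate 0.01/month) — the simplest model under which KM, log-rank
  and Cox recovery can be verified. Hazards derive from the published
  medians: overall survival log(2)/23 vs log(2)/39.6 per month; AML-free
  survival log(2)/18 vs log(2)/32.
* **Two-timepoint transitions.** Per chronic-phase driver, loss probability
  0.05; per unmutated candidate gene, gain probability 0.10.
* **Colonies.** Colonies are drawn from the clone prevalences of a linear
  trajectory; dropout (default 0.02) flips present calls to absent.

Every generator derives its stream from the master seed with a fixed
per-stage offset, so each stage and the whole pipeline are reproducible
byte-for-byte; the seed is recorded in every output header and in the run
manifest.

What the generator does *not* emulate: copy-number alteration and cnLOH
(which distort VAF in real data), read-level artifacts (strand bias,
mapping error), branching clonal topologies in the colony simulator beyond
what sibling-branch inference handles, and non-proportional or
non-exponential hazards. Tests passing on this generator therefore validate
the *statistical logic* of each stage, not robustness to those real-data
complications.

## Numerical choices and degenerate inputs

Tie handling: minimum-likelihood two-sided p with a 1e-7 relative slack for
floating-point ties (Fisher and binomial); midranks in the rank-sum test
and in the AUC; Breslow for tied event times in Cox. Zero depth is a hard
error (VAF undefined), never NaN propagation. Empty inputs follow explicit
contracts: an empty variant set filters to an empty report; zero colonies
give an empty matrix; an all-wild-type colony matrix yields a single
ancestral clone at prevalence 1. The rank-sum test is exact for combined
n ≤ 20 without ties, and otherwise uses the normal approximation with
midrank tie correction; the all-tied zero-variance case returns p = 1.

## Problem sizes used in validation

The shipped validation suite simulates cohorts of 2,000 patients for
threshold-recovery checks (where the Youden cutoff is compared against the
numerically computed equal-density crossing of the two Beta components,
0.233), 500 paired profiles for timing recovery, 1,000 variants per
contamination level for classifier specificity, 5,000 null replicates for
log-rank type-I calibration, 1,000 subjects for Cox hazard-ratio recovery,
and linear trajectories up to 6 mutations with 50 colonies per clone for
clone-order recovery. These sizes give Monte-Carlo standard errors well
inside the asserted bands while keeping a full run in the order of a
minute.
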