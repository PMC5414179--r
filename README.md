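# regvar

Statistical workflows for characterising an allele-specific regulatory
variant in a GWAS risk region, written for analysts who need the
computational chain behind such a study as tested, reusable functions:

* **Fine-mapping** — single-SNP and conditional case-control association by
  the 1-df logistic **score test** of the log-additive genetic effect
  (`U = gᵀ(y − p̂)`, efficient variance after projection onto the
  covariates, `U²/V ~ χ²₁`), variant QC (MAF ≥ 0.01, INFO ≥ 0.5), linkage
  disequilibrium (`r² = D²/(p_A q_A p_B q_B)`, `D′ = |D|/D_max`) from phased
  haplotypes or by EM from unphased genotypes, and correlated-set
  extraction (`r² > 0.6`).
* **Label-swap binder calling** — allele-oriented `log2(C/G)` pulldown
  ratios, median-centred per run, flagged by 1.5-IQR Tukey fences, with a
  protein called allele-preferential only when it is an outlier in the same
  allele direction in **both** the forward and reverse label-swap runs.
* **qPCR arithmetic** — `2^−ΔΔCt` relative expression, allelic-discrimination
  ratios with genomic copy-number adjustment, per-allele knockdown with
  paired t contrasts, an exact two-sided Fisher test of siRNA specificity,
  ChIP-qPCR percent-input enrichment over a control antibody, and
  dual-luciferase reporter normalisation.
* **Telomere length** — relative `T/S = 2^−(Ct_T − Ct_S)` against a
  single-copy gene.
* **Synthetic data** — seeded generators for LD-structured haplotype pools
  with exact pairwise r² targets, logistic case-control phenotypes with
  retrospective ascertainment, paired label-swap pulldown intensities with
  planted binders, and long-format Ct tables from latent template amounts —
  so every analysis is testable against planted ground truth.

## Worked example

The numbered scripts under `analysis/` run the whole chain on simulated
data and write their tables under `results/`. The fine-mapping pass:

```sh
Rscript analysis/01_simulate_region.R
Rscript analysis/02_finemap.R
```

prints

```
haplotype pool: 512 distinct haplotypes over 9 variants
sampled 4000 cases / 4000 controls; index sample AF 0.189 (pool 0.19)
top variant index: p = 4.96e-08 (all nine members p < 1e-4: TRUE)
conditioning on index: remaining p range 0.27-0.90 -> signal collapses to one variant
8 variants at r2 > 0.6 with index: proxy1, proxy2, ..., proxy8
masked variant: single-SNP p = 0.2, conditional p = 1.6e-06
```

Reading: the nine-variant block is individually genome-wide strong, but
conditioning on the index variant leaves every proxy flat (p 0.27–0.90) —
one underlying signal. The masked-pair demonstration shows the opposite
pattern: a variant null in single-SNP analysis (p = 0.2) becomes strongly
significant (p = 1.6e-06) after conditioning on its LD partner with an
opposite-direction effect, the signature of a masked independent signal.

The assay-side scripts (`03_binder_calls.R`, `04_qpcr.R`,
`05_telomere.R`) print, among others:

```
called 5 C-preferential binders; 5/5 planted binders recovered, 0 false calls
knockdown C 61.4% vs G 51.1% (paired t p = 0.0106)
siRNA specificity Fisher p = 0.0113
ChIP enrichment at amp6: 3.5-fold over IgG (others 0.94-1.16)
MIAPaCa2 relative telomere length: scrambled 1.00, siRNA3 0.73, ZNF148_si 0.72, TERT_si 0.61
```

i.e. the binder caller recovers exactly the planted allele-preferential
proteins, the allelic-discrimination arithmetic resolves a ~10-point
difference in per-allele knockdown, the Fisher enumeration gives the exact
specificity p for 3/8 target hits vs 0/24 pooled controls, only the planted
amplicon shows ChIP enrichment, and sustained knockdown shortens relative
telomere length.

Interactive use mirrors the scripts:

```r
library(regvar)
pool <- make_risk_region_pool()                      # 9-variant block, MAF 0.19
dat  <- simulate_gwas(pool, 4000, 4000, or = c(index = 1.3),
                      cohort_multiplier = 2.5, seed = 1)
association_scan(dat$G, dat$phenotype)               # single-SNP scan
association_scan(dat$G, dat$phenotype, condition_on = "index")
ld_pair(dat$G, "index", "proxy1")                    # EM-based r2, D'
sirna_specificity_test(3, 8, 0, 24)                  # 0.0113
```

See `vignettes/regulatory-variant-workflows.Rmd` for the models,
conventions and numerical choices, and for what the simulations do and do
not establish.

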