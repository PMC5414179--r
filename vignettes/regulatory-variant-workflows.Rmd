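---
title: "Methods: fine-mapping and allele-specific assay statistics in regvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fine-mapping and allele-specific assay statistics in regvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regvar)
```

# What this package computes

Characterising a putative regulatory risk variant in a GWAS region takes a
chain of quantitative analyses: statistical dissection of the association
signal (fine-mapping with conditional analysis and linkage disequilibrium),
identification of proteins that bind one allele preferentially
(label-swap quantitative proteomics), and allele-resolved functional readouts
(qPCR expression and knockdown arithmetic, chromatin immunoprecipitation
enrichment, reporter assays, telomere-length quantification). `regvar`
implements each of these steps as a tested function, together with seeded
synthetic-data generators so that every step can be validated against
planted ground truth. The `analysis/` scripts walk the whole chain on
simulated data.

# Case-control association: the logistic score test

Association between an additively coded genotype $g \in \{0,1,2\}$ and a
binary phenotype $y$ is tested with the 1-df efficient score test of the
log-additive genetic effect. A logistic null model with covariates only is
fitted; with fitted probabilities $\hat p$ and weights
$w = \hat p(1-\hat p)$,

$$U = g^\top(y - \hat p), \qquad
  V = g^\top W g - g^\top W X\,(X^\top W X)^{-1} X^\top W g,$$

and $U^2/V \sim \chi^2_1$ under the null. $V$ is the variance of the
genotype's score after projection onto the covariate space, so conditioning
on another variant is exactly "append its genotype to the covariates";
`association_scan(..., condition_on = v)` is verified in the tests to equal
`score_test()` with `v` appended by hand. Effect sizes (log OR and SE) are
reported from the alternative-model fit, flagged unreliable under
separation; the score p-value does not depend on the alternative fit.

Numerical choices: the null fit uses iteratively reweighted least squares
(`stats::glm.fit`) with log-likelihood tolerance `1e-8` and at most 100
iterations, erroring on non-convergence; for an intercept-only null the
closed-form MLE $\hat p = \bar y$ is used directly. Missing genotypes are
dropped pairwise per test (the simulators emit hard calls; dosage handling
is out of scope). P-values are reported unadjusted: fine-mapping scans of a
single region conventionally report raw p-values, and any multiplicity
handling belongs to the caller.

Variant QC uses the standard post-imputation filters, MAF $\ge$ 0.01 and
imputation INFO $\ge$ 0.5, inclusive at the boundary (a variant at exactly
MAF 0.01 is kept, because exclusion rules are phrased as "below threshold").
Variants without an INFO score pass that criterion.

# Linkage disequilibrium

For two biallelic loci with minor-allele frequencies $p_A, p_B$ and
haplotype frequency $p_{AB}$, $D = p_{AB} - p_A p_B$,
$r^2 = D^2/(p_A q_A p_B q_B)$ and $D' = |D|/D_{\max}$ with
$D_{\max} = \min(p_A q_B, q_A p_B)$ for $D > 0$ and
$\min(p_A p_B, q_A q_B)$ otherwise; $r^2 \le D'$ always. With phased
haplotypes the four frequencies are counted directly. With unphased
genotypes they are estimated by EM (gene counting): the only ambiguous
genotype class is the double heterozygote, split between cis and trans
configurations in proportion to their current expected frequencies;
iteration starts from linkage equilibrium and stops when the log-likelihood
changes by less than `1e-10` (or at 1000 iterations).

**Phase uncertainty is a real information loss.** The EM estimate and
direct phased counting on the same sample differ by the realised cis/trans
split of the double heterozygotes, a mean-zero error of order
$1/\sqrt{n}$ — about 0.01 on $r^2$ at $n = 500$ under moderate LD, and
only ~0.0008 at $n = 10^5$. The tests assert exactly this behaviour
(agreement improving with $n$); near-exact agreement at small $n$ is
attainable only when LD is strong enough that double heterozygotes are
nearly all cis, and no tolerance tighter than the information loss can hold
in general.

# The synthetic GWAS generator

`make_haplotype_pool()` builds a population haplotype table with exact
marginal allele frequencies and exact pairwise $r^2$ targets. Each targeted
pair is solved in closed form, $D = r\sqrt{p_A q_A p_B q_B}$, and a target
is rejected as infeasible when the implied $D$ exceeds its frequency-
determined bounds. Multiple targets are composed by a conditional-
independence construction along the edges of the target graph, which must
therefore be a forest; pools are enumerated exhaustively (at most 16
variants). Construction error is exactly zero by design, so any discrepancy
seen downstream is sampling noise — a deliberate separation that makes the
convergence tests meaningful. `sample_genotypes()` draws two haplotypes per
individual; `simulate_case_control()` draws phenotypes from
$\mathrm{logit}\,P(y=1) = \beta_0 + \sum_j \log(\mathrm{OR}_j) g_j + Z\gamma$,
either over a cohort or with retrospective (case/control) subsampling from
a larger simulated cohort (default 20-fold, 2.5-fold in the balanced
presets where prevalence is ~50%). One seed governs one dataset: each
composite generator seeds the RNG once and draws all of its stages from
that single sequential stream, so replicate datasets at different seeds
share no random numbers.

The fine-mapping preset (`make_risk_region_pool()`) emulates a tight
risk block: an index variant of MAF 0.19 carrying a per-allele OR of 1.3,
with eight proxies arranged as a positionally ordered Markov chain at
per-step $r^2 = 0.98$ (marginal index-proxy $r^2$ from 0.98 down to ~0.85).
The chain, not a hub-and-spokes layout, is the first-order model of a
haplotype block: neighbouring variants remain mutually correlated even
after conditioning on the index, as they do in real blocks — which is what
makes the joint "all proxies collapse after conditioning" behaviour
realistic. The masking preset (`make_masked_pair_scenario()`) couples a
modest protective variant (OR 0.72) to a risk variant (OR 1.45) at
$r^2 = 0.5$ with positive $D$, so the marginal effect at the first variant
is attenuated toward zero while its conditional effect is intact — the
classical pattern of a variant that is null in single-SNP analysis and
significant after conditioning on the region's top SNP.

What the generator does *not* emulate: recombination maps or coalescent
genealogies (LD is imposed, not evolved), imputation dosage uncertainty
(hard calls only; INFO scores are carried as metadata, not modelled),
population stratification, and genotyping error. Passing tests therefore
demonstrate the statistics' correctness and calibration under clean
ascertainment, not robustness to those artefacts.

# Label-swap binder calling

Allele-preferential binders are called from a pair of pulldown runs in
which the isotope channel assigned to each allele bait is exchanged
(forward: heavy = C). Per run, ratios are $\log_2(I_C/I_G)$ in
allele-oriented coordinates, so positive always means C-preference; a
protein quantified in neither channel is dropped (logged), and a single
zero intensity is floored at half the run's smallest positive intensity —
protein-level tables from standard quantification software contain zeros,
and the floor keeps the ratio finite without inventing signal. Ratios are
then median-centred per run (the upstream normalisation is unstated in
typical reports; median-centring removes global channel bias and is
shift-invariant), and outliers are flagged by Tukey fences at
$k = 1.5$ IQR with quartiles by linear interpolation of order statistics
(position $(n-1)p + 1$, R's type-7 default — the convention matters for
proteins near a fence, so it is fixed and documented). Flags use strict
inequality: a value exactly on the fence, or any value when the IQR is
zero, is not an outlier.

The concordance rule does the statistical work: a protein is
C-preferential only if it is an upper outlier in *both* runs (lower in
both for G). Under independent per-run noise a single-run false-positive
rate $\alpha$ becomes $\approx \alpha^2$ concordantly, which the null
simulation confirms (< 1% of proteins called with nothing planted). With
the default planted effect (log2 effect 2.0, noise SD 0.3, 5 binders in
1005 proteins) recall and precision both exceed 0.9 across replicates.
The competitor condition is carried as run metadata so analyses can be
partitioned by competitor.

# qPCR arithmetic

All quantification assumes perfectly efficient amplification (one doubling
per cycle), the model under which TaqMan-style relative quantification
$2^{-\Delta\Delta Ct}$ is exact; efficiency calibration by standard curves
is out of scope and documented as a limitation. Replicate Cts are averaged
within a group *before* differencing (rather than differencing per
replicate and averaging after); the choice is arbitrary for balanced
designs, is stated because it affects SEMs, and SEMs are propagated from
replicate Ct variances by the delta method
($SE(2^{-x}) = 2^{-x}\ln 2\, SE(x)$).

* **Relative expression**: $\Delta Ct = \overline{Ct}_\text{target} -
  \overline{Ct}_\text{reference}$, $\Delta\Delta Ct$ against the calibrator
  condition within the same sample, fold $= 2^{-\Delta\Delta Ct}$. A shared
  per-sample Ct offset cancels exactly.
* **Allelic expression**: C/G ratio $= 2^{-(\overline{Ct}_C -
  \overline{Ct}_G)}$ on cDNA; the reference-gene terms cancel within a
  sample but reference wells are required, keeping ratios comparable
  across samples.
* **Copy-number adjustment**: the cDNA ratio divided by the same assay's
  ratio on genomic DNA, removing allelic imbalance of the genome itself so
  the residual reflects per-copy regulatory preference.
* **Per-allele knockdown**: per replicate and allele,
  $100(1 - 2^{-(\Delta Ct_\text{treated} - \Delta Ct_\text{scrambled})})$,
  with the two alleles compared by a two-sided t test on replicate
  knockdown values — paired by replicate by default (replicates are
  independent experiments measuring both alleles together), Welch
  otherwise; the mode is recorded in the output. If all paired differences
  are identical the t statistic is degenerate: the p-value is reported as 1
  for a zero difference and 0 otherwise, with an explicit note, rather
  than erroring as `t.test()` would.
* **siRNA specificity**: a two-sided Fisher exact test by full
  hypergeometric enumeration, summing the probabilities of all tables with
  the same margins that are no more probable than the observed one. With
  the three control genes pooled (8 siRNAs × 3 genes = 24 trials), 3/8
  target hits against 0/24 gives p = 0.0113 — pooling, not a per-gene 0/8
  comparison, is the reading consistent with that printed value.
* **ChIP enrichment**: percent input
  $= 100 \cdot 2^{-(Ct_\text{antibody} - Ct_\text{input,adj})}$ with the
  input Ct adjusted for its dilution fraction
  ($Ct_\text{adj} = Ct_\text{input} + \log_2 d$; $d = 1$ by default since
  the dilution is a lab-specific constant), and enrichment is the
  IP-to-control-antibody ratio of percent inputs. Allelic ChIP contrasts
  use a paired two-sided t test on input-normalised replicate signals and
  report the C/G fold of means.
* **Reporter assays**: per-well firefly/renilla, normalised to the mean
  ratio of the empty-vector wells; C-vs-G contrasts per insert orientation
  by Welch t test on replicate activities.
* **Telomere length**: $T/S = 2^{-(\overline{Ct}_T - \overline{Ct}_S)}$
  against a single-copy gene, relative to the calibrator condition within
  each sample. The monochrome relative form is implemented; absolute
  calibration against standard curves is out of scope.

The Ct generator draws
$Ct = \text{offset} - \log_2(\text{amount}) + N(0,\sigma)$ per replicate
from latent template amounts, with design helpers for expression,
allelic-discrimination (cDNA split by expression ratio, gDNA split by copy
ratio), and telomere plates. It does not model plate-position effects,
inhibitors, or efficiency below 2 — recovery results bound what arithmetic
and replicate averaging can do, not instrument artefacts.

# Problem sizes and tolerances used in validation

The validation suite uses: 5000 null replicates at $n = 1000$ for type-I
error (accepting [0.04, 0.06] at $\alpha = 0.05$) and KS uniformity at the
1% level; 100 replicates of the 9-variant block at 4000 cases + 4000
controls for the conditional-collapse property; 100 replicates of the
masking preset; 50 replicates of the binder-recovery and null-suppression
settings; and 100 simulations per qPCR recovery at noise SD 0.1 with
triplicates (recoveries within 10%). Score-test p-values are checked
against a 20,000-draw permutation oracle with a mid-p convention (the
score statistic is lattice-valued) and an allowance of half a percent for
the $O(1/n)$ asymptotic-versus-exact gap that no number of permutation
draws removes. The conditional-collapse joint rates sit near 0.96–0.97 at
these settings, so individual 100-replicate runs can fluctuate by a few
percent around them.

# Known limitations

Individual-level conditioning only (no summary-statistic approximation);
no meta-analysis, imputation, or stratification correction — principal
components are accepted only as user-supplied covariates. The binder
caller applies no shrinkage or moderation across proteins and consumes
protein-level intensities as given. LD target graphs must be forests;
pools are exhaustively enumerated. qPCR assumes doubling-per-cycle
efficiency throughout. The degenerate zero-variance t convention (p of
exactly 0 or 1) is a reporting convention for noiseless fixtures, not an
inferential claim.
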