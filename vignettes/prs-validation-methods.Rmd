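---
title: "Methods: validating a polygenic risk score in an admixed case-control cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating a polygenic risk score in an admixed case-control cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`admixprs` packages the statistical machinery for asking whether a
breast-cancer polygenic risk score (PRS), typically trained in
European-ancestry populations, stratifies risk in an admixed cohort. This
vignette is the package's own account of the models it fits, the defaults
it ships, and what its verification does and does not demonstrate.

## The scoring model

A PRS file defines variants, an effect allele per variant, and a weight
$\beta_i$ on the log-odds scale. Given effect-allele dosages
$d_{ij} \in [0, 2]$, the raw score of sample $j$ is
$S_j = \sum_i \beta_i d_{ij}$. Two transformations follow:

1. **Zero-to-one normalization.** $S_j$ is rescaled by its diploid
   extrema, $S^{norm}_j = (S_j - 2\sum_{\beta_i<0}\beta_i) /
   (2\sum_{\beta_i>0}\beta_i - 2\sum_{\beta_i<0}\beta_i)$. The bounds are
   attained exactly by the two boundary genotype configurations (dosage 2
   at every positive-weight variant and 0 at every negative-weight one,
   and vice versa), which is the only min–max reading that forces the
   range $[0, 1]$; the package adopts it and tests it as a contract.
2. **Control standardization.** $z_j = (S^{norm}_j - \hat\mu_{ctrl}) /
   \hat\sigma_{ctrl}$, so that effect sizes read as odds ratios per
   control SD.

Orientation against the VCF is resolved per variant: the effect allele is
either the ALT (dosage used as-is) or the REF (dosage $2 - d^{alt}$);
incompatible allele pairs are excluded as mismatches rather than guessed.
A/T and C/G pairs cannot be oriented across strands and are excluded by
default (`include_ambiguous = FALSE`), the conservative convention for
transferred scores.

**Missing-dosage policy.** A missing genotype is imputed as twice the
cohort effect-allele frequency. This keeps the normalization denominator
sample-independent — per-sample renormalization would make scores
incomparable across samples — at the cost of slightly shrinking extreme
scores of samples with much missingness.

**Pre-scoring filters** (defaults): zero-weight variants always drop;
variants farther than `max_distance_bp = 200` from any capture-target
interval drop (imputation quality decays off target; the threshold is a
configuration value, as sensible values depend on the capture kit);
cohort MAF below `maf_min = 0.001` drops; and an explicit exclusion list
handles variants whose monogenic effect would be double-counted (the
moderate-penetrance *CHEK2* missense variant is the canonical example).
Dosages are clamped to $[0, 2]$ after arithmetic as a guard against
malformed DS fields.

## Cohort quality control

**Relatedness.** First-degree pairs (parent–offspring, full siblings)
form a graph. An isolated pair loses one member, chosen by a seeded
random draw; any connected component in which some member has two or more
first-degree links is removed entirely. We read "two or more
relationships" at the component level — the most literal reading — and
isolate it in `prune_related()` so an alternative policy is a one-function
change. When the kinship table carries coefficients instead of degrees,
first degree is the standard KING-style band $[0.177, 0.354]$. The rule
is idempotent, and the number removed from $k$ isolated pairs is exactly
$k$ regardless of seed; both properties are tested.

**Carriers.** Samples flagged as pathogenic/likely-pathogenic carriers in
the high-penetrance genes (*BRCA1*, *BRCA2*, *TP53*, *PALB2*, *PTEN*;
carrier OR > 5) are excluded before any score statistic. Moderate-risk
genes (*ATM*, *CHEK2*) are deliberately retained — their carriers are the
comparison group for the top-decile-versus-gene contrasts.

**Ledger.** Every removal stage records ids; the ledger refuses
overlapping removal sets and enforces
`final = initial − Σ removals`. Published cohort tables do not always
reconcile internally (rounding, post-hoc sex filters, samples lacking
ancestry estimates are common causes); the package's position is to
enforce strict arithmetic on its own accounting and surface any imported
inconsistency rather than emulate it.

**Ancestry groups.** With admixture proportions $(q_{EUR}, q_{AFR},
q_{EAS}, q_{AMR})$ summing to 1, a sample is EAS-majority if
$q_{EAS} > 0.5$, else Non-European-majority if $q_{EUR} \le 0.5$
(right-closed at 50%), else European-majority. The EAS rule takes
precedence and never conflicts with the EUR rule ($q_{EAS} > 0.5
\Rightarrow q_{EUR} < 0.5$). Ancestry rows summing to $1 \pm 0.02$ are
renormalized (upstream estimates are rounded); rows outside the band are
rejected as corrupt.

## Covariates

Population structure is adjusted with the top 10 genotype principal
components: variants at cohort MAF > 1%, deduplicated, mean-imputed,
centered at $2\hat p$ and scaled by $\sqrt{2\hat p(1-\hat p)}$, then a
truncated SVD. Each component's sign is fixed so its largest-magnitude
loading is positive (SVD signs are arbitrary; determinism matters for
reproducible runs), and components are z-scored before entering models.
The package computes PCs within the cohort rather than projecting onto
external reference panels; the downstream use of the PCs — ten z-scored
covariates — is identical, but the axes themselves are cohort-specific
and not comparable across studies.

## Association statistics

* **OR per SD**: maximum-likelihood logistic regression of status on $z$
  plus PCs 1–10; Wald 95% CI and two-tailed p; Nagelkerke (headline) and
  McFadden pseudo-R² against the intercept-only model. Separation or
  non-convergence aborts with a diagnostic rather than returning a
  meaningless estimate.
* **Bins**: deciles (boundaries at the 10–90% quantiles) or the reporting
  percentile scheme with edges 0, 1, 5, 10, 20, 40, 60, 80, 90, 95, 99,
  100. Intervals are left-open right-closed; a score exactly at a
  boundary falls in the lower bin; heavy ties may make bins unequal but
  the partition stays exhaustive. Boundaries come from controls by
  default — consistent with control-standardization and the PRS-reporting
  convention — with an all-samples option, since either choice is
  defensible.
* **Bin OR**: the target bin plus the 40–60% reference interval are
  retained, membership is binarized, and the same PC-adjusted logistic
  model is fitted. Without covariates this equals the closed-form 2×2
  odds ratio (tested to $10^{-8}$); the reference-versus-itself contrast
  returns OR 1 exactly, flagged as a self-comparison.
* **2×2 carrier ORs**: $(ad)/(bc)$ with Wald CI
  $\exp(\ln OR \pm 1.96\sqrt{1/a + 1/b + 1/c + 1/d})$. A zero cell gets
  the Haldane–Anscombe +0.5 correction and an explicit flag instead of a
  failure: strata of tens of samples are routine in 1% tails and for rare
  carriers.
* **AUC**: the rank statistic, on a stratified 25% holdout and by
  stratified 10-fold cross-validation. Since the score needs no
  training, a fold's AUC is the score's AUC within the held-out fold;
  the split protocol exists to mirror how such analyses are reported and
  to keep evaluation sets comparable across scores.
* **Multiplicity**: Bonferroni, $\min(1, mp)$, with $m$ the size of the
  score-by-group family in the run.

## The simulator and what passing tests mean

`simulate_cohort()` draws, under one seed: admixture proportions
$q \sim \text{Dirichlet}(\alpha)$ with default
$\alpha = (2.5, 0.2, 0.05, 0.25)$ for (EUR, AFR, EAS, AMR) — giving the
European-majority skew of the motivating setting, median $q_{EUR}$ near
0.84 with SD near 0.18; per-ancestry allele frequencies from a
Balding–Nichols model around a shared ancestral frequency
($F_{ST} = 0.1$ by default); genotypes
$g_{ij} \sim \text{Binomial}(2, q_j^\top p_i)$, i.e. Hardy–Weinberg at
each individual's mixed frequency; Gaussian effect weights with
randomized effect-allele orientation (so allele matching is exercised,
not bypassed); rare carrier flags per gene with odds ratios spanning the
moderate-to-high-penetrance range (defaults 2.1–14, frequencies
0.05–0.5%); and status from
$P(\text{case}) = \text{expit}(\alpha_0 + \gamma z + \sum_g c_g \ln OR_g)$
with $\gamma = \ln 1.43$ and $\alpha_0$ solved by root-finding for the
target prevalence (default 0.1, a lifetime-risk scale for breast cancer).
Case-control sampling happens after the population draw, which leaves the
logistic slope consistent (outcome-dependent sampling shifts only the
intercept). Families are two founders plus Mendelian-sampled offspring;
imputation noise replaces each genotype with probability $\varepsilon$ by
a fresh draw at the individual's own allele frequency, and
$\varepsilon$ can be calibrated by bisection to a target score-level
Spearman $\rho$ (default 0.74). The replacement mask and redraws are
generated once and thresholded, making $\rho(\varepsilon)$ monotone and
the bisection well-posed.

Deliberately **not** simulated: linkage disequilibrium (every statistic
in scope consumes dosages, and is LD-agnostic given them), genotyping
batch effects, age structure, and subtype heterogeneity. Passing tests
therefore demonstrate that the estimators recover known parameters under
a correctly specified liability model with independent variants — they do
not certify portability of any particular published score to any
particular population, which is exactly the empirical question a real
validation answers with real data.

## Verification design and problem sizes

Statistical calibration checks (CI coverage, AUC oracle, decile
staircase) run on the score-level generator
(`simulate_liability_scores()`), which draws $(z, \text{status})$
directly: the statistics under test consume only those two columns, so
genotype simulation would add runtime without adding evidence. The
genotype-level path is verified separately (orientation-randomized
scoring against a per-sample explicit-loop oracle at $10^{-10}$;
parameter recovery through the full simulate → QC → score → PCA →
regression pipeline). Sizes used by the test suite and acceptance
script, chosen to put Monte-Carlo error well inside each tolerance:

* CI coverage and bias: 200 cohorts of 3,000 cases / 4,500 controls at
  prevalence 0.05; coverage expected in 93–97%, bias below 0.02 on the
  log-OR scale.
* Binormal AUC oracle: a 200,000-person population at prevalence 0.05
  with a 25% stratified holdout, i.e. 50,000 evaluated samples
  (AUC standard error ≈ 0.005 against a ±0.01 band). The model's exact
  AUC by numeric integration, 0.5995, agrees with the binormal closed
  form $\Phi(\ln 1.43 / \sqrt 2) \approx 0.5998$ at this prevalence.
* Staircase monotonicity: 200 cohorts of 1,000 / 1,500; Spearman trend
  across non-reference decile ORs positive in ≥ 95%.
* Noise calibration: 3,000 samples × 500 variants; achieved $\rho$
  within ±0.03 of the 0.74 target.

## Known limitations

Exact-position, exact-allele matching only (no liftover, no proxy
variants); within-cohort PCs rather than reference-panel projection;
Wald inference throughout (profile-likelihood CIs would differ in tiny
strata — there the Haldane-corrected 2×2 is flagged); no ER-subtype or
gene–environment analyses; and the simulator's independence assumptions
above. The decile-boundary source (controls versus all samples) and the
pseudo-R² variant are reporting choices on which published analyses are
often silent; both options are implemented and the defaults documented
here.
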