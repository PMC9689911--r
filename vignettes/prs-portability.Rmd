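---
title: "Methods: cross-population risk scores from catalog associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-population risk scores from catalog associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(prscape)
```

## The problem

Disease risk variants are mostly discovered in one ancestry and then applied
to others. Because allele frequencies drift apart between populations, a
fixed set of risk variants implies different *expected* genetic burdens in
different populations, and one can ask (a) which individual variants are
strongly enriched or depleted in which population, and (b) whether the
population-level expected burden lines up with population-level disease
rates. prscape implements that workflow for catalog-reported risk SNPs:
harmonize the associations into a weighted risk model, measure per-population
effect-allele frequencies, score enrichment with a signed exact-test
statistic, compute a normalized polygenic risk score (PRS), and regress
population rates on it. Prostate cancer — where age-adjusted incidence
differs several-fold between African and East Asian ancestry men — is the
motivating use case, but nothing in the package is specific to it.

## Risk-model harmonization

Catalog association files report one row per (study, SNP) with a risk allele
string like `rs10486567-G` and an effect size that may be an odds ratio or a
log-scale beta. `harmonize_risk_model()` reduces this to one entry per SNP:

* **Weight.** `beta_i` is the arithmetic mean of the SNP's odds ratios
  across studies. Betas are mapped onto the OR scale as `exp(beta)` (for the
  logistic models behind these catalogs, `OR = exp(beta)`); the
  `beta_to_or = FALSE` flag drops them instead. A SNP with no usable effect
  size receives the neutral weight 1 and a flag, so it still counts alleles
  without tilting the score.
* **Effect-size kind.** The catalog's `OR or BETA` column is unlabeled. A
  kind column is used when the caller names one; otherwise positive values
  are read as ORs and non-positive values as betas, which is the only
  self-consistent reading (an OR cannot be ≤ 0).
* **Unknown and conflicting alleles.** Rows with `?` alleles are retained
  and flagged rather than dropped (dropping them would silently shrink the
  model; a `strict_alleles` mode drops them for users who prefer that).
  When studies disagree on the effect allele, the study with the largest
  `|log OR|` wins and the entry is flagged `allele_conflict`.
* **Strand ambiguity.** A/T and C/G SNPs cannot be checked from the catalog
  alone (only one allele is reported); they are flagged at VCF-counting
  time, where REF/ALT are known, and counted normally.

## Allele counting

Counts, not frequencies, are the stored observation: `eac / tac` (effect
allele count over total called haplotypes) per population and SNP. Missing
genotype calls leave both numerator and denominator; haploid genotypes
(male X) contribute one haplotype — the VCF's ploidy encoding is trusted.
Frequency-only resources are converted back to pseudo-counts as
`round(freq × n)` with the table's allele number or a declared `default_n`,
and flagged `counts_reconstructed`, which keeps exact tests runnable while
making the approximation visible.

## The signed enrichment statistic

For each SNP and focal population we form the 2×2 table of effect vs
non-effect alleles in the focal population against a comparison pool, and
compute the two-sided Fisher exact p-value under the probability-ordering
definition (sum of hypergeometric probabilities of all same-margin tables no
more probable than the observed one). The reported statistic is

\[ s = \mathrm{sign}(f_{\text{focal}} - f_{\text{pool}}) \cdot (-\log_{10} p), \]

so enrichment is positive (drawn red in the heatmap) and depletion negative
(blue), with `s = 0` when the proportions are equal or `p = 1`.

Design choices worth knowing:

* **The comparison pool excludes the focal population.** A 2×2 exact test
  needs disjoint groups; pooling the focal alleles into the "global" side
  would count them twice. With five superpopulations the pooled-rest
  frequency differs negligibly from the all-population one; the convention is
  recorded in the run manifest.
* **Two-sidedness.** The statistic is signed after the fact, which implies
  a two-sided p with direction recovered from the frequency comparison.
  The enumeration runs in log space (log-PMF + log-sum-exp), so cells in the
  thousands of haplotypes are no problem.
* **Underflow.** p is floored at 1e-300 before the log; cells therefore cap
  at |s| = 300.
* **No multiple-testing correction** is applied anywhere in the filtering;
  a Bonferroni column is emitted in the long-format output for reference
  only.
* **Divergence filter.** SNPs with `|s_A| + |s_B| > cutoff` for a chosen
  population pair (default AFR vs EAS) are listed separately; 60 is the
  default working cutoff and 100 a stricter display preset. The inequality
  is strict.
* **Clustering.** Heatmap row/column orders come from complete-linkage
  agglomerative clustering on Euclidean distances of the score matrix, with
  untestable cells imputed as 0 *for ordering only*. The linkage choice is
  a convention, recorded in the manifest; scores (not raw frequencies) are
  the clustering features.

## The normalized PRS

For dosages \(X_i \in \{0, 1, 2\}\) and weights \(\beta_i > 0\),

\[ \mathrm{PRS} = \frac{\sum_i \beta_i X_i}{2 \sum_i \beta_i} \in [0, 1]. \]

This normalization is chosen so that three calibration points hold for
*arbitrary* positive weights: all-homozygous-risk scores exactly 1, no risk
alleles scores exactly 0, and dosages uniform on {0, 1, 2} give expectation
exactly 0.5. A denominator of `2I` (twice the SNP count — the unweighted
convention) satisfies those properties only when all weights equal 1; it is
available via `literal_denominator = TRUE` and both forms are recorded in
the run manifest. Missing dosages renormalize (they leave both sums) rather
than being imputed at `2f`; the per-individual missing count is reported.
Hemizygous X calls are dosage-doubled by default (`{0,1} -> {0,2}`),
preserving the [0, 1] range; an `as_is` mode keeps them at face value.

For a population under Hardy–Weinberg equilibrium, \(E[X_i] = 2 f_i\), so
the expected score needs only allele frequencies:
\(E[\mathrm{PRS}] = \sum_i \beta_i f_i / \sum_i \beta_i\).

## Ecological regression

`fit_linear()` is ordinary least squares of a population-level rate on a
population-level predictor, with equal weight per population. This is an
*ecological* regression on a handful of points (typically 4–6
populations): R² values from it are descriptive, fragile, and say nothing
about individual-level risk. The printed fit object repeats this caveat.
Incidence and mortality are fitted separately; `covariate_report()` ranks
the PRS against hormone (DHT:T) and vitamin-D covariates by R² per
response, skipping covariates observed in fewer than 3 populations.
`predict_rate()` places a held-out population (e.g. one whose frequencies
come from a separate national reference panel) on the fitted line for
comparison with its observed rate.

## What the simulator emulates — and what it does not

The generator produces every input format with known ground truth:

* **Catalog rows**: ORs `exp(N(0, or_log_sd))` with `or_log_sd = 0.1`
  (typical catalog ORs 0.85–1.35), plus configurable fractions of
  duplicate-rsID rows (default 5%) and beta-scale rows (5%) to exercise
  harmonization.
* **Population frequencies**: Balding–Nichols — ancestral
  `p ~ U(0.05, 0.95)`, population frequency
  `Beta(p(1-F)/F, (1-p)(1-F)/F)`, hence `Var = F p(1-p)`. The bundled
  preset uses five codes (AFR/AMR/EAS/EUR/SAS) with unequal sample sizes
  matching the phase-3 reference panel and F of 0.15/0.11/0.10/0.08/0.09 —
  illustrative continental-scale divergence, clearly synthetic.
* **Genotypes**: HWE draws `Binomial(2, f)`, written as a plain VCF with a
  sample map; a configurable fraction of SNPs encodes the effect allele as
  REF to exercise the allele-flip path, and a missing-call rate exercises
  the denominator contract.
* **Epidemiology**: `rate = intercept + slope × E[PRS] + N(0, sd)`, floored
  at 0. Defaults (`slope 1500, intercept −650, sd 2` for incidence;
  `400/−170/1` for mortality) center incidence near 100 and mortality near
  30 per 100,000 at a typical expected PRS of 0.5, with covariates coupled
  to the PRS weakly (vitamin D negatively) so that a predictor comparison
  should rank the PRS first.

Two realism gaps matter for interpretation. First, symmetric
Balding–Nichols drift around a shared ancestral frequency produces only a
modest spread of expected PRS across populations (the per-SNP deviations
average out over hundreds of SNPs); real risk-SNP panels show larger
spreads because discovery is ascertained in particular ancestries. Second,
SNPs are simulated independently — no linkage disequilibrium — and no
selection or demographic history is modeled. Passing the simulation-based
tests therefore demonstrates correctness of the *computations*, not that
real cross-population PRS differences of any particular size will be
observed.

## Numerical and interface choices

* Exact-test enumeration uses the log-PMF with a `1e-7` relative tolerance
  when comparing table probabilities (guarding ties against rounding), the
  standard convention for probability-ordering exact tests.
* R² is computed as `1 − SS_res/SS_tot` and clamped to [0, 1] against
  last-ulp excursions in degenerate exact cases.
* All generators are pure functions of `(config, seed)`; reruns are
  byte-identical on tabular outputs.
* The pipeline config is YAML (`validate_config()` collects *all* problems
  in one error); the run directory always contains a `manifest.json` with
  the config, its hash, the seed, and every analysis convention in force,
  which is sufficient to rerun the pipeline identically.

## Problem sizes used by the test suite

The shipped tests run the exact-test oracle sweep over all 2×2 tables with
margins up to 30; parameter-recovery simulations use 200 SNPs × 5
populations with 50 replicate seeds; divergence monotonicity uses 100 SNPs
at F ∈ {0.01, 0.05, 0.2}; the VCF round trip uses 5,000 diploid samples and
the HWE panel check 2,000. These sizes were chosen to make sampling error
small relative to the asserted tolerances while keeping a full test run in
well under a minute.

## Known limitations

* Trait filtering is by literal label match; no ontology traversal.
* No LD pruning/clumping or shrinkage estimators — the score intentionally
  uses the raw averaged-OR weights.
* Liftover between genome assemblies, phasing and imputation are out of
  scope; coordinates are taken as given (GRCh37 in the motivating inputs).
* The ecological regressions must not be read as individual-level risk
  prediction, and with n ≈ 5 populations the difference between an R² of
  0.90 and 0.95 is not meaningful.
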