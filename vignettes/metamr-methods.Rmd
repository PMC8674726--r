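---
title: "Methods: summary-statistics meta-analysis, fine-mapping and Mendelian randomization in metamr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-statistics meta-analysis, fine-mapping and Mendelian randomization in metamr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metamr)
```

# Scope and model overview

`metamr` implements the analysis chain used to study blood-cell trait
genetics from GWAS summary statistics alone: multi-cohort fixed-effect
meta-analysis with genomic control, locus definition around lead SNPs,
Bayesian fine-mapping with 99% credible sets under a single-causal-variant
model, and two-sample Mendelian randomization (MR) of a quantitative
exposure (e.g., a white-blood-cell count on the inverse-normal scale) on a
disease outcome (e.g., asthma case-control log-odds). No individual-level
genotypes are touched anywhere; every stage consumes and emits per-SNP
effect sizes, standard errors, allele frequencies and p-values.

## Inverse-variance-weighted meta-analysis

For SNP $i$ observed in cohorts $k = 1,\dots,K_i$ with effect $\beta_{ik}$
and standard error $se_{ik}$, the pooled fixed-effect estimate uses weights
$w_{ik} = 1/se_{ik}^2$:

$$\hat\beta_i = \frac{\sum_k w_{ik}\beta_{ik}}{\sum_k w_{ik}}, \qquad
  se(\hat\beta_i) = \Big(\sum_k w_{ik}\Big)^{-1/2}.$$

This is the generalized-least-squares solution of an intercept-only
weighted regression, which the test suite uses as an independent oracle.
SNPs missing from some cohorts are pooled over the cohorts that carry them,
and the per-SNP study count $K_i$ is retained because the fine-mapping
Bayes factor depends on it. Two-sided p-values come from the normal
distribution; the chi-square form is equivalent, and one convention is
fixed for determinism.

Genomic control measures inflation as
$\lambda = \mathrm{median}(z^2)/0.4549364$ (the null median of
$\chi^2_1$). When $\lambda > 1$, z-scores are divided by $\sqrt\lambda$ and
standard errors multiplied by $\sqrt\lambda$; deflation is never applied,
the standard convention. By default the correction is applied once, to the
meta-analyzed statistics; `genomic_control_table()` supports the
alternative per-cohort pre-correction for users who prefer GWAMA-style
double control. We default to post-meta correction because it is the
single-correction reading of the usual workflow, and because per-cohort
correction of small cohorts is dominated by noise in the median.

## Locus definition and novelty

Loci are $\pm$250 kb windows anchored on lead SNPs. The window size and the
genome-wide threshold $p < 5\times 10^{-9}$ are the conventional values for
dense African-ancestry panels (the stricter threshold reflects the larger
effective number of tests); both are arguments. The assignment algorithm is
greedy and p-ranked: take the most significant unassigned SNP as a lead,
absorb every significant SNP within the window on the same chromosome,
repeat. The window boundary is inclusive (distance exactly 250 kb joins the
locus), ties on p break by chromosome then position, and the output is
provably invariant to input row order — properties the suite asserts. A
locus is *novel* when its lead SNP is farther than the window from every
entry of a user-supplied reference list (sentinel-based comparison; the
reference list for blood-cell traits is external data and is not bundled).

## Fine-mapping

Within $\pm$250 kb of each lead, every meta-analyzed SNP (significant or
not) receives a Bayes factor computed from its meta-analysis Z score and
study count $K$:

$$BF_i = \exp\!\big[(Z_i^2 - \log K_i)/2\big],$$

with the natural logarithm (a `log_base` argument guards the alternative
reading). Note this form omits the prior-variance shrinkage term of
standard approximate Bayes factors, so it grows without bound in $|Z|$;
it is implemented exactly as stated, and all normalization is done in log
space: posterior probabilities subtract $\max Z^2$ inside the exponent
before normalizing, which leaves $PP_i = BF_i / \sum_j BF_j$ unchanged but
remains finite far beyond the $|Z| \approx 37.6$ where the plain value
overflows a double. `bayes_factor(log = TRUE)` exposes the stable scale.

The 99% credible set is the smallest prefix of the pp-descending order
whose cumulative posterior reaches 0.99; the comparison uses a
$10^{-12}$ slack to absorb floating error, and reaching the level exactly
counts (a (0.95, 0.04) pair closes a 0.99 set). Ties in pp break by $|z|$
then SNP id so output is deterministic. A locus is *high confidence* when
its top SNP alone carries strictly more than 50% of the posterior. All of
this assumes exactly one causal variant per locus; with multiple causal
variants the posteriors concentrate on one signal and the credible set
loses its coverage interpretation — conditional or joint fine-mapping is
out of scope.

## Two-sample Mendelian randomization

Instruments are genome-wide-significant exposure SNPs thinned by greedy LD
clumping: a SNP is removed only when it is **both** in LD
($r^2 \ge 0.001$) with an accepted SNP **and** within 250 kb of it. The
retained set is therefore pairwise unlinked or distant, which the suite
checks exhaustively. SNPs absent from the LD matrix are treated as
unlinked with a logged warning rather than dropped, since a missing LD row
usually reflects panel coverage, not true linkage. Instruments missing
from the outcome can be routed through a user-supplied proxy table
(default $r^2 \ge 0.8$); outcome alleles are harmonized to the exposure
orientation with the same machinery used for cohort harmonization
(swapped alleles flip the effect sign and complement the frequency;
palindromic SNPs with MAF > 0.4 are dropped as strand-ambiguous).

With harmonized pairs $(\hat\beta_{Xj}, \hat\beta_{Yj})$ the estimators are:

* **IVW**: $\hat\theta = \sum_j \hat\beta_{Xj}\hat\beta_{Yj}/se_{Yj}^2 \big/
  \sum_j \hat\beta_{Xj}^2/se_{Yj}^2$, the through-origin WLS slope with
  first-order (fixed-effect) weights. One instrument degenerates to the
  Wald ratio, with a warning.
* **MR-Egger**: WLS of $\hat\beta_Y$ on $\hat\beta_X$ with an intercept,
  after orienting all $\hat\beta_X \ge 0$; the intercept estimates the
  average direct (pleiotropic) effect under the InSIDE assumption. Standard
  errors are model-based fixed-effect, coherent with the IVW convention; a
  `dispersion = "multiplicative"` option inflates them by the
  overdispersion factor (never below 1) for users who want the
  random-effects flavour.
* **Weighted median**: per-instrument Wald ratios with weights
  $(\hat\beta_{Xj}/se_{Yj})^2$, interpolated at standardized cumulative
  weight 0.5; consistent while valid instruments carry more than half the
  weight. Its standard error is a seeded parametric bootstrap (resampling
  both effect sides from their normal sampling distributions); the
  replicate count is an argument and `n_boot = 0` returns the point
  estimate alone.

Heterogeneity uses Cochran's
$Q = \sum_j w_j(\hat\beta_{Yj}/\hat\beta_{Xj} - \hat\theta)^2$ with
$J - 1$ degrees of freedom. Pleiotropy exclusion is deliberately a single
pass: each instrument's Q contribution is compared against the
Bonferroni-corrected $\chi^2_1$ quantile ($\alpha/J$), offenders are
removed, and the IVW estimate is refit once. Iterating the exclusion
invites data-dredging loops; one pass keeps the procedure pre-registerable.
`implied_wald_p()` is a small consistency utility that recovers the Wald
p-value implied by a published estimate/CI pair — useful for checking
reported MR tables whose underlying data are not deposited.

# The synthetic-data generator

Because the consortium summary statistics this kind of study draws on
(APCDR, BCX2, CAAPA) are not publicly deposited, every stage is exercised
on simulated data with known truth. The generator works at the summary
level by design: the pipeline consumes only summary statistics, so
simulating Z scores directly is sufficient, exact, and fast.

**Cohort simulator.** Each locus carries `snps_per_locus` SNPs 10 kb apart
(default 50, so a locus spans the same $\pm$250 kb window the pipeline
analyzes), loci 1 Mb apart. LD is AR(1), $R_{ij} = \rho^{|i-j|}$ (default
$\rho = 0.5$) — a deliberate simplification of real haplotype block
structure. Cohort $k$'s Z vector at a causal locus is multivariate normal
with covariance $R$ and mean $R e_c \cdot z_c \sqrt{n_k/n_{tot}}$, so the
stated `causal_z` is the non-centrality of the *meta-analyzed* Z at the
causal SNP $c$. Betas are back-computed through
$se = 1/\sqrt{2 n f (1-f)}$ with frequencies shared across cohorts.
Default cohort sizes (2,741 and 15,061) mirror a two-cohort
white-blood-cell count meta-analysis totalling 17,802.

**MR simulator.** Exposure effects are half-normal magnitudes
$|N(0, 0.05^2)|$, redrawn while $\le 0.01$ to keep Wald ratios stable, and
oriented to the exposure-increasing allele. The orientation matters:
*directional* pleiotropy is only directional relative to a fixed
instrument orientation, and with sign-symmetric exposure effects the IVW
bias it induces would average to zero. Outcome effects are
$\beta_Y = \theta\,\beta_X + \alpha + \varepsilon$, with $\alpha = 0$ for
valid instruments and $\alpha \sim N(\mu_\alpha, 0.01^2)$
(default $\mu_\alpha = 0.02$) for the pleiotropic fraction, drawn
independently of $\beta_X$ so InSIDE holds. With a pleiotropic fraction
$\pi$, the estimable average direct effect is $\pi\mu_\alpha$ — that, not
$\mu_\alpha$, is what the Egger intercept converges to, and what the
recovery tests check (0.006 for $\pi = 0.3$). The exposure side defaults to
$n = 17{,}802$; the outcome side defaults to $n = 200{,}000$, a modern
consortium-scale outcome study, sized so that instruments of the simulated
effect scale carry informative Wald ratios — with a mid-2010s-scale
outcome study ($n \approx 15$k) the weighted median's finite-sample bias
under 30% directional pleiotropy exceeds its consistency margin, which
says something true about that estimator on weak data but would make the
generator unrepresentative of the regime the estimators are meant for. A
random half of outcome rows have their allele orientation swapped so
harmonization is exercised end-to-end.

What the generator does **not** emulate: real haplotype LD (only AR(1)),
allele-frequency-dependent effect sizes, winner's-curse noise on the
exposure effects (the generated $\beta_X$ is used directly in $\beta_Y$,
so there is no regression-dilution bias), population structure, or sample
overlap between exposure and outcome. Passing recovery tests therefore
demonstrate correctness of the estimators under their own assumptions, not
robustness to the full messiness of real consortium data.

All randomness flows from the single config seed through an internal
RNG-scope helper, so any simulation re-run with the same config is
bit-identical and the caller's RNG stream is untouched.

# Numerical and interface choices

* **Strict boundaries.** MAF filtering keeps $\min(f, 1-f) > 0.05$
  strictly; genome-wide significance is $p < 5\times10^{-9}$ strictly;
  high confidence is top pp $> 0.5$ strictly; the locus/novelty window is
  inclusive at exactly 250 kb.
* **Palindromic threshold.** A/T and C/G SNPs are unresolvable from the
  letters; above MAF 0.4 the frequencies cannot orient them either, so
  they are dropped (the conventional safe cutoff, configurable); below it
  they are oriented by frequency.
* **Cohort n per trait** is the maximum per-record n — records carry
  per-SNP missingness, while trait-level totals are conventionally quoted
  at the full cohort size.
* **Text formats.** All tables are tab-separated with canonical headers
  (`SNP CHR POS EA OA EAF BETA SE P N`), numeric fields written with 17
  significant digits so write/read round-trips are exact; `column_map`
  adapts other header dialects. Rejected input rows go to a JSON-lines log
  with one reason code each.
* **Pipeline config** is YAML — a single declarative file with one block
  per stage, the most portable key-value format in the installed R stack —
  with CLI flags overriding file values. Every stage writes a manifest
  (parameters, seed, MD5 of inputs and outputs keyed by file name, row
  counts), and the run report echoes all five analysis thresholds so no
  default is silent.

# Problem sizes used by the test suite

The suite favours many replicates of small problems: null calibration uses
10,000 SNPs (200 loci of 50) in two cohorts; MR recovery uses 200
replicates of 50 instruments for each pleiotropy scenario; fine-mapping
coverage uses 500 replicates of 50-SNP loci; clumping correctness checks
100 random fixtures of 15–30 SNPs exhaustively. These sizes give stable
Monte-Carlo margins (the standard error of each reported mean is an order
of magnitude below the asserted tolerance) while keeping the full suite
fast enough to run on every change.

# Known limitations

* One causal variant per locus is assumed throughout fine-mapping; the
  Bayes factor is the unshrunk form stated above and is not comparable
  across loci with very different K without care.
* The 269-locus composite count reported for this kind of multi-trait
  analysis depends on how overlapping loci are de-duplicated across
  traits, which is not specified anywhere authoritative; `define_loci()`
  operates per trait and no cross-trait union is asserted.
* MR estimates are reported on the scale of the supplied effect sizes;
  the package does not adjudicate units (per-SD vs per 10^9 cells/L) or
  direction-of-effect language.
* Proxy substitution trusts the supplied proxy table's allele alignment;
  live LD-panel queries are out of scope.
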