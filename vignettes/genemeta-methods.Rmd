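---
title: "Methods: pooling genotype-count association studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooling genotype-count association studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genemeta)
```

## The statistical model

`genemeta` implements the standard two-stage meta-analysis of case-control
SNP studies reported as genotype counts.

**Stage 1 — per-study effects.** Each study's genotype triples
$(n_{GG}, n_{GT}, n_{TT})$ for cases and controls are collapsed into a 2×2
exposure table under one inheritance model for the variant allele:

| model | exposed | unexposed |
|---|---|---|
| additive | GG | TT (GT excluded) |
| dominant | GG + GT | TT |
| recessive | GG | GT + TT |

"Additive" here is the homozygote contrast GG vs TT, the convention common
in candidate-gene meta-analyses — *not* the Cochran-Armitage per-allele
trend test, which this package deliberately does not implement. The study
effect is the log odds ratio $\hat\theta_i = \log(a_i d_i / b_i c_i)$ with
the Woolf standard error
$se_i = \sqrt{1/a_i + 1/b_i + 1/c_i + 1/d_i}$. If any collapsed cell is
zero the Haldane–Anscombe correction adds `cc` (default 0.5, the
RevMan-compatible choice) to all four cells of that table; a table whose
whole case or control margin vanishes is degenerate and the study is
excluded from that model with a warning. Confidence intervals are
log-symmetric, $\exp(\hat\theta \pm z_{1-\alpha/2}\,se)$.

**Stage 2 — pooling.** Heterogeneity is quantified on inverse-variance
weights $w_i = 1/se_i^2$:
$Q = \sum_i w_i(\hat\theta_i - \bar\theta)^2$ referred to
$\chi^2_{k-1}$, $I^2 = \max(0, (Q - df)/Q) \cdot 100$, and the
DerSimonian–Laird moment estimator
$\hat\tau^2 = \max\{0, (Q - df)/(\sum w - \sum w^2/\sum w)\}$.
The pooled estimate is then

* **Mantel–Haenszel fixed effects** when the Q-test gives
  $p > $ `het_threshold` (default 0.1):
  $OR_{MH} = \sum_i (a_i d_i/n_i) / \sum_i (b_i c_i/n_i)$, with the
  Robins–Breslow–Greenland variance estimator for $\log OR_{MH}$ (the
  RevMan standard; no variance formula accompanies MH pooling in most
  source papers, and RBG is what the era's software used);
* **DerSimonian–Laird random effects** otherwise:
  weights $w^*_i = 1/(se_i^2 + \hat\tau^2)$, pooled
  $\hat\theta = \sum w^* \hat\theta_i / \sum w^*$,
  $se = 1/\sqrt{\sum w^*}$.

Ties at the threshold ($p$ exactly equal) go to random effects — the gate
is the strict inequality $p > 0.1 \Rightarrow$ fixed. Pooled significance
is the Z-test $z = \hat\theta/se$ against the standard normal. Note the
deliberate asymmetry, matching RevMan 5 behaviour: $Q$, $I^2$ and $\tau^2$
always come from inverse-variance weights on Woolf estimates, even when the
pooled point estimate is Mantel–Haenszel. A single-study "pool" returns
that study's estimate labelled MH-fixed with no heterogeneity block
(rendered as nulls/dashes).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `het_threshold` | 0.1 | Q-test p above which fixed effects are used; 0.1 (not 0.05) is conventional because Q is under-powered at small k |
| `conf_level` | 0.95 | all intervals; the 95% multiplier is `qnorm(0.975)` = 1.959964, never a rounded 1.96 — display layers round, internals do not |
| `cc` | 0.5 | continuity correction, applied per table only when a raw cell is zero |
| `hwe_alpha` | 0.05 | flagging level for control-arm HWE; failing studies are flagged, never excluded, because silent exclusion is an undocumented data change |

## Hardy–Weinberg quality control

Control arms are tested against the HWE proportions
$(p^2, 2p(1-p), (1-p)^2)$ at the estimated variant-allele frequency
$\hat p = (2n_{GG} + n_{GT})/2n$ by the plain chi-square goodness of fit on
1 df, no continuity correction — this is the statistic association papers
tabulate, and it is the operative QC gate here. The exact test
(`hwe_exact()`) — enumeration of all heterozygote counts compatible with
the observed allele counts, summing probabilities no larger than the
observed configuration's — is provided alongside for small samples, where
the chi-square approximation is unreliable, but does not drive flagging.
Monomorphic arms get $\chi^2 = 0$ with an explicit flag rather than an
error.

## Subgroup model selection

Stratified analyses raise a design question the literature rarely makes
explicit: is the fixed/random decision re-taken inside every stratum, or
is the model chosen on the overall data carried into its strata?
`run_pipeline()` supports both and defaults to the latter
(`subgroup_selection = "overall"`): one results table then reports a single
estimator per genetic model across all its rows, rather than silently
switching between a narrow fixed-effect CI in one stratum and a wide
random-effects CI in the next. This is also, empirically, how the
published tables this package's example reproduces were computed — the
worked MDM2 example only matches its source on the Caucasian rows (where
the stratum Q-test is non-significant) under the inherited random-effects
model. `subgroup_selection = "stratum"` re-applies the `p > 0.1` gate per
stratum, which is what the stated selection rule implies when read
literally; `pool_or()` on a subset does the same. Per-stratum genotype
counts for annotations like smoking status or histology are usually not
recoverable from publications; the stratification machinery is therefore
validated on synthetic strata attached by the generator.

## Bias and sensitivity diagnostics

Egger's test is the classical unweighted OLS of the standard normal
deviate $\hat\theta_i/se_i$ on precision $1/se_i$ (the STATA `metabias`
default of the relevant era); the statistic is
$t = \hat\beta_0 / se(\hat\beta_0)$ on $k-2$ df, two-sided, requiring
$k \ge 3$. Funnel coordinates are exported untransformed (log OR, SE);
axis inversion is left to plotting. Leave-one-out re-pools every $k-1$
subset with the full selection machinery re-run per subset.

On the shipped MDM2 data the leave-one-out analysis is instructive about
borderline pools: the full recessive-model CI (0.99–1.27) excludes 1 only
barely on one side, and omitting either of two studies (the largest
protective-leaning one, or the small study with the lowest OR) tips it —
and the additive model with one omission — into nominal significance. The
test suite computes this pattern explicitly; it is a property of the data,
and a caution against reading robustness claims off borderline intervals.

## The synthetic-data generator

`simulate_dataset()` emulates the structure of a genotype-count study
collection with known truth:

* control genotypes are multinomial draws from exact HWE proportions at a
  configurable variant-allele frequency `p_g`;
* the study-level odds ratio is $\psi_i = \exp(N(\log\psi, \tau^2))$ —
  log-normal between-study heterogeneity, the generative assumption under
  which DerSimonian–Laird is the natural estimator;
* case genotype probabilities multiply each genotype counted as exposed
  under the generating inheritance model by $\psi_i$ and renormalize, so
  the model-matched collapsed 2×2 has population OR exactly $\psi_i$
  (dominant tilts GG and GT; additive and recessive tilt GG);
* arm sizes are fixed (case-control sampling), strata labels are drawn
  independently per study from user-specified level probabilities.

Each study draws from its own seed, derived deterministically from
`(seed, study index)`; datasets therefore depend only on the configuration
and never on ambient RNG state, and any single study can be reproduced
without regenerating the rest.

What the generator does **not** emulate — and hence what passing recovery
tests cannot certify about real data: linkage disequilibrium with causal
variants, genotyping error, population stratification confounding,
covariate effects, selective reporting, and non-HWE control populations.
Recovery results validate the estimators under their own assumptions, no
more.

## Monte-Carlo validation settings

The estimator-recovery harness (`evaluate_recovery()`) is exercised at two
problem sizes chosen to be realistic for this literature while keeping the
default test run quick: recovery of $\psi = 1.5$ from 30 studies of
2000 + 2000 subjects at `p_g` = 0.4 (close to the control G-allele
frequency in the MDM2 example) over 200 replicates, and the type-I error
of the Q-test gate under the null ($\psi = 1, \tau = 0$) from 10 studies of
1000 + 1000 over 1000 replicates, judged against binomial 99% bounds around
the nominal 0.1.

## Numerical notes and limitations

* All pooling is on the natural-log OR scale; reported CIs exponentiate at
  the end. Display rounding (OR/CI to 2 decimals, heterogeneity to 3,
  $I^2$ to 1) lives entirely in the text renderer and print methods.
* $I^2$ is truncated at 0 and cannot reach 100; $\tau^2$ is truncated at 0
  (the moment estimator's usual censoring).
* The exact HWE enumeration is $O(\min(n_G, n_T))$ per study in log-space;
  it is exact, not simulated.
* Only odds ratios are supported (no risk ratios or differences), only
  MH and DL pooling (no Peto, REML, Paule–Mandel or Hartung–Knapp), and
  only the three genotype contrasts above (no allele-count contrast, no
  trend test) — matching the scope of the genotype-count meta-analyses
  this package targets.
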