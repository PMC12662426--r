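---
title: "Two-sample MR screening and two-step mediation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR screening and two-step mediation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MRmediate)
```

# The model

Two-sample Mendelian randomization treats genetic variants as instruments
for an exposure. For instrument $j$, let $\gamma_j$ be its per-allele
association with the exposure (with standard error $\sigma_{\gamma j}$) and
$\Gamma_j$ its association with the outcome ($\sigma_{\Gamma j}$), estimated
in two non-overlapping samples. Under the instrumental-variable assumptions
(relevance, independence from confounders, exclusion restriction) each SNP
provides a Wald ratio estimate of the causal effect,

$$\hat\beta_j = \Gamma_j / \gamma_j, \qquad
  \mathrm{SE}(\hat\beta_j) = \sigma_{\Gamma j}/|\gamma_j|,$$

and the inverse-variance-weighted (IVW) estimator pools them with weights
$w_j = 1/\mathrm{SE}(\hat\beta_j)^2 = \gamma_j^2/\sigma_{\Gamma j}^2$:

$$\hat\beta_{IVW} = \frac{\sum_j w_j \hat\beta_j}{\sum_j w_j},$$

identical to weighted least squares of $\Gamma_j$ on $\gamma_j$ through the
origin (the package tests this identity to $10^{-10}$ against a
normal-equations oracle). For binary outcomes the associations are log odds
ratios, so estimates exponentiate to odds ratios.

The Wald-ratio standard error is first order only: the exposure-side noise
in $\gamma_j$ is ignored. This is the conventional choice — it makes the
ratio weights coincide exactly with the standard IVW weights — but it
understates per-SNP uncertainty when instruments are marginal, one reason
the weak-instrument filter below matters.

## Validation estimators

Four further estimators probe the exclusion restriction from different
directions; agreement in sign and magnitude across them is the practical
robustness criterion.

* **MR-Egger** fits the same weighted regression with a free intercept,
  after re-orienting each SNP so $\gamma_j \ge 0$ (without a fixed
  orientation the intercept is meaningless). Under the InSIDE assumption
  (instrument strength independent of direct effects) the slope remains
  consistent under directional pleiotropy, and the intercept estimates the
  average pleiotropic effect — its $t$-test on $J-2$ degrees of freedom is
  the package's pleiotropy diagnostic.
* **Weighted median**: order the ratios, form standardized mid-cumulative
  weights $p_j = (\sum_{k\le j} w_k - w_j/2)/\sum_k w_k$, and interpolate at
  $p = 0.5$. Consistent while valid instruments hold $>50\%$ of the weight.
* **Weighted / simple mode**: the argmax of a Gaussian kernel density over
  the ratios (inverse-variance weights or equal weights), bandwidth
  $\varphi \cdot 1.06\, s\, J^{-1/5}$ with $s$ the (weighted, population
  form) standard deviation of the ratios and $\varphi$ a tuning factor
  (default 1). Consistent when the largest group of instruments sharing one
  ratio value is the valid one.

Weighted-median and mode standard errors come from a parametric bootstrap:
$\gamma_j^\ast \sim N(\gamma_j, \sigma_{\gamma j}^2)$,
$\Gamma_j^\ast \sim N(\Gamma_j, \sigma_{\Gamma j}^2)$, re-estimate, take the
standard deviation over replicates (default 1000; a seed is mandatory, and
every bootstrap draws from a named substream of the single top-level seed so
results are order-independent).

## Random-effects scaling and inference

The paper-standard diagnostic for instrument heterogeneity is Cochran's
$Q = \sum_j w_j(\hat\beta_j - \hat\beta_{IVW})^2$ on $J-1$ degrees of
freedom (for MR-Egger, the residual-based Rücker $Q'$ on $J-2$). The IVW
and Egger standard errors use the multiplicative random-effects model:
the fixed-effect SE is inflated by $\max(1, \sqrt{Q/(J-1)})$ (respectively
$\sqrt{Q'/(J-2)}$), so the fixed- and random-effects estimates coincide
when $Q \le \mathrm{df}$. This is the default of the dominant reference
implementations; since no flavor is mandated by the workflow this package
follows, the choice is exposed as `ivw_mode` and recorded in run logs.
P-values are two-sided normal, except MR-Egger's, which use $t_{J-2}$.

# Instrument selection

Three filters apply in a fixed order, each with a literal boundary:

1. **Relevance screen**: keep exposure associations with $p < 10^{-5}$
   (strict; $p = 10^{-5}$ is excluded). This is the conventional threshold
   for phenotypes, such as individual immune-cell subsets, whose GWAS are
   too small to yield many genome-wide-significant hits.
2. **LD clumping**: greedy by ascending p-value; a kept SNP removes every
   remaining SNP with $r^2 \ge 0.001$ within 10,000 kb on the same
   chromosome. Ties break by position then variant id, making the result
   independent of input order (a tested invariant, along with maximality of
   the retained set). LD itself comes from an abstract `LDSource` — a dense
   matrix for fixtures and simulations, a precomputed pair list for real
   use; the package never computes LD from a reference panel, and results
   that depend on the panel choice should be flagged as such.
3. **Weak-instrument filter**: discard SNPs with $F = \beta^2/SE^2 < 10$
   (strict: $F = 10$ survives), computed from the exposure association.

Harmonization then intersects exposure and outcome on variant id (never on
position), re-expresses the outcome effect for the exposure's effect allele
(sign flip for swapped coding), attempts a base-complement strand flip
before declaring an allele pair irreconcilable, and removes palindromic
(A/T, C/G) SNPs unconditionally — no allele-frequency rescue, since
frequency-based strand inference is fragile and the workflow specifies
removal without qualification. Duplicate variant ids keep the first
occurrence; both drop counts are retained on the result and satisfy the
conservation identity kept + dropped = intersection size. Missing
allele-frequency and sample-size columns are tolerated: no estimator here
uses them.

# Screening and evidence tiers

For panels of exposures, every exposure–outcome pair runs the full pipeline;
failures (e.g. no surviving instruments) are recorded per pair, not fatal.
Benjamini–Hochberg q-values (hand-rolled step-up, tested exactly against
enumeration oracles and `p.adjust`) are computed within an *FDR family*,
defined as all exposures of one trait class against one outcome. The
workflow's counts are reported per outcome but do not disambiguate the
family width; one-class-by-one-outcome is the most conservative reading
consistent with them, and is applied uniformly. Tiers: **strong** when
$p < .01$ and $q < 0.05$; **suggestive** when $p < .05$ but not strong;
**null** otherwise.

# Two-step mediation

With exposure $X$, candidate mediator $M$ and outcome $Y$:
$\alpha$ = IVW effect of $X$ on $Y$ (total), $\beta_1$ = IVW effect of $X$
on $M$, $\beta_2$ = IVW effect of $M$ on $Y$, each leg re-selecting
instruments from its own exposure's associations. The indirect effect is
$\beta_1\beta_2$ with the first-order product delta SE
$\sqrt{\beta_1^2 se_2^2 + \beta_2^2 se_1^2}$ (the second-order
$se_1^2 se_2^2$ term is omitted, matching the common two-step convention),
and the proportion mediated is $(\beta_1\beta_2/\alpha) \times 100\%$, with
a delta-method CI over $(\beta_1, \beta_2, \alpha)$ treated as independent
(three non-overlapping GWAS). Bounds are always reported ascending, even
when the point estimate is negative. The row p-value is the normal test of
indirect $= 0$. A zero total effect leaves the proportion undefined and is
reported as a flagged row rather than an error escaping the run.

Two caveats are deliberate: the $\alpha$ and $\beta_1$ legs share the
exposure's instruments, so their estimation errors are positively
correlated and the independence-based proportion CI is slightly
conservative (simulated coverage sits near the top of the 90–99% band);
and when the direct effect is large, exposure instruments that leak into
the mediator's instrument set would bias $\beta_2$ — at the default effect
scales this contamination is negligible (see below), and no Steiger-type
filtering is applied.

# The synthetic world

`simulateTriple()` generates summary statistics only — no individual-level
genotypes — from a three-trait linear system chosen to mimic the motivating
design: an immune-cell exposure GWAS of $n = 3757$, a plasma-metabolite
GWAS of $n = 8299$, and an IBD case–control GWAS of $n = 34652$ (log-OR
scale, no liability-scale conversion). Defaults and rationale:

| parameter | default | why |
|---|---|---|
| `n_snps_x`, `n_snps_m`, `n_snps_null` | 150 / 150 / 100 | enough candidate loci that ~20–30 exposure instruments survive selection, as typical for immunophenotypes |
| `gamma_sd` | 0.08 SD | at $n=3757$ only effects $\gtrsim 0.11$ pass $p<10^{-5}$, so exposure instruments are detectable but honest ($F \approx 20$–60) |
| `delta_sd` | 0.25 SD | metabolite QTLs are large-effect; keeps the mediator's instruments strong and their selection essentially free of winner's curse |
| `alpha_total`, `b1`, `b2` | 0.5 / 0.3 / 0.25 | the reference causal system; true proportion mediated $(0.3 \times 0.25/0.5) \times 100\% = 15\%$ |
| `palindromic_rate` | 0.1 | exercises the harmonization drop path at a realistic strand-ambiguous fraction |
| sample sizes | 3757 / 8299 / 34652 | the motivating cohorts' sizes; SEs are $1/\sqrt{2nf(1-f)}$ with $f \sim U(0.05, 0.5)$ |
| `pleiotropy_scale` | 0.05 | comparable to a typical per-SNP outcome effect $\alpha\gamma_j$, i.e. a moderate, detectable violation |

True instrument effects are half-normal magnitudes: the effect allele is
defined as the trait-increasing allele. This orientation convention is what
makes *directional* pleiotropy (per-SNP outcome shifts with nonzero mean)
actually bias the IVW slope — with sign-symmetric effects the bias would
average out and the Egger intercept would have nothing to detect.
`simulateHarmonized()` exposes the same model post-harmonization with a
fixed instrument count, for calibration studies that should not depend on
the selection step. `simulatePanel()` builds a many-exposure screen: each
trait owns a disjoint block of instrument loci and one shared outcome GWAS
spans their union (a screen needs a common outcome sample; fully
independent per-trait outcomes would not compose into one FDR family).
Optional LD is injected as equicorrelated blocks among exposure
instruments, block members sharing one true effect, emitted through the
same pair-list interface the clumping consumes.

What the generator does **not** emulate: realistic allele-frequency
spectra, imputation noise, sample overlap between GWAS, liability-scale
effects, or fine-scale LD. A green test therefore establishes that the
estimators and pipeline are correct under their own assumptions — not that
those assumptions hold in any particular real data set, where panel choice,
overlapping samples and selection on significance all intrude.

Measured behaviour of this stated world (all recomputed by the test suite,
none asserted beyond what the tests check): the IVW and Egger-intercept
tests reject at roughly 3–7% under the null at the 5% level (the
multiplicative random-effects floor makes both slightly conservative);
across 200 seeded triples the mean estimated mediation proportion is within
two Monte-Carlo standard errors of the true 15% and the delta-method CI
covers truth at the high end of the nominal range; with 40% invalid
instruments under directional pleiotropy the weighted median beats IVW on
absolute bias in well over 90% of replicates.

# Numerical and degenerate-input choices

* Zero exposure effects ($\gamma_j = 0$) are excluded from ratio-based
  estimators with a warning; a single surviving SNP degenerates IVW to its
  Wald ratio; fewer than 3 SNPs make Egger/median/mode refuse with an
  informative error.
* `n_boot = 0` skips bootstrap SEs (returned as `NA`) for point-estimate
  studies; any `n_boot > 0` requires a seed.
* The mode estimators fall back to the maximum-weight ratio when the
  kernel bandwidth degenerates (all ratios identical).
* Leave-one-out instability is flagged when any leave-one-out CI lies
  entirely on the opposite side of zero from the full estimate, or when the
  largest relative change of the estimate exceeds 30% (configurable); the
  reference workflow's own criterion is qualitative ("slightly differed"),
  so both operationalizations are reported.
* Clumping tie-breaks (equal p-values): smaller coordinate, then
  lexicographic variant id — determinism over cleverness.
* BH q-values are capped at 1 and mathematically dominate their p-values;
  comparisons in tests allow $10^{-12}$ of floating-point slack.

# Limitations

The package computes LD from nothing: without an `LDSource` the clumping
step keeps all candidates, which is only correct when instruments are
already independent (true of the simulator's default, rarely of real data).
MR-PRESSO-style outlier removal, Steiger directionality filtering and
multivariable MR are out of scope. The mediation CIs inherit every
first-order delta approximation listed above; for weak total effects
($\alpha$ near zero) the proportion's distribution is heavy-tailed and the
normal CI should be read cautiously.
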