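---
title: "Models and methods behind dopacca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dopacca}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dopacca)
```

`dopacca` studies multivariate association between a predictor set — age and
four regional dopamine D2-like receptor availabilities (non-displaceable
binding potential, BP_ND) — and a criterion set of five behavioral error
measures from a learning-based risky investment task. Because the package is
built around simulation, every stage is generative: the task, the
decision-maker, the cohort, and the statistical analysis are all explicit
models with named parameters. This vignette documents those models, the
conventions and numerical choices, and what the simulations can and cannot
establish.

## The task and the objective belief

The task is a 2 (framing: gain/loss) x 2 (stock type: good/bad) design played
in blocks (default 10 blocks of 6 trials, 5 blocks per frame). Within a
block the participant repeatedly chooses between a certain bond (+6, or −6 in
the loss frame) and a risky stock whose dividend is drawn from a fixed
distribution: a *good* stock pays the high dividend (+10 gain / −2 loss) with
probability `q_high = 0.7`, a *bad* stock with probability 0.3. The dividend
is revealed on every trial whether or not the stock was chosen, so learning
is independent of choice behavior.

With prior `p = 0.5` that the block's stock is good, the objectively correct
posterior after observing `n` high dividends in `t` trials multiplies the
prior odds by the likelihood ratio `(q/(1−q))^(2n−t)`:

$$P(\mathrm{good} \mid n, t) = \frac{1}{1 + \frac{1-p}{p}\left(\frac{q}{1-q}\right)^{t-2n}}.$$

`bayes_posterior()` implements this closed form; the test suite verifies it
against brute-force Bayes enumeration over all $(n, t)$ with $t \le 12$ to
$10^{-12}$. One high dividend in one trial gives $0.7$; balanced evidence
($t = 2n$) returns the prior. In the loss frame the "high" dividend counted
in $n$ is the better (less negative) outcome, mirroring the gain-frame
contingencies.

Expected values follow directly: at belief $b$, the stock's expected dividend
is $b\,E[d\mid\mathrm{good}] + (1-b)\,E[d\mid\mathrm{bad}]$. With the default
payoffs both frames tie exactly at $b = 0.5$, so every block's **first trial
carries no objective choice signal** — a structural fact the behavioral
metrics below exploit.

## The generative agent

The measured participant is replaced by an agent with six interpretable
parameters (`agent_params()`):

| parameter | symbol | default | units / role |
|---|---|---|---|
| `stickiness` | $\kappa \ge 0$ | 1.0 | payoff units added toward repeating the block's first choice |
| `risk_propensity` | $\rho$ | 0.85 | payoff units added to the stock every trial; sets the first-trial stock rate |
| `inv_temperature` | $\beta > 0$ | 1.0 | softmax slope per payoff unit |
| `belief_slope` | $\lambda > 0$ | 1.0 | multiplicative log-odds distortion of reports |
| `belief_bias` | $\delta$ | 0.0 | additive log-odds shift (optimism) |
| `report_noise` | $\sigma_r \ge 0$ | 15 | SD of report noise, percentage points |

Choices: $P(\mathrm{stock}) = \mathrm{logistic}(\beta\,[EV_{stock} -
EV_{bond} + \rho + \kappa\,\mathrm{sign}(\text{anchor})])$, evaluated at the
*pre-trial* posterior because the choice precedes feedback. On trial 0 the
EV terms cancel, so $P(\mathrm{stock}) = \mathrm{logistic}(\beta\rho)$; the
default $\beta\rho = 0.85$ gives a first-trial stock rate of about 0.70,
a realistic mild risk seeking. Stickiness anchors to the block's **first**
choice because the inflexibility measure is defined against it; a
previous-trial kernel is available (`stick_anchor = "previous"`) but off by
default.

Reports: subjective log-odds are $\lambda\,\mathrm{logit}(P_{post}) +
\delta$; the report is $100\times$ the corresponding probability plus
$N(0, \sigma_r^2)$ noise, clipped to $[0, 100]$. Clipping introduces a small
bias toward the interior at extreme posteriors; this is accepted and the
tests that quantify optimism use interior posteriors.

## The synthetic cohort

`sample_cohort()` draws ages uniformly on 26–79 years. A uniform age
distribution is the clean synthetic choice for an adult-lifespan design (real
convenience samples are rarely uniform; this is configurable). Regional
BP_ND is generated on the log scale: each region's standardized log-BP is
`age_slope` times the standardized age plus a correlated residual
(equicorrelation 0.4 across regions), then mapped through lognormal moment
matching so the *population* mean and SD on the natural scale equal the
configured targets — midbrain 1.73/0.41, amygdala 3.08/0.80, insula
1.86/0.55, anterior cingulate 1.19/0.38. The log-scale construction
guarantees positivity; moment matching is exact in population and therefore
approximate in any finite sample. Default age slopes (−0.45, −0.15, −0.40,
−0.40) are order-of-magnitude choices encoding the usual adult decline with
relative preservation of the amygdala; no claim is made that they equal any
particular sample's values, and they are fully configurable. The striatum is
excluded because the [11C]FLB 457 ligand cannot quantify it reliably.

`link_agent_params()` plants the brain–behavior linkage: each agent parameter
is `base + W z + noise` with `z` the within-cohort standardized
(age, regions) matrix. The default `W` has exactly three nonzero entries —
stickiness gets +0.30 from age and −0.35 from amygdala BP_ND, and belief bias
gets +0.30 from amygdala BP_ND — so older age and lower amygdala availability
produce more inflexible choice, and higher amygdala availability more
optimistic reports. Parameter noise SDs (0.30, 0.30, 0.20, 0.15, 0.30, 4)
keep individual differences realistic while leaving the planted signal
recoverable. Out-of-range draws are clamped to the nearest valid value,
which slightly distorts the tails (about 4% of stickiness draws hit the 0
bound under the defaults); the recovery oracle simulates the same law, so
clamping is part of the ground truth, not a bias.

## The five behavioral measures

All suboptimality judgments use the **pre-choice** posterior (the information
available when choosing) and exclude expected-value ties, where neither asset
is wrong; the prior makes every block's first trial a tie, consistent with
treating the first stock choice as a separate risk-propensity measure.

- **Choice inflexibility** — among non-first trials where the block's
  first-chosen asset is strictly suboptimal, the proportion on which it was
  chosen again. The denominator pools eligible trials across blocks (the
  per-block average is available via `per_block = TRUE`); pooling stabilizes
  the estimate when some blocks contribute few eligible trials. A
  participant with no eligible trials gets a flagged missing value and is
  excluded downstream with a warning.
- **First stock choice** — proportion of blocks whose first choice was the
  stock.
- **Suboptimal investment** — proportion of non-tie trials choosing the
  lower-EV asset.
- **Optimism** — mean of (report − 100·posterior) over trials, in percentage
  points, against the *post-feedback* posterior (reports are elicited after
  the dividend is shown).
- **Absolute error** — mean of the per-trial |report − 100·posterior|. This
  is deliberately *not* |optimism|: a reporter alternately 10 points high and
  10 points low has optimism 0 but absolute error 10. The per-trial
  definition is the only one consistent with absolute error exceeding
  |optimism| in typical data, and Jensen's inequality
  (absolute_error ≥ |optimism|) is enforced as a tested invariant.

`task_payment()` implements the incentive rule (a tenth of cumulative
payoffs plus 0.10 per estimate within 5 points of the objective posterior)
for completeness; it feeds no analysis.

## Canonical correlation analysis

`dopacca(x, y)` standardizes both sets (N−1 denominator; canonical
correlations are invariant to that choice) and takes the SVD of
$R_{xx}^{-1/2} R_{xy} R_{yy}^{-1/2}$. The singular values are the canonical
correlations; back-transformed singular vectors are the standardized
coefficients, which give unit-variance variates by construction. Structure
coefficients are the correlations between each observed variable and its own
set's variate ($R_{xx} a$, $R_{yy} b$ on standardized data).

Numerical conventions:

- **Rank deficiency.** The within-set correlation matrices are inverted via
  their eigendecompositions. An eigenvalue below $10^{-10}$ of the largest is
  an error by default, with two explicit escapes: a user-set `ridge`, or
  `pseudo_inverse = TRUE` (drop the null space). Defaults are exact (ridge
  0) because the reference design (N = 35, 10 variables) is well-conditioned.
- **Sign orientation.** Canonical pairs are sign-indeterminate;
  `orient_signs()` flips each pair jointly so the criterion variable with the
  largest |structure coefficient| loads positively. The flip is joint, so
  correlations and geometry are untouched; an exactly-zero top loading falls
  back to the first-listed variable with a message.
- **Degenerate inputs.** Constant columns are refused by name; duplicated
  sets produce unit correlations, which are clamped to $1 - 10^{-12}$ only
  inside the dimension tests (Wilks' lambda is otherwise 0).

**Dimension tests.** For roots $k..s$ ($s = \min(p, q)$),
$\Lambda_k = \prod_{i \ge k} (1 - R^2_{c,i})$ is transformed by Rao's F
approximation with deflated set sizes $p_k = p - k + 1$, $q_k = q - k + 1$:
$df_1 = p_k q_k$, $t_k = \sqrt{(p_k^2 q_k^2 - 4)/(p_k^2 + q_k^2 - 5)}$ (set
to 1 when the denominator is non-positive, i.e. the terminal 1×1 case), and
$df_2 = m\,t_k - p_k q_k/2 + 1$ where $m = N - 3/2 - (p+q)/2$ is held at the
**original** set sizes for every $k$. Holding $m$ fixed while deflating
$df_1$ and $t_k$ is the convention of the classical CCA significance
packages this analysis style comes from, and it is the unique combination
that yields df2 = 94.373, 80.07, 65.86, 56.00, 29.00 at N = 35, p = q = 5;
the suite pins those values exactly, and verifies that at $p = q = 1$ the F
statistic collapses to the squared t of the Pearson correlation test.

The full-model effect size is reported as $R^2_{c,1}$ (shared variance of
the first function); $1 - \Lambda_1$ is also printed, labeled, because the
two are easy to conflate. An optional permutation test (`permutations > 0`)
freely permutes criterion rows and compares $\Lambda_1$; it is off by
default since the asymptotic test is the reference procedure, but it is a
useful small-sample diagnostic and is calibration-checked in the suite.

**Age handling.** Two modes: `age_as_variable` (age is a fifth predictor,
the default) and `age_residualized` (age dropped and regressed out of every
remaining column, with intercept, giving $s = 4$ functions) — the standard
robustness variant for "is this just age?".

## Follow-up regressions

`followup_suite()` fits three labeled OLS models for the headline univariate
decomposition: inflexibility on age, on amygdala BP_ND, and on both. The
amygdala effect "controlling for age" is ambiguous between the simple and the
age-adjusted model, so both are reported, never conflated. One caveat worth
stating: at N = 35 the raw $R^2$ of a simple regression is biased upward by
roughly $(1 - \rho^2)/(N - 1) \approx 0.025$; the suite's Monte-Carlo
recovery test therefore targets the adjusted $R^2$ and checks that the raw
estimate shows exactly the predicted bias.

## What the simulations do and do not show

Problem sizes were chosen to make the statistical claims sharp while staying
desk-scale: null calibration uses 1000 replicate cohorts at the study's own
N = 35 (full pipeline, rejection rate compared with the exact binomial 99%
interval around 0.05); parameter recovery uses cohorts of N = 2000 with 200
replicates for sign recovery, against a Monte-Carlo oracle of $10^6$
participants for the population first canonical correlation. A default
N = 35 pipeline run takes well under a second.

Passing these tests shows the machinery is correct and calibrated *under the
generator's assumptions*: Gaussian parameter variation, lognormal BP_ND with
equicorrelated residuals, uniform ages, a softmax agent whose only
perseveration mechanism is first-choice anchoring. Real data differ in known
ways — non-uniform age distributions, region-specific covariance, belief
dynamics not reducible to a static log-odds distortion, and measured (not
planted) effect sizes. Consequently the data-dependent quantities of any
real analysis — the squared canonical correlations themselves, behavioral and
BP_ND sample means, specific slopes and $R^2$ values — are *not* reproduction
targets here; what the package reproduces exactly is the analytic layer (the
belief oracle, the dimension-test table for the reference design) and what
it demonstrates statistically is type-I calibration and recovery of planted
ground truth.

Known limitations: Rao's F is an approximation (exact only when
$\min(p,q) \le 2$), and with 10 variables at N = 35 its calibration rests on
approximate multivariate normality of the metrics — the null-cohort
calibration test probes precisely this; the agent has no reinforcement-
learning component (belief updating is exact Bayes, distorted only at
report time); confidence ratings and reaction times are not modeled; and the
cohort generator makes no attempt to emulate PET acquisition or kinetic
modeling — BP_ND values are drawn, not reconstructed.
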