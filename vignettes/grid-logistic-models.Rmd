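---
title: "Grid fitting of multi-category logistic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid fitting of multi-category logistic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridlogit)
```

## The problem

Clinical data often cannot leave the institution that collected them, yet a
model fitted on one site's patients is noticeably worse than a model fitted
on everyone's. When the outcome has more than two categories - cancer stage,
birth weight class, screening behaviour - the extra parameters of ordinal
and multinomial logistic models make small single-site samples even more
limiting than in the binary case.

gridlogit fits these models *federated*: each site evaluates its local
log-likelihood, gradient and Hessian at the coordinator's current parameter
vector and transmits only those aggregates. Because every likelihood in the
package is a sum over observations, the aggregated derivatives are exactly
the pooled-data derivatives, and the federated Newton iteration is
algebraically identical to the centralized fit. This is an exactness
guarantee, not an approximation: the only discrepancies are floating-point
summation order, at the 1e-13 level in practice.

## Models

With outcome $Y \in \{1, \dots, K\}$ ($K \ge 3$) and covariates $x \in
\mathbb{R}^m$:

* **Proportional odds (ordinal)**: $\mathrm{logit}\,\Pr(Y \le w \mid x) =
  \alpha_w + \beta^T x$ for $w = 1, \dots, K-1$; parameters
  $\theta = (\alpha_1, \dots, \alpha_{K-1}, \beta)$. Note the sign: the
  linear predictor is $\alpha_w + \beta^T x$, so slopes are the *negation*
  of those reported by implementations (such as `MASS::polr`) that model
  $\zeta_w - \beta^T x$.
* **Generalized ordered logit**: the same cumulative form with a
  split-specific slope vector $\beta_w$ per cut. It exists in the package as
  the alternative hypothesis of the proportional-odds score test; its
  cumulative curves may cross, in which case a category probability goes
  nonpositive and the likelihood is undefined (the package raises a
  structured error rather than flooring the probability, because silent
  flooring would bias the fit).
* **Multinomial (baseline-category) logit**: $\log \Pr(Y = w)/\Pr(Y = K) =
  \alpha_w + \beta_w^T x$, reference class $K$.

The stacked parameter vectors of the latter two models are flattened
block-major, $(\alpha_1, \beta_1^T, \dots, \alpha_{K-1}, \beta_{K-1}^T)$.
All gradients and Hessians are exact analytic expressions (standard
cumulative-logit and softmax algebra), validated in the test suite against
central finite differences at tolerances 1e-6 (gradient) and 1e-4 (Hessian).

## The grid Newton iteration

Each round, site $u$ returns $\left(l_u(\theta),\ \partial l_u/\partial
\theta,\ \partial^2 l_u/\partial\theta\partial\theta^T\right)$ at the
current $\theta$; the coordinator sums and updates
$$\theta^{(J+1)} = \theta^{(J)} -
\left[\textstyle\sum_u \partial^2 l_u/\partial\theta\partial\theta^T\right]^{-1}
\left[\textstyle\sum_u \partial l_u/\partial\theta\right].$$

Implementation choices that the mathematics leaves open:

* **Initialization.** One preliminary exchange of per-site category counts
  gives feasible starting values: empirical pooled cumulative logits with
  zero slopes (ordinal), or empirical baseline-category log odds with zero
  slopes (stacked models). The fixed point does not depend on this choice.
* **Convergence.** Maximum absolute parameter change below `tol = 1e-6`,
  capped at 25 rounds; well-behaved problems converge in 5-8.
* **Step halving.** A proposed step that produces a non-finite likelihood
  (possible for the cumulative models) or lowers the aggregated
  log-likelihood is halved, up to 10 times. Pure Newton rarely needs this at
  the sample sizes studied here; the safeguard matters for small or
  nearly separated sites and never changes the fixed point. A tiny
  acceptance slack (`1e-10` relative) prevents rounding noise at
  convergence from triggering spurious halvings.
* **Linear algebra.** The update solves the symmetric system rather than
  inverting the Hessian; the explicit inverse is formed once, at the
  optimum, for the variance-covariance matrix
  $-\left[\partial^2 l/\partial\theta\partial\theta^T|_{\hat\theta}\right]^{-1}$.
* **Round synchronization.** Summaries carry a 17-significant-digit decimal
  fingerprint of the parameter vector they were evaluated at; aggregation
  refuses to mix fingerprints, so a stale site message cannot silently
  corrupt a round. The JSON wire format round-trips all doubles bit-exactly.

Separation, or an otherwise singular aggregated Hessian, is reported as an
error at the round where it occurs; an iteration-capped fit is returned
with `converged = FALSE` and refuses to produce a Wald table.

## Testing the proportional-odds assumption

The score test evaluates the generalized ordered logit's gradient and
observed information at the embedded restricted MLE $\tilde\psi =
(\hat\alpha_1, \hat\beta, \dots, \hat\alpha_{K-1}, \hat\beta)$ and forms
$T_o = g^T [-H]^{-1} g$, asymptotically $\chi^2_{m(K-2)}$ under the null.
Both $g$ and $H$ are aggregated over sites exactly like the fit itself, so
the grid statistic equals the pooled statistic and no refit of the larger
model is needed - valuable because the generalized model often fails to
converge on exactly the small-site data that motivate federation.

## Goodness of fit and discrimination

The Hosmer-Lemeshow statistics sort observations by a fitted score, split
them into `g` near-equal-count groups and compare observed with expected
counts. Defaults and conventions (the source procedures leave these open):

* `g = 10` groups, the classical deciles-of-risk convention, matching the
  degrees of freedom $g - 2 = 8$ and $(g-2)(K-1) = 24$ used throughout.
* Equal-count binning: sizes $\lceil n/g \rceil$ or $\lfloor n/g \rfloor$,
  the first $n \bmod g$ bins taking the extra observation; ties in the
  score keep input order (stable sort).
* The binary test sorts by $\Pr(Y=1)$; the extended test by
  $\Pr(Y < K)$.
* An ordinal fit is assessed by running the binary test on each cumulative
  collapse $[Y \le w]$; the overall verdict requires **all** $K-1$
  collapses to pass at the 0.05 level. A single reported passing rate is
  also consistent with an at-least-one reading, so the `"any"` rule is
  exposed as an option; the all-pass convention reproduces the published
  rates (see below) and is the default.

Discrimination uses rank statistics only: the binary AUC is the Mann-Whitney
mid-rank formula (ties count 1/2, equal to all-pairs counting exactly);
multinomial fits use the Hand-Till average of symmetrized pairwise
separabilities $[\hat A(k_1|k_2) + \hat A(k_2|k_1)]/2$; ordinal fits use the
mean of the $K-1$ cumulative-collapse AUCs. Rank statistics are invariant
to which site an observation came from, so pooling (label, score) pairs and
then computing equals computing on pooled data. Outcome labels are pooled
plainly here; privacy-protected variants of the evaluation step exist but
are outside this package's scope, as is any network transport.

## The simulation harness

`study_design()` and `run_study()` reproduce a four-study validation
design: $K = 4$; covariates $x_1, x_2 \sim N(0,1)$ and $x_3, x_4 \sim
\mathrm{Bernoulli}(0.5)$; an ordinal DGP with $\alpha = (-1, 0, 1)$ and
unit slopes (Studies 1-2, total $n$ = 1800 and 900) and a multinomial DGP
with $\alpha = (2, 3, 1)$ and slope vectors $(0.5,0.5,0.5,0.5)$,
$(2,2,2,2)$, $(1,1,1,1)$ (Studies 3-4, same sizes); three sites per study
with splits such as (600,600,600), (100,200,1500), (50,50,1700).

Two replication details are fixed here because the procedure description
leaves them open:

* **Halving before dealing.** Each replicate's pooled stream is halved
  first - the first $\lceil n/2 \rceil$ rows fit the model, the rest
  evaluate AUC and goodness of fit - and the fitting half is then dealt to
  sites per the split, site $u$ receiving $\lceil n_u/2 \rceil$ consecutive
  rows (for all six splits above these sum to exactly $n/2$). Each site
  thus holds half its nominal size for fitting, and the pooled fitting set
  is the same under every split, which is what makes a single common
  results column per study meaningful: the grid fit depends on the pooled
  fitting rows only.
* **Seeding.** A master seed spawns per-replicate seeds (`seed + r`), so
  any replicate can be reproduced in isolation.

`run_study()` reports per-coefficient bias, the empirical SD of estimates
across replicates, and the mean of model-based standard errors. The last
two agree closely for the ordinal studies; for multinomial intercepts at
$n_{\mathrm{fit}} = 450$ the empirical SD runs about 10% heavier (the
reference class is rare, giving occasional near-separated replicates with
heavy-tailed estimates), and the published per-coefficient "Se" values are
reproduced by the model-based mean. Replicates whose fit hits the
iteration cap (about 2% in Study 4, none elsewhere) are counted and
excluded, as their capped iterates are not MLEs.

What the generator does *not* emulate: covariate imbalance between sites,
site-level random effects, missing data, and model misspecification. The
passing tests therefore demonstrate the exactness of the federation algebra
and the calibration of the tests under a correctly specified model - not
robustness to the messiness of real multi-center data, where harmonization
and cluster effects are separate problems.

At these designs, 1000 replicates of all four studies run in about two
minutes on a single core; the acceptance script uses the full 1000 and the
equivalence checks use 100.

## Worked examples

`prepare_lbw()` codes the classic low-birth-weight table
(`MASS::birthwt`): birth weight cut at 3500/3000/2500 g into four
categories with category 1 the heaviest - under the $\alpha_w + \beta^T x$
link this gives smoking its expected negative slope - plus race indicators
against white and premature-labor/physician-visit indicators against zero.
Fitting the two-site split reproduces the published standard errors of all
eleven coefficients to within 0.002 and the SMOKE coefficient to within
0.002; the remaining point estimates differ by up to 0.09, consistent with
the circulating copies of this dataset not being identical (no observation
sits on a cutoff, so the boundary convention is not the cause). Our
estimates agree with an independent `MASS::polr` fit of the same data to
1e-6.

`prepare_mam()` codes the mammography-experience survey (response: never /
within a year / over a year ago; attitude and detectability items expanded
to reference-coded indicators). The source tables do not record which
levels anchored the published coding, so the reference levels are exposed
as arguments with the lowest level as default; the raw table is not
redistributed with any installed package, so this recipe is validated
structurally rather than against the published coefficients.

## Known limitations

* The generalized ordered logit is supported as a score-test alternative
  and for direct fitting on well-behaved data, but its parameter space is
  not constrained to monotone cumulative probabilities; expect non-finite
  likelihood errors when fitting it far from the proportional-odds null.
* The HL battery's all-pass rule makes the combined criterion conservative
  as $K$ grows (more collapses, more chances to fail); published
  discussion of these tests notes they can flag adequate fits.
* Wald inference uses the observed information; no small-sample or robust
  corrections are provided.
* The coordinator/site message layer is in-process; network transport,
  authentication and fault tolerance are out of scope.
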