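---
title: "Detecting additive interaction by constrained and penalized logistic regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting additive interaction by constrained and penalized logistic regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(addint)
```

## The problem

Epidemiologists usually ask whether two risk factors interact on the
*additive* scale, because public-health relevance is about risk differences:
if the joint effect of smoking and alcohol exceeds the sum of their separate
effects, intervening on either factor in the doubly exposed group prevents
more cases than the single-factor effects suggest. With odds ratios
$OR_{10}, OR_{01}, OR_{11}$ for the A-only, B-only and jointly exposed
groups against the unexposed group, departure from additivity is measured by
the interaction contrast

$$\mathrm{IC} = OR_{11} - OR_{10} - OR_{01} + 1,$$

and by three derived indices: the relative excess risk due to interaction
$\mathrm{RERI} = \mathrm{IC}$, the attributable proportion
$\mathrm{AP} = \mathrm{RERI}/OR_{11}$, and the synergy index
$S = (OR_{11}-1)/(OR_{10}+OR_{01}-2)$. Additivity holds exactly when
$\mathrm{RERI} = \mathrm{AP} = 0$ and $S = 1$, and these are equivalent —
yet confidence intervals computed separately for each index routinely
disagree about whether the null is excluded, which is confusing in
applications.

This package works directly with the equivalence. All estimation is done in
the combined-level logistic model

$$\mathrm{logit}\,p = \theta_0 + \theta_1 I(A_1B_0) + \theta_2 I(A_0B_1)
  + \theta_3 I(A_1B_1) + z^\top\gamma,$$

with the unexposed cell $A_0B_0$ as reference, so
$\mathrm{IC} = e^{\theta_3} - e^{\theta_1} - e^{\theta_2} + 1$ is a smooth
function of the coefficients. The model with a product term
$\beta_3 AB$ is the same fit ($\theta_1=\beta_1$, $\theta_2=\beta_2$,
$\theta_3=\beta_1+\beta_2+\beta_3$); the test suite verifies this
equivalence against `glm` on random tables.

Three routes to a verdict are provided:

1. **Confidence intervals** for RERI, AP and S — delta-method
   (`delta_ci()`) and outcome-stratified percentile bootstrap
   (`bootstrap_ci()`). No interaction is declared when the interval
   contains the null value (0, 0, 1 respectively; closed containment).
2. **Penalized estimation** (`penalized_fit()`, `lambda_path()`,
   `tune_lambda()`): minimize $-\ell(\theta) + \lambda\,|\mathrm{IC}(\theta)|$.
   The L1-type penalty shrinks the contrast exactly to zero once $\lambda$
   is large enough; if the $\lambda$ tuned by generalization error lands in
   that regime, the data support additivity.
3. **Model selection** (`select_interaction()`): fit the unconstrained
   model $M_1$ and the constrained model $M_2$ (maximum likelihood subject
   to $\mathrm{IC} = 0$) and compare them by
   $GAIC(\kappa) = \mathrm{GDEV} + \kappa\,df$ with $\kappa = 2$ (AIC),
   $\ln n$ (BIC), $2\ln\ln n$ (HQ), or by the likelihood-ratio test. Since
   the models differ by one constraint, a criterion prefers $M_1$ exactly
   when the deviance gap $\Lambda = \mathrm{GDEV}_2 - \mathrm{GDEV}_1$
   exceeds $\kappa$. For $n \ge 16$ the HQ penalty sits strictly between
   AIC's and BIC's (at $n = 15$, $2\ln\ln n = 1.993 < 2$, so the often
   quoted bound "from $n \ge 15$" is off by one; we document rather than
   hide this).

Routes 2 and 3 give one verdict for all three indices by construction,
which is their main appeal over route 1.

## Fitting details

**Unconstrained fit.** Without confounders the model is saturated and the
MLE has a closed form: each $\hat\theta_j$ is a log cross-product ratio
against the reference cell, the covariance is a sum of reciprocal cell
counts, and the log-likelihood is the cell-wise binomial one
(`saturated_from_counts()`). This closed form is also the per-resample
engine of the bootstrap. With confounders, the fit is IRLS via
`stats::glm.fit`. The reported log-likelihood is always the Bernoulli
$\sum_i y_i\eta_i - \log(1+e^{\eta_i})$, so deviances are comparable across
the count and subject-level paths.

**Constrained fit.** The additive-null manifold
$e^{\theta_3} = e^{\theta_1} + e^{\theta_2} - 1$ is parameterized globally
and smoothly by $(\theta_3, \phi)$ with

$$e^{\theta_1} = (e^{\theta_3}+1)\,\sigma(\phi), \qquad
  e^{\theta_2} = (e^{\theta_3}+1)\,(1-\sigma(\phi)),$$

$\sigma$ the logistic function. The obvious alternative — substituting
$\theta_3 = \log(e^{\theta_1}+e^{\theta_2}-1)$ — leaves a restricted domain
$e^{\theta_1}+e^{\theta_2} > 1$ that a line search can step out of; the
$(\theta_3,\phi)$ chart has no boundary and covers exactly the manifold, so
the reduced problem is unconstrained and solved by BFGS (gradient-norm
style convergence through `optim`'s relative tolerance $10^{-12}$, 200
iterations, never silently accepted). The covariance of the full
coefficient vector is recovered from the reduced inverse Hessian by the
delta method. A solution pushed to the boundary
$e^{\theta_1}+e^{\theta_2}\to 1^+$ is reported as non-converged.

**Delta intervals.** The gradients are
$(-e^{\theta_1}, -e^{\theta_2}, e^{\theta_3})$ for RERI,
$(-e^{\theta_1-\theta_3}, -e^{\theta_2-\theta_3},
(e^{\theta_1}+e^{\theta_2}-1)e^{-\theta_3})$ for AP, and the gradient of
$\log S$ for S, whose interval is built on the log scale and exponentiated
back. They are verified against central finite differences in the tests.
When $S$'s denominator $e^{\theta_1}+e^{\theta_2}-2$ is $\le 0$ (both
factors protective), or the point estimate of $S$ is $\le 0$, $S$ is an
explicit *undefined* value state — not an error — and such replicates are
excluded from simulation denominators with a logged count. Exclusion is the
only choice that does not silently convert an unanswerable question into a
verdict.

**Bootstrap.** Case-control designs fix the outcome margins, so resampling
is with replacement *within* cases and within controls, preserving both
stratum sizes exactly. The interval is the percentile interval — the
flavor is our choice (the applied literature this design follows reports
percentile intervals, and the fixed strata remove the main argument for
studentizing); BCa and bootstrap-t are out of scope. Without confounders
the resample is a multinomial draw of cell counts per stratum and the refit
is the closed form, which is distributionally identical to row resampling
and orders of magnitude faster; the row-level path remains for
confounder-adjusted data. A resample that empties a cell is, by default,
repaired by the Haldane–Anscombe correction (0.5 to all eight cells) inside
that resample only; the `"drop"` policy discards it without topping up, so
the denominator is the valid-resample count. Both are recorded in the
result's diagnostics; more than 50% degenerate resamples is a hard error.

**Penalized fit.** The absolute value is smoothed as
$s(x) = \sqrt{x^2+\varepsilon^2}$ with $\varepsilon = 10^{-8}$, small
enough that the smoothing is invisible at the scale of the likelihood.
Because BFGS can stall a hair off the kink at $\mathrm{IC}=0$, each
penalized fit is run from two warm starts — the previous path solution and
the exactly constrained fit — keeping the better optimum. A solution with
$|\mathrm{IC}| < 10^{-4}$ is snapped to the exact constrained fit and
flagged, which makes verdicts independent of $\varepsilon$. The default
grid is 41 log-spaced points in $[10^{-3}, 10^3]$: wide enough that the
small end reproduces the MLE and the large end the constrained fit on any
reasonably sized dataset, and user-overridable. Along increasing $\lambda$
the achieved $|\mathrm{IC}|$ is non-increasing and the training
$-\ell$ non-decreasing (tested); each solution also solves the
$t$-constrained problem with $t = |\mathrm{IC}(\hat\theta(\lambda))|$.

**Tuning.** $\lambda$ is chosen by generalization error: one random split
(default two thirds training), the path fitted on the training part, and
the $\lambda$ minimizing the held-out deviance chosen, ties broken toward
the larger $\lambda$ (the simpler model). K-fold would average away some
split noise but the single split matches the procedure this package
mirrors and keeps the verdict attributable to one fit; a split missing an
exposure level in either part is redrawn up to 10 times.

## The simulation harness

`generate_dataset()` draws each subject's exposure cell from a multinomial
with equal probabilities $1/4$ and the outcome from the cell's logistic
probability with baseline $\theta_0 = 0$ (baseline risk one half,
configurable). The seven standard scenarios fix $OR_{10}=4$, $OR_{01}=5$
and sweep $OR_{11}$ from 20 (strong synergy) through 8 (exact additivity)
to 2 (strong antagonism). `run_experiment()` runs 1000 seeded replicates
per condition by default (per-replicate seeds are spawned once from the
master seed, so results do not depend on evaluation order), applies the
nine methods (three criteria, three delta intervals, three bootstrap
intervals at 300 resamples) and reports the fraction of no-interaction
verdicts. The acceptance script exercises scenario S2 at $n = 400$ for the
delta and bootstrap RERI intervals and scenario S4 at $n = 400$ for HQ,
at 1000 replicates; the test suite uses 150–1000 replicates per property,
sized so the full suite runs in about a minute.

**What the generator does and does not emulate.** It reproduces a
prospective Bernoulli draw under the exact four-cell logistic model — no
confounding, no misclassification, no case-control sampling of the outcome.
Two consequences matter for interpreting results. First, with
$\theta_0 = 0$ the exposed cells are case-heavy (e.g. $p_{11} = 16/17$ in
S2), so controls are scarce exactly where the interaction information
lives; interval methods are therefore noticeably more conservative here
than under designs that fix the case/control margins, and absolute
no-interaction fractions from this harness are not comparable to studies
using such designs, even though *relative* statements (HQ tracks the
bootstrap within about 2 percentage points everywhere; the three bootstrap
indices agree to three decimals; AIC flags more interactions than HQ than
BIC) reproduce robustly. Second, passing simulation tests says nothing
about confounded or measured-with-error data; the confounder path is
exercised only structurally.

## Degenerate inputs and numerical conventions

* Empty exposure cell: fitting errors name the cell; the opt-in
  `continuity_correct()` (0.5 to all eight cells) is the only correction,
  and it marks its output.
* Separated cell (all cases or all controls): explicit error pointing to
  the correction, never a silent huge coefficient.
* All-one-outcome data: degenerate-data error.
* $\Lambda$ is floored at 0 before the $\chi^2_1$ tail; exactly equal GAIC
  prefers the constrained model (parsimony).
* $n$ in BIC/HQ is the number of subjects, not of cells.
* Likelihood overflow is guarded (`log1p(exp(x))` switched to $x$ for
  large $x$).

## Known limitations

* The generalization-error verdict under an exactly additive truth is
  close to a coin flip regardless of sample size: a single held-out split
  cannot consistently separate models that differ by one degree of
  freedom (the same reason cross-validation is inconsistent for model
  selection). The model-selection route (HQ in particular) is the
  recommended verdict; the tuned path is best read as a description of how
  the contrast shrinks, with its verdict trusted mainly when it keeps a
  nonzero contrast under strong interaction.
* The delta interval for $S$ requires $\hat S > 0$; antagonistic data can
  produce undefined $S$ verdicts, which the simulation harness counts and
  excludes.
* Only two binary factors are handled; Cox or log-binomial variants of the
  measures and Bayesian intervals are out of scope.

## Worked example

```{r}
tab <- oral_cancer_counts()
select_interaction(tab)
delta_ci(fit_unconstrained(tab), "RERI")
bootstrap_ci(tab, "RERI", bootstrap_spec(seed = 1))
```

The deviance gap of about 1.80 is below every criterion's penalty
($\kappa \ge 2$), so all three criteria keep the additive model, and both
interval routes agree: no additive interaction between smoking and alcohol
use on oral cancer risk in these data — with the constrained coefficients
satisfying $e^{\hat\theta_3} - e^{\hat\theta_1} - e^{\hat\theta_2} + 1 = 0$
exactly, so RERI $=0$, AP $=0$ and $S=1$ simultaneously.
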