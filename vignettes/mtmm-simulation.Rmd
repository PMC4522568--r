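---
title: "Simulating model–design mismatch in multitrait-multimethod factor analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating model–design mismatch in multitrait-multimethod factor analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Multitrait-multimethod (MTMM) measurement designs cross a construct with
several assessment methods — raters, instruments, item formats. A
long-standing distinction separates *interchangeable* methods (drawn from an
exchangeable pool, e.g. randomly selected student raters) from *structurally
different* methods (fixed and non-exchangeable, e.g. self- vs parent-report).
Each implies a different confirmatory factor model, and fitting the wrong one
produces a characteristic pathology: method factors whose loadings are all
jointly non-significant ("method-factor collapse"), Heywood cases, and
optimizers that never converge — while global fit indices look fine.

`mtmmsim` implements a Monte Carlo laboratory for this phenomenon in the
single-trait, three-method, three-indicators-per-method design. It generates
populations from two data-generating structures, fits four competing model
structures by normal-theory maximum likelihood, and aggregates four outcome
families: non-convergence, improper solutions, fit-index rejections, and
method-factor collapse.

## The model space

Nine observed variables $Y_{im}$ ($i$ = indicator, $m$ = method), ordered
method-major ($Y_{11}, Y_{21}, Y_{31}, Y_{12}, \dots, Y_{33}$). Every model
decomposes the covariance matrix as

$$\Sigma(\theta) = \Lambda \Psi \Lambda^\top + \Theta,$$

with one trait factor, up to three method factors, all factor variances fixed
to 1 for identification, trait–method covariances fixed to 0, diagonal
$\Theta$, and no mean structure. The four families differ in their loading
constraints and latent correlation structure:

| family | trait loadings | method loadings | method correlations | free parameters | df |
|---|---|---|---|---|---|
| `UM_constrained` | 3 (equal across methods) | 3 (equal across methods) | fixed 0 | 15 | 30 |
| `CMm1` | 9 | 6 (none for the reference method) | 1 | 25 | 20 |
| `UM_unconstrained` | 9 | 9 | fixed 0 | 27 | 18 |
| `CM` | 9 | 9 | 3 | 30 | 15 |

`UM_constrained` is the structure implied by interchangeable methods
(loading invariance across methods); `CMm1` — the correlated methods-minus-one
structure — is the structure implied by structurally different methods, with
method 1 as the default reference. `UM_unconstrained` and `CM` are the
highly parameterized structures common in empirical practice. Equality
constraints are encoded declaratively by label sharing: the constrained
model's trait loading for indicator $i$ carries the single label `lam_i` at
all three method positions, so constrained parameters move in lockstep by
construction rather than via penalty terms.

Nesting follows from the parameter counts: every constrained-model
covariance structure is attainable by the unconstrained model, and every
unconstrained or methods-minus-one structure by the correlated-methods
model. The test suite verifies this by refitting the wider family to implied
covariances of the narrower one.

## Population synthesis

Populations are parameterized by two interpretable quantities under unit
trait, method and indicator variances:

* **consistency** $con = \lambda^2 / (\lambda^2 + \gamma^2)$ — the share of
  an indicator's true-score variance due to the trait;
* **reliability** $rel = \lambda^2 + \gamma^2$ — the share of observed
  variance that is true-score variance.

Inverting gives $\lambda = \sqrt{rel \cdot con}$,
$\gamma = \sqrt{rel(1 - con)}$, $\theta = 1 - rel$, positive roots throughout
(loading signs are not identified; positivity matches the consistency
parameterization). Reference-method indicators of `CMm1` populations carry no
method factor, so $\lambda = \sqrt{rel}$ there.

The design grid crosses two population families with $N \in \{250, 1000\}$,
nine consistency levels $\{0.1, \dots, 0.9\}$, three reliability bases
$\{0.6, 0.7, 0.8\}$, and — for `CMm1` populations — method-factor
correlations $\{0.2, 0.5, 0.8\}$: $54 + 162 = 216$ population cells, each fit
by all four families, 864 grid entries. Consistency 0 is rejected (a zero
trait loading leaves the trait factor empirically empty and unidentified).

Reliabilities are jittered around the base level by
$(b - 0.5) \cdot 0.05$ with $b \sim \mathrm{Beta}(3,3)$, so each indicator's
reliability stays within $\pm 0.025$ of the base with the base as its
expectation — enough to keep indicators from being exactly parallel. Two
choices the design leaves open are resolved as follows:

* **Jitter is drawn once per cell** and held fixed over the cell's
  replications, so each cell has a single, fixed population covariance.
  Redrawing per replication would make every per-cell rate a mixture over
  populations and blur the interpretation of cell-level summaries.
* **Constrained populations jitter per indicator** (3 draws reused across
  methods), because method-varying population loadings would contradict the
  loading-invariance structure that defines that family. Methods-minus-one
  populations jitter all nine positions independently.

Samples are i.i.d. multivariate normal with mean zero; the sample covariance
uses the $N-1$ divisor, which pairs with the Wishart $\chi^2$ convention
below. What the generator deliberately does *not* emulate: non-normality,
missing data, ordinal indicators, mean structures, multiple traits. Passing
tests therefore speak to the estimation geometry of these models under clean
conditions, not to robustness under realistic data blemishes.

## Maximum-likelihood estimation

The estimator minimizes the normal-theory discrepancy

$$F_{ML}(\theta) = \ln|\Sigma(\theta)| + \mathrm{tr}\,(S\,\Sigma(\theta)^{-1})
  - \ln|S| - 9$$

by BFGS with the analytic gradient
($\partial F/\partial \Sigma = \Sigma^{-1} - \Sigma^{-1} S \Sigma^{-1}$,
chained through $\Lambda$, $\Psi$, $\Theta$ with shared labels accumulating
their contributions). Three design choices matter for the simulation
outcomes and are therefore spelled out:

* **Parameters are unbounded.** Negative error variances and correlations
  outside $[-1, 1]$ are representable, so improper solutions are observable
  events rather than being masked by box constraints. Only positive
  definiteness of $\Sigma(\theta)$ is enforced, by the line search: steps
  leaving the PD cone are halved away, and a search that cannot find a
  positive-definite decreasing step ends the fit as non-converged.
* **Line search.** A weak-Wolfe bisection search (Armijo constant $10^{-4}$,
  curvature constant $0.9$, at most 60 trials). The curvature condition
  guarantees update pairs with $s^\top y > 0$, which keeps the BFGS inverse
  Hessian useful on the ill-conditioned ridge problems that mismatched
  models produce; with a backtracking-only search the same fits crawl and
  time out far more often. The first accepted step rescales the initial
  inverse Hessian by $s^\top y / y^\top y$.
* **Convergence criterion.** A fit converges when the largest absolute
  gradient entry falls below $3 \times 10^{-5}$; otherwise it is
  non-converged at 1000 iterations (or at a stalled line search).
  Non-convergence *rates* are not a property of the model alone — they
  depend on the optimizer's stopping dialect, because the interesting
  failures are flat likelihood ridges along which mismatched overparameterized
  models drift to extreme correlations with tiny but nonzero gradients.
  The criterion is a derivative criterion in the dialect of mainstream SEM
  software, whose documented default derivative tolerance of
  $0.5 \times 10^{-4}$ brackets our value across the two common objective
  scalings ($F_{ML}$ vs the per-observation log-likelihood $F_{ML}/2$,
  which halves every gradient entry). A stricter dual rule (gradient
  *and* relative parameter change) is available via `fit_ml(gtol=, xtol=)`;
  it reclassifies a sizable share of converged-but-improper ridge fits as
  non-converged and correspondingly shrinks the improper-solution rates.
* **Starting values** are deterministic and scale-aware: trait loadings
  $\sqrt{0.5\,S_{ii}}$, method loadings $\sqrt{0.25\,S_{ii}}$, error
  variances $0.5\,S_{ii}$, correlations 0; shared labels start at the mean
  of their per-position values. No multistart — a single documented start
  keeps rates interpretable and runs reproducible.

Standard errors come from the inverse of the observed information of
$\tfrac{N-1}{2} F_{ML}$, with the Hessian obtained by central finite
differences of the analytic gradient. Singular information (common exactly
when a method factor has collapsed) yields `NA` standard errors with a log
note rather than an error.

Improper solutions are flagged for converged fits only: a Heywood case
(`theta_npd`) is any negative error variance; `psi_npd` holds when the
latent correlation matrix over the model's active factors has an eigenvalue
below $-10^{-8}$.

## Fit evaluation

The model $\chi^2$ is $T = c\,F_{ML}$ with $c = N-1$ by default (the
"wishart" dialect, matching the $N-1$ covariance divisor; $c = N$
available). With $p^*$ free parameters, $df = 45 - p^*$. Then

* RMSEA $= \sqrt{\max(T - df,\, 0) / (df \cdot c)}$ — the denominator moves
  with the dialect so the two always pair coherently;
* CFI $= 1 - \max(T - df, 0)\,/\,\max(T - df,\ T_b - df_b,\ 0)$ with the
  independence baseline fit in closed form
  ($T_b = c\,[\sum_i \ln S_{ii} - \ln|S|]$, $df_b = 36$) — no second
  optimization;
* SRMR $= \sqrt{\tfrac{1}{45}\sum_{i \le j}
  \big[(S_{ij} - \hat\Sigma_{ij})/\sqrt{S_{ii}S_{jj}}\big]^2}$, including
  the nine diagonal residuals (the 36-cell off-diagonal variant is a
  switch).

Rejection rules: $\chi^2$ $p$-value $< 0.05$, RMSEA $> 0.05$, CFI $< 0.95$,
SRMR $> 0.05$; boundary values count as acceptable. Rejection rates are
reported among converged fits by default (switchable to the
requested-replications denominator).

Two properties of these indices under this design deserve emphasis, because
they bound what any reimplementation can reproduce:

* **CFI is saturated.** The populations have within-method correlations
  approximately equal to the reliability (0.6–0.8), so the independence
  baseline is violated enormously: $T_b - df_b$ is on the order of 800–1200
  at $N = 250$. A correct model with $T \approx df$ then has
  $\mathrm{CFI} \ge 0.98$ in essentially every replication — CFI cannot
  reject a well-fitting model here. A CFI rejection rate materially above
  zero for the correct constrained model would require baseline chi-squares
  two orders of magnitude smaller than these populations produce.
* **SRMR sits on its cutoff at $N = 250$.** A correct model absorbs about
  $p^*$ of the 45 standardized moments, leaving an expected SRMR near
  $\sqrt{(df/45)\,(1 + r^2)/N}$, which is approximately 0.05 for the
  constrained model at $N = 250$. Roughly half the replications therefore
  land above the 0.05 cutoff at the small sample size, while at $N = 1000$
  SRMR rejections vanish. This is a property of the index and the design,
  not of the estimator.

## Collapse detection

A loading is non-significant when its 95% Wald interval contains zero,
i.e. when $|\hat\beta| \le z_{0.975}\,\widehat{SE}$; significance requires
the $z$-ratio to exceed the critical value strictly, so an exact boundary
counts as non-significant. A method factor *collapses* when all three of its
loadings are jointly non-significant. The 18 loadings are grouped in six
sets of three (sets 1–3: trait loadings of methods 1–3; sets 4–6: method
loadings of methods 1–3); in a fitted methods-minus-one model set 4 is zero
by construction and excluded from collapse statistics. Loadings with
unavailable standard errors are indeterminate and do not count as
non-significant unless explicitly requested — this keeps singular-information
fits from inflating collapse rates by bookkeeping alone.

One empirical regularity is worth flagging: collapse frequency for
unconstrained-model fits to methods-minus-one data rises with consistency at
every correlation level, but is *not* monotone in the method-factor
correlation at moderate consistency — the low-correlation condition shows
elevated collapse of the *first* method factor while the moderate condition
is nearly clean below consistency 0.8. Monotonicity in the correlation holds
in the high-consistency regime, and the test suite asserts it there.

## Simulation harness

`run_cell()` draws one dataset per replication and fits every requested
family to that same dataset, so fitted families are always compared on
identical data. Per-replication seeds derive from
(master seed, cell index, replication index) through an integer hash that is
exact in double arithmetic; replication index 0 is reserved for the cell's
reliability jitter. Cells are therefore independent, order-insensitive work
units, and an entire run is reproducible from one master seed. A crashed fit
is logged and counted as non-converged rather than propagating.

Outcome denominators follow the study's definitions: percent convergence and
the two improper-solution percentages divide by *requested* replications;
rejection and collapse rates divide by *converged* fits by default, with the
denominator recorded in every summary row.

The default profiles are scaled down from the full 1000-replications-per-cell
study: the bundled acceptance script uses 25 replications per cell for the
full-grid sweep (21,600 fits), 100 and 50 for the two correlated-methods
pools, and 200 for the CFI panel — sizes at which the binomial standard
error of a pooled percentage is a fraction of a point, so the headline rates
are stable while a complete run stays in the minutes range. All report
tables carry their replication counts.

## Known limitations

* Absolute non-convergence rates are reproducible only up to the stopping
  dialect; the package documents its dialect and exposes the stricter one.
* The split of improper solutions between negative error variances and
  out-of-range correlations is optimizer-specific: on an empirically
  underidentified ridge, *which* boundary the estimate escapes through
  depends on the search geometry. The combined improper-solution rate is
  the stable quantity.
* Standard errors use observed information; expected-information standard
  errors would differ slightly in small samples.
* The auxiliary regression over simulation conditions, multi-trait designs,
  mean structures, and non-normal or incomplete data are out of scope.
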