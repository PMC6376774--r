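---
title: "Dynamic prediction of recurrent and terminal events with landmark pseudo-observations"
author: "dynpseudo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic prediction of recurrent and terminal events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynpseudo)
```

## The prediction problem

In follow-up studies of diseases with repeated events of the same type —
the motivating setting is tumor recurrence after curative resection, where
a patient can recur, be re-resected, and recur again, and where death ends
the process — clinicians want *dynamic* risk statements: given that a
patient is alive and uncensored ("at risk") at time $s$ after baseline,
what is the probability of experiencing exactly $k$ recurrences within the
next $w$ years, and what is the probability of dying within that window?

Write $T^*_k$ for the $k$-th recurrent event time counted from the
landmark time $s$ (a patient with two events before $s$ has their third
overall event relabeled as $T^*_1$), $T^D$ for the terminal-event time and
$w > 0$ for the prediction window.  The targets are the mutually exclusive
conditional probabilities

$$F_k(s+w \mid s) = \Pr\!\left(T^*_k \le s+w,\; T^*_{k+1} > s+w,\;
  T^D > s+w \,\middle|\, T^D > s\right), \qquad k = 0, 1, \dots$$

$$F^D(s+w \mid s) = \Pr\!\left(T^D \le s+w \mid T^D > s\right),$$

which sum to one together.  Event counts at or above a cap `k_max` are
pooled into a top category ("$k_\max$ or more"), mirroring clinical usage
("multiple recurrences").

Landmarking handles time-dependent information without a joint
longitudinal model: at each landmark $s$ on a grid, the risk set is formed
from the subjects still under observation, covariates are frozen at their
value at $s$ (including derived summaries such as the number of prior
events), and the analysis conditions on being at risk at $s$.

### Conventions at the boundary

The data generating process is continuous, but observed data may contain
boundary ties, so the package fixes the conventions explicitly (they are
choices, not consequences of the definitions):

* a recurrent event at exactly time $s$ counts toward the prior-event
  count, not the window; window events live in the half-open interval
  $(s, s+w]$;
* a terminal or censoring time exactly equal to $s$ removes the subject
  from the risk set (strict inequality defines "at risk");
* a recurrent and a terminal event recorded at the identical instant for
  one subject is rejected as invalid input: the multi-state model
  underlying the estimators has no simultaneous two-step transition.

## Dynamic pseudo-observations

If nobody were censored, $F_k$ would be estimated by the sample average
of per-subject indicators.  Under censoring the indicator is unknown for
censored subjects; pseudo-observations replace it by each subject's
leave-one-out jackknife contribution to a consistent estimator
$\widehat F_k$ computed within the landmark risk set of size $n_s$:

$$\widehat\theta_{ik}(s) = n_s \widehat F_k(s+w \mid s)
  - (n_s - 1) \widehat F_k^{(-i)}(s+w \mid s),$$

and analogously $\widehat\theta^D_i(s)$ for the terminal category.  With
no censoring these are exactly the 0/1 category indicators; in general
they may fall outside $[0, 1]$, which is expected and deliberately left
untouched — clipping would bias the regression stage.  Each leave-one-out
estimate is an honest re-estimation on the $n_s - 1$ remaining subjects
(no analytic update formulas); at the sample sizes this method targets
(around $10^2$ at-risk subjects per landmark) the $O(n_s)$ refits cost
milliseconds.

Two estimators of the category probabilities are provided.

**Aalen–Johansen route** (`dpo_aj()`).  The event process is a
progressive multi-state chain $0 \to 1 \to \dots \to k_\max$, with an
absorbing death state $D$ reachable from every transient state when the
terminal event is modeled.  The transition probability matrix over
$(s, s+w]$ is the product-integral of the empirical transition-hazard
increments $\mathrm d\widehat A_{qr}(u) = N_{qr}(u) / Y_q(u^-)$, and
since every at-risk subject occupies state 0 at the landmark, the
category probabilities are row 0 of the cumulative matrix.  All
transitions at a tied time enter the same $(I + \mathrm d\widehat A(u))$
factor with risk sets taken just before $u$.  With zero censoring the
product-integral reproduces the empirical state proportions exactly,
whether or not the process is Markov, so its use does not rest on a
Markov assumption for state occupation.

**Kaplan–Meier route** (`dpo_km()`).  Without a terminal state the
ordering of the event times gives
$F_k = S^*_{k+1}(s+w) - S^*_k(s+w)$, where $S^*_k$ is the survival
function of $T^*_k$, estimated by the product-limit estimator with
subjects lacking event $k$ censored at their end of observation (a
terminal endpoint is treated as censoring on this route).  This avoids
matrix computation entirely.  Under heavy censoring the estimated
ordered-event curves can cross and produce slightly negative interior
$\widehat F_k$; the values are returned as computed, with a warning.
The state-occupation estimator cannot go negative — an asymmetry the
test suite checks in both directions.

### Exactness of the averaging identity

The mean of jackknife pseudo-values, $n\widehat F - (n-1)
\overline{\widehat F^{(-i)}}$, coincides with the full-sample estimate
exactly for the Kaplan–Meier route — provided the estimated curves remain
positive at $s + w$; when censoring drives a curve to zero the identity
breaks down at the boundary — and for the Aalen–Johansen route in the
two-state chain (where it reduces to Kaplan–Meier) and under no
censoring.  For the censored multi-state chain the product-integral is
not a linear statistic and the averaging identity holds only up to a
small higher-order term.  The *dynamic predicted value* of the
evaluation harness is therefore defined as the full-sample estimate
itself (the quantity the pseudo-observation mean is meant to recover);
`run_scenario(..., predicted = "dpo_mean")` selects the jackknifed
column mean instead, which is identical wherever the identity holds and
strictly noisier under heavy censoring where it does not.

## The regression stage

Collect the non-reference pseudo-observations
$\widehat{\boldsymbol\theta}_i(s)$ (the zero-event category is the
reference; dropping it removes the redundancy created by the sum-to-one
constraint) and model them through a generalized-logit link,

$$\theta_c(\mathbf Z) = \frac{\exp(\eta_c)}{1 + \sum_{c'} \exp(\eta_{c'})},
\qquad \eta_c = \boldsymbol\beta_c^\top (1, \mathbf Z_i(s)^\top)^\top,$$

solving the multinomial estimating equation
$\sum_i \mathbf D_i^\top \mathbf V_i^{-1}
(\widehat{\boldsymbol\theta}_i - \boldsymbol\theta_i) = \mathbf 0$ with
$\mathbf V_i$ the multinomial covariance
$\mathrm{diag}(\boldsymbol\theta_i) -
\boldsymbol\theta_i\boldsymbol\theta_i^\top$ at the current fit.  Because
the generalized logit is the canonical link for this covariance, the
quasi-score has the usual IRLS structure and is solved by Fisher scoring.

Two model shapes are available:

* **Fixed-landmark model** (`fit_landmark_gee()`): one landmark,
  model-based covariance $\{\sum_i \mathbf D_i^\top \mathbf V_i^{-1}
  \mathbf D_i\}^{-1}$.
* **Supermodel** (`fit_landmark_supermodel()`): pseudo-observation blocks
  stacked over the landmark grid, every coefficient multiplied by the
  polynomial basis $f_b(s) = s^b$, $b = 0, \dots, h$ ($f_0 \equiv 1$), so
  that $\boldsymbol\beta(s) = f(s)\cdot\boldsymbol\beta$ varies smoothly
  in $s$.  Working independence is used across a subject's blocks (the
  estimating equation stays consistent under any true dependence), and
  the covariance is the robust sandwich $A^{-1} B A^{-1}$ clustered by
  subject.

Predicted probabilities come from the inverse link; their standard errors
from the delta method, with Wald intervals truncated to $[0,1]$.  The
truncation scale is a display choice; interval transformation scales
(logit, complementary log-log) would be alternatives, but the Wald
interval on the probability scale matches how stacked prediction curves
with error bars are usually drawn.

### Numerical choices

* Fisher scoring from $\boldsymbol\beta = \mathbf 0$, step-halving
  whenever a step fails to reduce the score norm; convergence at
  $\max_j |U_j| < 10^{-8}$ or relative coefficient change $< 10^{-10}$;
  at most 100 iterations, error on non-convergence.
* Fitted probabilities are floored at $10^{-10}$ (and capped at
  $1 - 10^{-10}$) before building $\mathbf V_i$, so boundary fits with
  empty categories cannot produce singular working covariances.
* Landmark times are centered at the grid midpoint before taking powers:
  a raw cubic basis over a grid like $0,\dots,5$ years is badly
  conditioned.  Coefficients are reported on the centered scale and
  `uncenter_coefficients()` maps them back to powers of raw $s$.
* Rank-deficient expanded designs are rejected up front, naming the
  collinear columns, rather than silently pivoting.
* A `working = "binary"` option replaces $\mathbf V_i$ in the weighting
  (not in $\mathbf D_i$) by its diagonal — the multivariate-binary
  workaround usable with standard binomial software.  It reproduces the
  multinomial point estimates exactly in saturated designs and serves as
  a cross-check; the multinomial weighting is the primary formulation.
* The product-limit estimator evaluated beyond the last observed time
  carries the last value forward and warns: the positivity assumption on
  the censoring distribution up to $s+w$ is the user's responsibility,
  and the fraction of the risk set remaining near $s+w$ is the practical
  diagnostic.

## The synthetic cohort generator

`scenario()` / `simulate_cohort()` generate the evaluation conditions:
per subject a frailty $u_i$ (constant 1, or gamma with shape and rate
0.5, hence mean 1 and variance 2), then

$$t_{i1} \sim \mathrm{Exp}(u_i\lambda_{01}), \quad
  t_{i2} - t_{i1} \sim \mathrm{Exp}(u_i\lambda_{02}), \quad
  t_{iD} \sim \mathrm{Exp}(u_i\lambda_{0D}),$$

with independent censoring $c_i \sim \mathrm{Exp}(\lambda_c)$.  The
shared frailty induces all dependence between a subject's times; for the
gamma(0.5, 0.5) frailty the Kendall's tau of any pair is
$\mathrm{var}(u)/(\mathrm{var}(u) + 2) = 0.5$.  $\lambda_{01} =
\lambda_{02}$ gives a Markov chain; $\lambda_{02} > \lambda_{01}$ a
semi-Markov acceleration after the first event.  Repeated events are
capped at two under the default conditions ($n = 100$, unit event
hazards, $\lambda_{0D} \in \{0, 0.3\}$, $\lambda_c \in \{0.5, 2\}$,
horizon 1); the cap is a parameter (`max_events`), with gaps i.i.d.
beyond the second event, so higher event counts are exercisable.

Per replication, the *true values* are the empirical category proportions
computed from the same subjects' latent (uncensored) times — paired
truth, not the analytic limit; the closed forms ($e^{-1}$, $e^{-1.3}$,
$1 - e^{-0.3}$, …) are kept separately as oracles in the tests.  A single
R RNG stream per cohort (seeded once) makes cohorts byte-reproducible;
the package never parallelises, so per-subject substreams are
unnecessary.

What the generator does *not* emulate: covariate-dependent hazards (the
demonstration covariates are noise by design), non-exponential baselines,
informative censoring, and interval censoring.  Passing tests on this
generator therefore show calibration and internal consistency of the
estimators and regression machinery under the stated conditions — not
performance under covariate-driven heterogeneity or misspecified
censoring.

## The evaluation harness

`run_scenario()` repeats: simulate a cohort, form the risk set at
$s = 0$ with window $w$ = horizon, compute the dynamic predicted values
for each estimator on the *same* cohort (paired arms isolate the
estimator difference), and compare with that replication's true values.  Reported per category: bias (mean of
predicted minus true), RMSE, and Monte Carlo standard errors of both (the
RMSE's via the delta method from the variance of squared errors), so
scaled-down runs remain honestly comparable.  `rmse_ratio_table()` forms
the AJ/KM efficiency ratios; with uncensored data both estimators are
exact and a 0/0 ratio is reported as 1.

Because the exact definition of the "censored proportion" summary
attached to such designs is ambiguous, the report carries three candidate
definitions (censored before the horizon; censored before both latent
events and the horizon; censoring observed as the endpoint before the
horizon) and asserts none of them.

Problem sizes used by the package's own test suite: truth calibration at
1000 replications; pseudo-observation accuracy at 200 replications with
comparisons at three Monte Carlo standard errors; efficiency ratios at
200 paired replications per scenario; the acceptance script runs the full
eight-scenario grid at 1000 paired replications.

## The demonstration model

`demo_supermodel()` exercises the full pipeline in the clinical shape of
the motivating application: 263 patients, yearly landmarks $0,\dots,5$,
3-year window, categories \{no recurrence, one recurrence, multiple
recurrences, death\}, three binary covariates (prior recurrence at the
landmark — a landmark-dependent covariate, carried rather than
stratified —, multiple tumors, tumor > 2 cm) and cubic smoothers, giving
3 categories × 4 bases × 4 design columns = 48 coefficients with robust
standard errors (32 when the terminal state is dropped and death is
treated as censoring on the KM route).  The covariate effects are
synthetic noise: the demo validates structure, convergence and the
sum-to-one of stacked predicted probabilities, not effect recovery.

```{r demo, eval = FALSE}
demo <- demo_supermodel(seed = 1)
demo$fit
head(demo$coefficients)
head(demo$predictions)
```

## Known limitations

* Only the generalized-logit link is implemented (the estimating-equation
  machinery does not depend on it, but no other link is tested).
* Polynomial smoothers only; no splines.
* Covariates are frozen at the landmark; trajectory modeling of
  longitudinal covariates is out of scope.
* Prediction-accuracy measures for the fitted regressions (Brier score,
  calibration curves) are not provided; the evaluation harness measures
  the pseudo-observation stage.
* The supermodel refuses to extrapolate outside the fitted landmark
  range, by design: polynomials are untrustworthy beyond the grid.
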