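---
title: "Calibrating a colorectal-cancer natural-history model with incremental mixture ABC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating a colorectal-cancer natural-history model with incremental mixture ABC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcabc)
```

## The natural-history model

`crcabc` simulates individual colorectal-cancer histories through the
adenoma–carcinoma sequence. Four components describe each agent's disease
process, governed by 22 calibrated parameters plus two fixed inputs (the
minimum and maximum adenoma diameters, `d0 = 1` mm and `d_infinity = 50` mm):

1. **Adenoma risk.** Adenomas arise in agent $i$ according to a
   non-homogeneous Poisson process with intensity $\psi_i(a)$, where
   $\ln\psi_i(a)$ is piecewise linear in age with knots at 50, 60 and 70
   years, slope parameters $\alpha_{20},\alpha_{50},\alpha_{60},\alpha_{70}$,
   a female offset $\alpha_1$, a person-level intercept
   $\alpha_{0i}\sim N(A,\sigma_\alpha)$ (we read $\sigma_\alpha$ as a
   standard deviation), and zero risk before age 20.
2. **Adenoma growth.** Each adenoma draws a hypothetical time to reach
   10 mm from a Fréchet distribution,
   $F(t)=\exp[-(t/\beta_2)^{-\beta_1}]$, with separate shape/scale pairs
   for colon and rectum. Diameter follows the Richards curve
   $d(t)=d_\infty[1+((d_0/d_\infty)^{1/p}-1)e^{-\lambda t}]^p$; the
   per-adenoma rate $\lambda$ is obtained in closed form by forcing
   $d(t_{10mm}) = 10$ mm.
3. **Transition to preclinical cancer.** The size at transition is
   lognormal; its log-mean is linear in sex, location, their interaction,
   and the initiation age in decades centred at 50 (`(init_age - 50)/10`),
   with log-sd $\sigma_\gamma$. An adenoma becomes a preclinical cancer
   exactly when its trajectory reaches its drawn transition size, so larger
   lesions are more likely to have transitioned.
4. **Sojourn time.** Time from preclinical to clinical (symptomatic)
   cancer is Weibull with survival $S(t)=\exp[-(t/\lambda_1)^{\lambda_2}]$
   in the colon. For rectal cancers we multiply the scale by
   $e^{\lambda_3}$ (an accelerated-scale formulation), which makes the mean
   sojourn times exactly $\lambda_1\Gamma(1+1/\lambda_2)$ and
   $\lambda_1 e^{\lambda_3}\Gamma(1+1/\lambda_2)$. A proportional-hazards
   reading of the location effect would instead scale the mean by
   $e^{-\lambda_3/\lambda_2}$; we adopt the scale-multiplier convention
   because it is the one consistent with those closed-form means, and
   `mean_sojourn_time()` implements them.

Other-cause mortality uses a synthetic life table
(piecewise-constant hazards rising with age, capped at 100 years). It is a
structural stand-in for a national life table: it imposes realistic
censoring, but its absolute levels are not calibrated to any registry.
Stage and size at clinical detection, and survival after diagnosis, are
out of scope; clinical detection ends a trajectory.

Adenoma location is a single colon/rectum split with a configurable rectal
probability (default 0.25), a deliberate simplification of full
multi-segment anatomy; it is exactly the knob exercised by the
location-specific growth and sojourn parameters.

### Sampling choices

Initiation events are drawn by thinning with a per-segment constant
majorant: between knots the log-intensity is linear, so the segment maximum
sits at an endpoint and thinning is exact, with no discretisation bias.
Fréchet, Weibull and truncated-normal draws use inverse-CDF sampling.
Each agent owns a counter-based random stream derived from the population
seed and the agent's index (a splitmix64 hash), so simulated outcomes are
reproducible per agent and invariant to agent ordering and to batch
partitioning. The population core is compiled (Rcpp) because calibration
evaluates the simulator thousands of times; `simulate_agent()` is a plain-R
reference implementation of the same process used for inspection and
cross-checking in the test suite.

## Screening and calibration targets

Colonoscopy sensitivity for adenomas is a monotone piecewise-linear
function of diameter through the anchors (5 mm, 0.81), (10 mm, 0.92),
(15 mm, 0.98), extended to 0.70 at 1 mm and 1.0 at 20 mm and above; the
sub-5 mm and supra-15 mm behaviour is declared interpolation, not an
estimate of any published miss-rate curve. Preclinical-cancer sensitivity
is the maximum of 0.95 and the size-based value, so it equals 0.95 up to
12 mm. Flexible sigmoidoscopy reaches all rectal lesions and a configurable
fraction (default 0.4) of colon lesions — a distal-colon stand-in, since
the model does not resolve colon segments. Detected lesions are removed;
only one-time screens are modelled.

Calibration targets are summary statistics with accept bands. The final
tolerance interval of a target is a Wilson score interval at the observed
sample size; the initial interval widens it tenfold about the observed
value, truncated to the target's natural range. Rates per 100,000 are
handled on the proportion scale and rescaled.

### Simulation noise in the tolerance bands

At desk scale the simulator's own Monte-Carlo error is not negligible: a
precisely observed rate (tens of thousands of trial participants) cannot
be resolved by an evaluation with a few hundred simulated agents. The
engine therefore carries a guard (`check_target_mc_error()`): the
simulation binomial SE of each target should not exceed 20% of its final
half-width. Meeting that guard literally for the precise screen-detection
targets would require populations two orders of magnitude larger than a
desk-scale budget allows. The synthetic scenario instead constructs final
intervals from an effective sample size $n_{eff} = (1/n_{obs}+1/n_{sim})^{-1}$,
which folds the evaluation-scale simulation noise into the tolerance band
(a total-uncertainty band), and runs with the guard in warning mode. The
cost is a wider posterior than the observed sample sizes alone would give;
the benefit is a statistically honest accept band at the simulation sizes
actually used.

## The IMABC engine

Calibration is likelihood-free. Draws are accepted when every simulated
target falls inside every current tolerance interval; importance weights
are prior density over proposal density, with no likelihood term. The
proposal starts as the prior (`n_init` draws; draws inside all initial
intervals are retained with uniform weights) and grows by adaptive
mixture components: each iteration centres `n_centers` multivariate
normals at the highest-weight accepted draws (ties broken by draw id),
with covariance taken from each centre's nearest accepted draws in
standardised coordinates and regularised by adding $10^{-8}\times$ trace
to the diagonal. Batches mix 10% prior draws (a defensive component) with
the new Gaussians. Weights use the balance heuristic: the proposal density
is the mixture of all sampling stages weighted by the number of draws
actually taken from each, which keeps the estimator consistent as stages
accumulate.

Tolerance intervals narrow geometrically: each iteration closes a
configurable fraction (default 0.5) of the remaining gap between current
and final endpoints, one target at a time, skipping any step that would
leave fewer than `min_draws_retained` accepted draws. The run stops when
the effective sample size $(\sum w)^2/\sum w^2$ at the *final* intervals
reaches the target (5000 at production scale; 200 in the toy experiments),
or an iteration cap flags the state unconverged. If the retained prior
draws already satisfy the final intervals with enough ESS, the run
converges with zero mixture iterations.

### Warm-start recalibration

When new targets $z$ arrive after a calibration to targets $y$ has
converged, the posterior factorises as
$p(\theta\mid y,z)\propto p(\theta\mid y)\,p(z\mid\theta,y)$, so the
accepted draws from $p(\theta\mid y)$ remain valid importance material.
`warm_start_recalibration()` simulates only the new targets for every
stored draw, reusing each draw's stored seed so the original targets'
simulated values are unchanged without recomputation; acceptance is then
re-applied against the combined set with $z$ at its initial intervals,
the existing mixture components are retained, and the iteration loop
resumes with the counter continuing. How the original full-scale study
obtained new-target values for previously accepted draws is not
documented; seed reuse is this package's mechanism, chosen because it
makes the warm start exact rather than approximate. If no stored draw
satisfies the new initial intervals the warm start degenerates and the
engine stops with an instruction to widen the bands or start from scratch.

All engine randomness is derived from the master seed and the iteration
counter, and simulator calls take per-draw seeds, so runs are exactly
reproducible, batch evaluations may be parallelised without changing
results, and a state saved mid-run and resumed reproduces an uninterrupted
run bit for bit.

## Posterior comparison

Two posterior sample sets are compared per parameter with four metrics:

* **CI overlap** — for 95% equal-tailed weighted credible intervals
  $(L_1,U_1)$, $(L_2,U_2)$ with intersection $(L_I,U_I)$:
  $0.5(U_I-L_I)/(U_1-L_1)+0.5(U_I-L_I)/(U_2-L_2)$; 1 when identical, 0
  when disjoint. Quantiles invert the right-continuous weighted empirical
  CDF; this rule is fixed because interval endpoints feed the overlap
  measure directly.
* **Area overlap** — $\int\min(\hat f_1,\hat f_2)$ with weighted Gaussian
  KDEs, Silverman bandwidths computed from weighted moments, on a shared
  512-point grid spanning the pooled range plus three bandwidths. The
  KDE recipe is fixed here for reproducibility; weighted draws are the
  default and an unweighted flag exists because the convention used for
  the published comparisons is not recorded.
* **SMD** — absolute difference in weighted means standardised by the
  *reference* (first) sample's weighted sd; reported as an absolute value.
* **Hellinger distance** — $\sqrt{1-\int\sqrt{\hat f_1\hat f_2}}$ on the
  same grid.

`mst_posterior()` converts each draw's $(\lambda_1,\lambda_2,\lambda_3)$
to colon and rectum mean sojourn times and summarises the transformed
draws — the mean of the transform, not the transform of the mean, which
differ by Jensen's inequality on dispersed posteriors.

## The synthetic study and what it does (not) show

No external data ship with the package. `make_default_scenario()` fixes a
ground truth, simulates it at 25 times the evaluation scale, perturbs each
target by binomial (multinomial for the size bins) noise at the declared
observation sample sizes, and emits an original target set `y` (two
incidence bands, detected-adenoma prevalence by sex, three size-bin
percentages, preclinical cancers per 1000 large lesions, and one
deliberately imprecise overall screen-detection rate with its final band
widened fourfold, mirroring a small early study) plus a new set `z` of
two precise sex-specific screen-detection rates with observation sample
sizes 20,519 (men) and 20,155 (women) from a simulated one-time
sigmoidoscopy trial of 55–64-year-olds.

Deliberate desk-scale choices, stated once and not tuned thereafter:

* **Free parameters**: only the sojourn parameters
  $(\lambda_1,\lambda_2,\lambda_3)$, truth $(3.77, 2.38, 0.87)$ — values
  on the scale of published recalibrated posterior means — with
  truncated-normal priors TN(3, 1.5) on [0.5, 8], TN(2.5, 1) on [1, 5]
  and TN(0.5, 1) on [−1.5, 2]. The remaining 19 parameters are fixed at
  truth.
* **Evaluation size**: 2,000 agents per simulator evaluation, split 40/30/30
  across the incidence population (ages 40–90), a colonoscopy study
  (50–75) and the sigmoidoscopy trial (55–64).
* **Event rates** are scaled up relative to real registry data (annual
  clinical incidence of order 500–1500 per 100,000 in the simulated bands;
  screen-detection rates of order 2–4%) so that a 2,000-agent evaluation
  carries signal. The generator therefore emulates the *structure* of a
  registry-plus-studies target set — mixed precisions, shared simulator,
  binomial sampling — not the absolute magnitudes of real colorectal
  cancer epidemiology. Passing tests show the calibration machinery
  recovers truth and that sequential and scratch recalibration agree at
  this scale; they do not certify the model against real incidence data.
* **Engine scale for tests**: `n_init = 400`, 5 components × 60 draws per
  iteration, ESS target 200, at most 25 iterations. The experiment is
  replicated 20 times; a replicate takes roughly half a minute on one CPU,
  and the paired arms let one replicate serve both the parameter-recovery
  and the sequential-versus-scratch checks.

Numerical details worth knowing: component covariances fall back to an
inflated diagonal if Cholesky fails after regularisation; draws proposed
outside the prior support get zero weight and are never accepted; target
statistics that are undefined for a draw (for example size-bin percentages
when no lesion is detected) are treated as failed acceptance for that
draw; size bins use the half-open operationalisation [1, 5.5), [5.5, 9.5),
[9.5, ∞) mm of the reported ≤5 / 6–9 / ≥10 mm categories.

## Known limitations

* One colon/rectum split, no serrated pathway, no treatment, no repeat
  screening, no test specificity: the screening layer exists to generate
  detection-rate targets, not to evaluate screening policies.
* The marginal posterior for $\lambda_2$ (the Weibull shape) is only
  weakly identified by rate-style targets at toy scale; its credible
  intervals remain close to the prior's span. This mirrors the motivating
  problem — detection-rate targets mostly inform the sojourn scale — and
  is why coverage of the truth is assessed rather than posterior
  concentration.
* Hard-threshold ABC acceptance with noise-inflated bands widens the
  posterior relative to an exact-likelihood analysis; the comparison
  metrics are therefore meaningful between arms run under identical
  conditions, which is how they are used.
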