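# crcabc

Microsimulation of colorectal-cancer natural history, likelihood-free
calibration with Incremental Mixture Approximate Bayesian Computation
(IMABC), sequential "warm start" recalibration when new calibration targets
arrive, and posterior-comparison metrics that quantify how new evidence
shifts a calibrated posterior.

The package is aimed at disease modellers who calibrate stochastic
microsimulation models to published summary statistics (registry incidence
rates, adenoma prevalence, screen-detection rates) and who need to update an
expensive calibration when a new study is published, without starting over.

## The model and the method

Each simulated person progresses through the adenoma–carcinoma sequence:

* adenomas arise by a non-homogeneous Poisson process whose log-intensity
  is piecewise linear in age (knots at 50/60/70, zero risk before 20) with
  a person-level intercept `N(A, σ_α)` and a sex effect;
* each adenoma grows along a Richards curve
  `d(t) = d_∞ [1 + ((d_0/d_∞)^{1/p} − 1) e^{−λt}]^p`, with the rate `λ`
  solved from a Fréchet-distributed time to reach 10 mm;
* it transitions to preclinical cancer when its diameter reaches a
  lognormal transition size;
* the sojourn time to clinical presentation is Weibull, with survival
  `exp[−(t/λ₁)^{λ₂}]` in the colon and scale multiplied by `exp(λ₃)` in the
  rectum, so mean sojourn times are `λ₁Γ(1+1/λ₂)` and `λ₁e^{λ₃}Γ(1+1/λ₂)`.

Calibration is ABC with tolerance intervals: a parameter draw is accepted
when every simulated target lies inside every current accept band; bands
narrow from wide initial intervals to final Wilson-score intervals; the
proposal grows by adaptive Gaussian mixture components centred on the
best accepted draws, and draws carry importance weights `prior/proposal`
until the effective sample size reaches its target. When new targets `z`
arrive after calibration to `y`, `p(θ|y,z) ∝ p(θ|y) p(z|θ,y)` justifies a
warm start: stored draws are re-scored on `z` only (per-draw seeds are
reused, so `y`-statistics are unchanged) and the engine resumes instead of
restarting. Agreement between sequential and scratch posteriors is
measured per parameter by 95% credible-interval overlap, kernel-density
area overlap, standardized mean difference and Hellinger distance.

## Worked example

```r
library(crcabc)

# a self-contained synthetic calibration experiment: ground truth,
# original targets y, and two precise new screen-detection targets z
sc  <- make_default_scenario(seed = 7)
cfg <- imabc_config(n_init = 400, n_centers = 5, batch_size = 60,
                    target_ess = 200, max_iterations = 25, mc_guard = "off")
rep <- run_two_arm_experiment(sc, cfg, seed = 7)
rep
#> <two_arm_report> converged: orig TRUE, seq TRUE, scratch TRUE
#> simulator draws: sequential post-restart 936 vs scratch total 1600
#> # A tibble: 3 × 5
#>   parameter ci_overlap area_overlap     smd hellinger
#>   <chr>          <dbl>        <dbl>   <dbl>     <dbl>
#> 1 lambda1        0.953        0.877 0.242      0.106
#> 2 lambda2        0.989        0.880 0.115      0.0987
#> 3 lambda3        0.978        0.968 0.00925    0.0321
```

The two arms calibrate the same three free sojourn-time parameters
(`λ₁, λ₂, λ₃`, truth 3.77/2.38/0.87) to the same targets — one by warm
start after the new targets arrive, one from scratch. The comparison rows
say the two posteriors are nearly interchangeable (interval overlap close
to 1, Hellinger close to 0), and the header shows the warm start needed
936 simulated parameter draws after the restart versus 1600 for the full
recalibration. Mean sojourn time per arm:

```r
rep$mst
#> # A tibble: 4 × 5
#>   location  mean lower upper run
#>   <chr>    <dbl> <dbl> <dbl> <chr>
#> 1 colon     3.27  1.41  5.34 seq
#> 2 rectum    7.88  1.30 20.5  seq
#> 3 colon     3.52  1.64  5.46 scratch
#> 4 rectum    8.59  1.34 24.3  scratch
```

Lower-level entry points: `simulate_agent()` / `simulate_population()` for
natural histories, `adenoma_sensitivity()` / `simulate_screen()` for the
screening layer, `run_calibration()` / `warm_start_recalibration()` for
the engine, `compare_posteriors()` / `mst_posterior()` for posterior
summaries, and `tidy()` / `glance()` / `autoplot()` methods on the fitted
objects. A thin command-line wrapper lives at `inst/cli/crcabc`
(subcommands `simulate`, `calibrate`, `recalibrate`, `compare`,
`make-fixtures`).

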