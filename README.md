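# bowmimic

Motor-imitation analysis of violin bowing from synchronized motion capture
and audio.

`bowmimic` is for researchers in movement science and music performance who
record a *leader* (for example a life-size avatar of a section leader) and a
*follower* (a participant imitating it) and want to quantify how faithfully
the follower reproduces the leader's bowing — and whether an experimental
manipulation (such as a 2D screen versus a 3D holographic display) changes
that fidelity and the accompanying sense of presence.

The pipeline:

1. **Kinematics** — from marker trajectories (bow frog/tip, violin
   bridge/scroll, arm clusters) compute the bow–string contact point:
   `dist_frog` and `dist_bridge` (the 2D bowing curve), tilt angle, smoothed
   derivatives, and ISB-style wrist/elbow/shoulder joint angles.
2. **Strokes** — segment bow strokes at velocity reversals (with hysteresis),
   keep strokes longer than 150 mm and louder than 15% of the performance's
   median loudness, and pair the two performers over identical time windows.
3. **Metrics** — per stroke, gesture similarity as the 2D **Procrustes
   distance** (PD, in [0, 1]; translation/rotation/reflection/scale
   invariant, 0 = identical shape) and smoothness as the **spectral
   arc-length** (SPARC) difference `dSI = SI_follower − SI_leader` (positive
   = follower smoother).
4. **Statistics** — standardize, take cell medians (11 participants x 2
   conditions x 4 trials = 88 rows in the default design), subtract
   piece-by-section group medians, then fit the hierarchical Bayesian model

   `response ~ 0 + condition + (1 | condition:participant) + (1 | condition:trial)`

   with weakly informative priors, compare it against a covariate model by
   Bayes factor (with a LOO cross-validation check), run posterior
   predictive diagnostics and variance-components R², and evaluate directed
   contrasts (`c12`, `c1t12`, `c12t1`, ...) with 95% credible intervals and
   the probability of direction.
5. **Questionnaires** — score WPQ / MPQS / MPQP presence scales and
   perceived difficulty, with Cronbach's alpha per scale.

A synthetic-data module generates leader/follower performances, cohort
designs and questionnaire responses with known ground truth (minimum-jerk
strokes; followers with controllable lag, gain error, offset, low-passed
positional noise and tremor), so the entire pipeline is testable without any
recording hardware. See the vignette
(`vignettes/bowing-imitation-analysis.Rmd`) for the model details and design
choices.

## Worked example

Simulate a follower with realistic imperfections and score it against the
leader:

```r
library(bowmimic)

score    <- default_score(n = 12, length = 300, duration = 0.5)
avatar   <- generate_avatar(score)
follower <- generate_follower(avatar, fidelity_params(
  spatial_noise_sd = 4, tremor_amp = 2, tracking_lag = 0.04, seed = 42))

m <- performance_metrics(avatar, follower)
head(m[, c("stroke_index", "pd", "si_avatar", "si_participant", "dsi")], 4)
#>   stroke_index     pd si_avatar si_participant     dsi
#> 1            1 0.0257   -1.4034        -1.7724 -0.3690
#> 2            2 0.0205   -1.4033        -1.7484 -0.3451
#> 3            3 0.0195   -1.4033        -1.4229 -0.0196
#> 4            4 0.0220   -1.4033        -1.8061 -0.4028
```

Each row is one gated bow stroke: `pd` near 0 says the 4 mm positional noise
barely distorts the stroke *shape*, while the 2 mm / 8 Hz tremor lowers the
follower's spectral arc length below the leader's (`dsi < 0`, follower less
smooth).

Fit the hierarchical model to an 88-cell dataset (here simulated with a
known condition difference) and read off the condition contrast:

```r
d <- expand.grid(participant = 1:11, condition = c("2D", "3D"), trial = 1:4,
                 stringsAsFactors = FALSE)
set.seed(1)
cp <- interaction(factor(d$condition), factor(d$participant))
d$value <- rnorm(22, 0, 0.3)[as.integer(cp)] + rnorm(88, 0, 0.4) +
  ifelse(d$condition == "2D", 0.25, -0.25)

fit <- fit_hbm(d, seed = 1)
fit
#> <hbm_fit> value ~ 0 + condition + (1 | condition:participant) + (1 | condition:trial)
#>   88 obs, 4 chains x 35000 draws; max split R-hat 1.002
#> condition2D condition3D
#>   0.3651610  -0.1342708

contrasts_hbm(fit, c("c12", "c1t12", "c12t1"))
#>   label estimate ci_lower ci_upper post_prob
#> 1   c12  0.49950    0.191    0.809     0.998
#> 2 c1t12 -0.00491   -0.189    0.117     0.421
#> 3 c12t1  0.49681    0.181    0.812     0.998

bayes_r2(fit)[c("conditional", "marginal")]
#> $conditional [1] 0.52   $marginal [1] 0.22
```

`c12` is the posterior for condition 1 (2D) minus condition 2 (3D): the
injected +0.5 difference is recovered with probability of direction 0.998
(strong evidence), while the trial contrast `c1t12` is flat — exactly the
pattern the model should report. `run_workflow()` chains all of this
(simple + covariate model, Bayes factor, diagnostics, full contrast table)
for every response, and `run_pipeline()` runs the whole study end to end,
writing stroke metrics, calibrated datasets, contrast tables and a manifest.

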