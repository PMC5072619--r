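# chromdyn

Chromatin-domain structure from subdiffusive nucleosome dynamics.

Interphase mammalian genomes are partitioned into submegabase chromatin
domains (CDs, including topologically associating domains).  Single-nucleosome
imaging in living cells shows that nucleosome motion is subdiffusive,

```
MSD(t) = D_app * t^beta ,   0 < beta < 1 ,
```

and the question `chromdyn` addresses is what that motion says about the
*structure* of the domain the nucleosome lives in.  The package implements a
polymer model in which a CD of `N` nucleosomes folds with fractal size
scaling `<R>_CD ~ N^(1/d_f)` and fluctuates in a viscoelastic nuclear medium
with power-law memory friction `gamma(t) ~ t^(-alpha)` (a generalized
Langevin equation consistent with fractional Brownian motion).  Under a
linearization (preaveraging) approximation of the long-range interactions,
the normal modes relax through a Mittag-Leffler function and the
position-averaged nucleosome MSD at short times is an exact power law whose
parameters carry the domain structure:

```
beta  = 2 * alpha / (2 + d_f)
D_app = C(d_f, alpha) * [3 D_EGFP / (4N)]^(2/(2+d_f)) * (<R>_CD^2)^(d_f/(2+d_f))
```

so a fitted `(D_app, beta)` can be inverted (given an assumed `alpha`, `N`
and reference diffusivity `D_EGFP`) into the fractal dimension `d_f`, the RMS
domain size `<R>_CD`, and the relaxation time `tau` of nucleosome
fluctuations.  The package is aimed at single-particle-tracking analysts and
chromatin biophysicists who want to run that inversion on their own MSD
curves, or to interrogate the forward theory and its approximations.

## What is inside

* **Theory** — `fractal_domain_model()` plus closed-form evaluators for
  every derived quantity: mode variances/stiffnesses, Mittag-Leffler mode
  correlation (`mittag_leffler()` is evaluated to ~1e-10 absolute accuracy),
  center-of-mass MSD, the asymptotic internal MSD, and a brute-force
  normal-mode sum `msd_mode_sum()` that serves as the numerical oracle for
  the closed forms.
* **Inversion** — `fit_power_law()` (nonlinear least squares on MSD curves,
  optional SEM weighting) and `estimate_domain()` / `alpha_sweep()` /
  `ncd_sweep()` implementing the structural inversion with delta-method
  error propagation.
* **Trajectories** — `read_tracks()` / `write_tracks()` for delimited track
  tables and `ensemble_msd()`, the origin-anchored ensemble MSD estimator
  with the 3/2 isotropy factor and per-lag SEM (plus a clearly-labelled
  time-averaged alternative).
* **Simulator** — `simulate_tracking_experiment()` generates synthetic 2D
  tracking data directly in linearized mode space with exact Gaussian
  covariances (no Euler discretization bias), including localization noise,
  for end-to-end validation without any external data.
* **CLI** — `inst/cli/chromdyn` with subcommands `simulate`, `msd`, `fit`,
  `estimate`, `table1`.

## Worked example

Invert the published HeLa nuclear-interior MSD fit
(`MSD = 0.018 t^0.44 um^2`) under an assumed medium exponent `alpha = 0.8`:

```r
library(chromdyn)
interior <- power_law_fit(0.018, 0.44)
estimate_domain(interior, alpha = 0.8)
#> Chromatin-domain estimate
#>   from fit: D_app = 0.018 um^2/s^beta, beta = 0.44
#>   assuming: alpha = 0.8, N = 5000, D_EGFP = 20.6 um^2/s
#>   d_f    = 1.64
#>   <R>_CD = 376 nm
#>   tau    = 4.65 s
```

The domain is estimated to be relatively open (`d_f = 1.64`, between a
straight line and an ideal chain), a few hundred nanometres across, with
internal fluctuations that equilibrate within a few seconds.  Repeating with
the periphery fit (`0.013 t^0.39`) gives a more compact, smaller domain —
heterochromatin-rich regions pack tighter.

The forward direction, and a synthetic experiment:

```r
m <- fractal_domain_model(alpha = 0.9, d_f = 2.09, n_nucleosomes = 5000,
                          r_rms = 0.268)
m
#> derived: beta = 0.4401, D_app = 0.01833 um^2/s^beta, tau = 2.797 s

trk <- simulate(m, nsim = 2000, seed = 7, frames_per_track = 11,
                localization_sigma = 0)
fit_power_law(ensemble_msd(trk))
#> Subdiffusion power-law fit: MSD(t) = D_app * t^beta
#>   D_app = 0.02176 um^2/s^beta (se 0.00033)
#>   beta  = 0.4917 (se 0.012)
#>   window [0.05, 0.5] s, 10 points, weighting: none
```

Note that the fitted exponent (0.49) sits above the asymptotic `beta = 0.44`:
over the experimental 0.05-0.5 s window the measured MSD also contains
center-of-mass motion and the beginning of mode saturation, so the pure
short-time power law is an approximation there.  The methods vignette
(`vignettes/chromatin-domain-dynamics.Rmd`) quantifies these systematics and
what they imply for parameter recovery.

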