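# dkisubsample

Monte-Carlo test bench for the effect of **truncating multi-shell diffusion
MRI acquisitions** on diffusional kurtosis imaging (DKI) parameters. It is
aimed at researchers designing interruption-robust acquisition protocols:
if a scan is cut short, how biased do FA, MD, AD, RD, MK, AK and RK become,
and how much does the gradient **ordering strategy** protect you?

The package provides, end to end:

* **Scheme design** — bipolar electrostatic-repulsion (EEM) optimization of
  multi-shell direction sets (32 directions at b = 1000 s/mm², 60 at
  b = 2000 s/mm², 8 b = 0; 100 volumes), incremental interruption-robust
  ordering, and three subsampling strategies at 95–50% retention:
  `Opt_EEM` (ordered truncation), `Opt_SC` (spherical-code selection
  maximizing the covering radius, nested chain) and `Random_TRUNC`
  (seeded shuffle + truncation).
* **Signal simulation** — a crossing-fiber substrate (two fibers at 60°,
  intra/extra-cellular Gaussian compartments, AD/RD = 1.4/0.1 and
  2.0/0.5 × 10⁻³ mm²/s, equal fractions) with Rician noise at a chosen
  b = 0 SNR.
* **DKI fitting** — the 22-parameter log-linear model
  `ln S = ln S0 − b·D_app(n) + (b²/6)·MD²·W(n)`, fitted by two-pass
  weighted least squares, optionally subject to non-negative apparent
  directional kurtosis (`K_app(n) ≥ 0` on all acquired directions, solved
  as a quadratic program). `dki_fit()` returns a classed object with
  `print`, `summary`, `coef`, `predict`, `fitted` and `residuals` methods.
* **Scalar metrics** — FA/MD/AD/RD from the diffusion-tensor eigenvalues;
  MK/AK/RK by numerical spherical averaging of `K_app`.
* **Histogram summaries** — normalized histograms (1000 bins) with median,
  peak height, peak value and peak width (p95 − p5) for any scalar map,
  including masked NIfTI volumes.
* **The experiment pipeline** — the full factorial
  method × fraction × SNR × orientation × noise-instance study with paired
  subset-versus-full relative errors, tidy CSV export and plotting.

## Worked example

```r
library(dkisubsample)

scheme <- order_scheme_eem(generate_scheme(seed = 1))
scheme
#> Multi-shell gradient scheme: 100 volumes
#>   shell 1: b = 1000 s/mm^2, 32 directions
#>   shell 2: b = 2000 s/mm^2, 60 directions
#>   b = 0 volumes: 8

voxel <- fiber_substrate()            # two fibers crossing at 60 degrees
round(ground_truth_metrics(voxel), 4)
#>     FA     MD     AD     RD     MK     AK     RK
#> 0.6060 0.0008 0.0014 0.0005 0.8070 0.1245 0.7163

noisy <- add_rician_noise(simulate_signal(voxel, scheme), snr = 20, seed = 3)
fit <- dki_fit(noisy)                 # positivity-constrained WLS
summary(fit)
#> DKI fit (constrained), 100 volumes, convergence: constrained_active
#>   MD = 0.0007641 mm^2/s, FA = 0.635
#>   scalar metrics:
#>        FA        MD        AD        RD        MK        AK        RK
#> 0.6350000 0.0007641 0.0014000 0.0004464 0.7906000 0.0986600 0.2769000
#>   signal-domain RMSE: 0.0386
```

A single noisy voxel at SNR 20 recovers MD within a few percent while the
kurtosis metrics scatter much more — the instability the full experiment
quantifies. The experiment crosses the three subsampling strategies with
retention levels and SNRs, always cutting every subset out of the *same*
noisy realization of the full acquisition (paired comparisons):

```r
cfg <- experiment_config(fractions = c(1, 0.7, 0.5), snr = 20,
                         n_orientations = 100, n_noise = 100, seed = 1)
ex  <- relative_error(run_experiment(cfg))   # ~2 minutes on one core
summary(ex, snr = 20)
#> Relative errors of parameter medians vs the full dataset (%), SNR 20
#>        method fraction    FA   MD    AD   RD   MK   AK    RK
#>       opt_eem      0.7 0.124 0.98 0.761 0.96 3.40 21.3  6.10
#>       opt_eem      0.5 0.110 1.99 1.790 1.78 6.86 42.3 10.20
#>        ...
```

Reading: at a typical SNR of 20, halving the acquisition moves the MD
median by ~2% and the MK median by ~7% under optimized ordering, while FA
barely moves; kurtosis parameters are far more truncation-sensitive than
diffusion parameters.

Histogram characteristics of any scalar map (e.g. a skeletonized in-vivo
parameter map) use the same summaries as the simulation outputs:

```r
set.seed(1)
histogram_summary(rnorm(1e5, mean = 0.8, sd = 0.1))
#> Normalized-histogram summary (1000 bins)
#>   median:      0.80008
#>   peak height: 4.5056
#>   peak value:  0.81027
#>   peak width:  0.33045 (p95 - p5)
```

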