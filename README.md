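# robustpet

Robust least-squares PET image reconstruction when the system matrix is
only approximately known.

## The problem

Iterative PET reconstruction estimates a nonnegative activity image *x*
from coincidence counts *y* ≈ *D x*, where the system matrix *D* maps voxel
activity to expected detector-bin counts.  MLEM and penalized weighted
least squares (PWLS) both assume *D* is exact; in reality the matrix used
for reconstruction carries errors from attenuation, normalization and
detector-response factors, and those errors — not counting noise — are
what systematically distorts the image.  `robustpet` implements an
**uncertainty-penalized weighted least-squares (UPWLS)** estimator that
minimizes the *worst-case* weighted residual over a norm-bounded
perturbation set

min&#8339; max<sub>‖Δ‖≤φ</sub> ‖x‖²<sub>Q</sub> + ‖(D + M&#8342;ΔE&#8342;)x − (y + M&#8342;ΔE&#8343;)‖²<sub>W</sub>,

solved in closed form through corrected penalty/weighting matrices
Q̂ = Q + λE&#8342;′E&#8342; and Ŵ = W + WM&#8342;(λI − M&#8342;′WM&#8342;)⁺M&#8342;′W with
λ ≥ ‖M&#8342;′WM&#8342;‖, and run as a static state-space (Kalman-style)
recursion.  Setting M&#8342; = 0 recovers the classical penalized WLS/Kalman
update exactly.

The package also contains everything needed to study the estimator:
an exact ray-traced parallel-beam projector, the Shepp-Logan emission
phantom, a Poisson acquisition simulator with uniform randoms/scatter and
delayed-window correction, controlled (spatially correlated) system-matrix
perturbation at a requested mean relative error, MLEM and PWLS+CG
baselines, and a Monte-Carlo bias/variance harness.

It is aimed at researchers in tomographic image reconstruction who want a
small, fully inspectable reference implementation of robust (min-max)
least squares in the PET setting.

## Worked example

Reconstruct a 64×64 Shepp-Logan scan with a system matrix that carries a
12% mean relative error, using the accurate-model baselines and the robust
estimator (which assumes a fixed 6% uncertainty budget):

```r
library(robustpet)
geom    <- default_geometry()            # 64x64 image, 60 angles x 95 bins
D       <- build_system_matrix(geom)
phantom <- shepp_logan_phantom(geom)

proto <- scan_protocol(total_counts = 1e5, n_realizations = 1, seed = 7)
scan  <- simulate_scan(phantom, D, proto, realization = 0)
y     <- correct_sinogram(scan$prompt, scan$delayed, proto)

# reconstruct with a *wrong* system matrix (12% mean relative error)
D_hat <- apply_perturbation(D, perturb_system_matrix(D, 0.12, seed = 7))
truth <- scan$scale * phantom$values

fit <- pet_recon(y, D_hat, method = "upwls", x_true = truth,
                 U = make_norm_bounded_model(D, 0.06), epsilon = 1e-3)
summary(fit)
#> PET reconstruction summary (UPWLS)
#>   iterations:      5
#>   total activity:  1595
#>   max activity:    1.255
#>   normalized error: 0.4069
#>   bias / std:       0.3839 / 0.4538
```

Comparing the three estimators on the same realization (normalized L2
error against the truth; bias/std are the mean and spread of per-pixel
error magnitudes normalized by the mean true activity):

```
mlem   error 0.978   bias 0.844   std 1.153
pwls   error 0.455   bias 0.426   std 0.509
upwls  error 0.407   bias 0.384   std 0.454
```

The MLEM and PWLS reconstructions are driven far from the truth by the
coherent matrix error, while the robust recursion stays close to its
accurate-model accuracy.  `run_monte_carlo()` repeats this comparison over
seeded realizations and error levels and writes the bias ± std table:

```r
report <- run_monte_carlo(scan_protocol(n_realizations = 20),
                          noise_levels = c(0, 0.06, 0.12),
                          methods = c("em", "pwls", "upwls"),
                          geom = default_geometry())
write_eval_report(report, "table.csv")
```

A thin command-line wrapper with `simulate` / `reconstruct` / `evaluate` /
`fixture` subcommands is installed at `inst/cli/petrecon`.

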