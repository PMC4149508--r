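# radialnav

Respiratory self-navigation for interleaved 2D radial MRI, with
compressed-sensing-assisted motion detection.

## The problem

Free-breathing cardiac MR images blur and ghost because the heart moves
with respiration. Navigator gating (accepting data only near
end-expiration, tracked by a diaphragmatic echo) restores image quality but
discards roughly two thirds of the scan. **Image-based self-navigation**
keeps every heartbeat: in an interleaved 2D radial acquisition, the handful
of projections acquired in each cardiac cycle (an *interleave*) is
reconstructed into a heavily undersampled *sub-image*; registering all
sub-images to a reference yields the per-heartbeat in-plane displacement
`(Δx, Δy)`, which is then corrected in k-space before the conventional
final reconstruction.

The package implements both the linear ("LN": density compensation +
gridding + FFT) and the compressed-sensing ("CS") sub-image pathway, where
each sub-image solves

```
x̂ = argmin_x ‖y − F x‖₂² + λ · TV(x),       TV(x) = Σᵢ √(|Dₓx|ᵢ² + |D_y x|ᵢ²)
```

with `F` the non-uniform Fourier (NUFFT) operator of the interleave, `λ =
10⁻⁵` by default, solved by FISTA with an exact isotropic-TV proximal step.
TV suppresses the streaking of 15-of-360-projection sub-images and makes
registration markedly more accurate, which is the point of the method.
Motion correction applies the Fourier-shift-theorem phase ramp

```
Δβ(k) = −2π · (k − N/2)/N · (Δx cosθ + Δy sinθ)
```

per projection. A synthetic cardiac phantom, quasi-periodic respiratory
traces and an exact (phase-ramp) acquisition simulator make the whole
pipeline testable end to end with known ground truth; quality is scored by
blood-pool SNR/CNR, percent vessel sharpness (%VS), vessel diameter and
per-interleave Euclidean motion-detection error.

Intended audience: MR physicists and methods researchers who want a small,
fully self-contained reference implementation of CS-assisted 2D
translational self-navigation, with oracles and property tests around every
numerical component.

## Worked example

An eight-interleave desk experiment (matrix 96, 2 mm pixels, displacements
drawn in 0–7 mm), comparing no correction, self-navigation with LN and CS
sub-images, and the ground-truth ("oracle") correction:

```r
library(radialnav)
cfg <- run_config(matrix = 96, fov_mm = 192, projections = 160, interleaves = 8,
                  seeds = list(phantom = 5, trace = 2, noise = 9))
res <- run_pipeline(cfg)
print(summarize_run(res), digits = 3)
#>   method  snr  cnr vessel_sharpness_pct mean_diameter_mm nrmse_vs_static
#> 1   none 11.8 3.87                 49.7             5.66          0.0572
#> 2     LN 11.3 3.80                 64.2             4.01          0.0219
#> 3     CS 11.3 3.80                 64.8             4.00          0.0216
#> 4 oracle 11.3 3.78                 64.5             4.00          0.0215
#>   motion_error_mean_mm motion_error_mean_px
#> 1               2.4481               1.2241
#> 2               0.2666               0.1333
#> 3               0.0963               0.0481
#> 4               0.0000               0.0000
```

Reading the table: without correction the vessel smears (diameter
overestimated at 5.66 mm, sharpness 49.7%) and the "motion error" row is
just the excursion of the uncorrected motion. Both self-navigation variants
restore the 4 mm-scale vessel and the sharpness, with CS clearly ahead of
LN in trace accuracy (0.05 px vs 0.13 px here) and image fidelity
(`nrmse_vs_static` compares against the static noiseless reference in the
common reference frame); the oracle row is the ceiling given the shared
noise realisation. Motion errors are reported relative to the registration
reference, since the absolute respiratory position of the reference
sub-image is unobservable to any self-navigation method. At the default
desk scale (`run_config()`: matrix 160, 24 interleaves of 15 projections)
CS-assisted detection reaches a mean error well under the half-pixel bound
the method is expected to satisfy (0.06 px at seed 1, versus 0.38 px for
LN), and the acceptance suite asserts the orderings
none < LN ≤ CS ≤ oracle for %VS and error(CS) ≤ error(LN).

The per-heartbeat trace itself:

```r
res$methods$CS$trace        # motion_trace: dx_mm, dy_mm per interleave
si_component(res$methods$CS$trace, diag(3))   # SI projection, mm
```

## Command line

```sh
exec/radialnav simulate --out run.rnav --seed 1      # phantom + corrupted k-space
exec/radialnav run --out run.rnav                    # full four-method comparison
exec/radialnav correct --in run.rnav --trace t.tsv --out-image img.pgm
exec/radialnav evaluate --in run.rnav --report report.json
```

Containers are single self-describing files (R serialization) holding
phantom, trajectory, k-space, traces, masks, config and seeds; images
export as plain-text PGM, traces as TSV, reports as JSON.

## Layout

| module | contents |
| --- | --- |
| `R/trajectory.R` | interleaved radial patterns, density-compensation weights |
| `R/nufft.R`, `src/nufft.cpp` | Kaiser–Bessel gridding NUFFT (forward/adjoint), TV prox |
| `R/recon.R` | gridding and FISTA-TV reconstruction, k-space/sub-image containers |
| `R/selfnav.R` | elliptical ROI masks, masked-MSE registration, trace extraction, SI projection |
| `R/motion_correct.R` | phase ramps, per-interleave correction, final reconstruction |
| `R/synthdata.R` | phantom, respiratory traces, coil maps, acquisition simulator |
| `R/metrics.R` | SNR/CNR, %VS, diameter, motion error, navigator agreement, protocol arithmetic |
| `R/pipeline.R`, `R/container.R` | end-to-end runner, run containers, exports |

See `vignettes/selfnav-methods.Rmd` for the model, parameter meanings,
numerical choices and the limits of what the synthetic world establishes.
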