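# mrewave

Model-independent analysis of magnetic resonance elastography (MRE) wave
images in R.

## The problem

MRE drives a time-harmonic shear wave through tissue (or a gel phantom)
and images the displacement field, yielding a complex scalar image
`u(x) = φ(x) − iψ(x)` on a metric pixel grid.  Stiffness is encoded in
the local wavelength: stiffer material, longer wavelength.  Most
inversion schemes fit a PDE model to `u`; this package instead assumes
only that `u` is locally a finite sum of attenuated complex plane waves

```
u(x) ≈ Σₙ cₙ · exp( ω (αₙ + iβₙ) · (x − p) )
```

with slowness vectors `βₙ` (s/m), attenuation vectors `αₙ` (s/m) and the
vibration angular frequency `ω`.  At each probe point `p` it computes a
Gaussian-windowed Fourier (Gabor) transform

```
W(u; p, σ)(ξ) = ∫ e^{−i(x−p)·ξ} u(x) e^{−|x−p|²/2σ²} dx
```

For a single attenuated wave, `|W|` is an exact Gaussian centered at
`ξ = ωβ`, and the phase of `W` is linear in `ξ` with slope `−ωσ²α`.  So:

* **local wave vector**: `β = argmax_ξ |W| / ω` (sub-cell refined);
* **local attenuation vector**: `α = −∇_ξ arg W / (ωσ²)`, the gradient
  obtained by a Gaussian-weighted least-squares fit of wrapped phase
  differences around the peak;
* **moduli**: the viscoelastic dispersion relation
  `ρ + (G′ + iG″)(α + iβ)·(α + iβ) = 0` converts the vectors into the
  storage and loss moduli

```
(G′, G″) = ρ / [ (|α|²−|β|²)² + 4(α·β)² ] · ( |β|²−|α|², 2 α·β )
```

  with the lossless shortcut `G′ = ρ/|β|²` when attenuation is
  negligible.

Two spectral filters reuse the same machinery for denoising: each pixel
tile is replaced by the single plane wave at its own strongest spectral
peak (local filter) or at the global spectral peak (global filter).

A synthetic-data generator produces bounded noisy wave fields whose
per-pixel ground truth satisfies the dispersion relation exactly, so the
entire pipeline is testable without scanner data.

## Worked example

```r
library(mrewave)

# simulate the reference phantom study: 96 x 96 pixels of 1.2 mm at 250 Hz,
# true G' = 14.4 kPa, G'' = 0.69 kPa, noise RMS just below 0.1 of the signal
study <- run_simulation_study(seed = 1)
study$stats
#>   region quantity    mean_Pa    sd_Pa  n
#> 1 center       Gp 14411.5373 28.13135 64
#> 2  right       Gp 14378.4612 73.60435 42
#> 3 center      Gpp   673.1084 42.96592 64
#> 4  right      Gpp   660.1900 71.08235 42

mean(study$beta_errors < 0.1)   # fraction of sample points with beta within 10%
#> [1] 1
```

The recovered storage modulus averages 14.41 kPa over the center region
and 14.38 kPa over the right third (truth: 14.4 kPa) despite noise ten
times weaker than the signal being clearly visible in the dimmer half of
the attenuated field; the loss modulus, which is far harder to estimate,
comes back at 0.66 kPa against a truth of 0.69 kPa.

Lower-level entry points: `fbi_transform()`, `spectral_peak()`,
`local_wave_vector()`, `local_attenuation_vector()`, `moduli_map()`,
`roi_stats()`, `denoise_local()`, `denoise_global()`.  Figures:
`plot_vector_overlay()`, `plot_modulus_map()`, `plot_spectrum()`.

A thin command line ships in `exec/mrewave`:

```sh
mrewave simulate --out sim --seed 1
mrewave analyze --input sim/field --out results
mrewave denoise --input sim/field --mode global --out filtered
```

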