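# starkir

Analysis of electric-field-dependent infrared difference nanospectra.

In photothermal IR nanospectroscopy (AFM-IR), a conductive probe tip in
contact mode doubles as a nanoelectrode: applying a bias V across the
tip–substrate nanogap puts a static field F = V/d (parallel-plate model,
d the film thickness) across the probed nanovolume while the same tip
provides the IR field enhancement. Recording absorption spectra A(ν) in
interleaved at-bias / zero-bias pairs and averaging the single-shot
differences δA(ν) = A(ν)|V − A(ν)|0 over ~10 repeats isolates the
field-induced response ΔA(ν) while cancelling slow drift. `starkir`
implements the complete analysis of such data for two regimes:

* **Vibrational Stark effect (VSE).** For an isotropic immobilized
  sample (thick PMMA films are the classic calibration case) the field
  broadens the band, and ΔA is fitted in the Liptay derivative basis of
  the zero-bias band:

  ΔA(ν) = (f·F)² · [ Aχ·A(ν) + Bχ·ν d(A/ν)/dν + Cχ·ν d²(A/ν)/dν² ],

  with Cχ = Δμ²·[5 + (3cos²ζ − 1)(3cos²χ − 1)] / (30 h²c²). Here Δμ is
  the dipole-moment change of the vibration, f the local field
  correction factor, χ the angle between the static and IR fields and ζ
  the angle between Δμ and the transition moment. Regressing the fitted
  second-derivative coefficient against F² through the origin yields Δμ
  (in Debye, 1 D = 3.34 × 10⁻³⁰ C·m); conversely, a sample with known
  Δμ calibrates the actual field via f.

* **Reorientation and protein response.** Thin films and membrane
  proteins with orientational freedom respond by shifting rather than
  broadening: the difference resembles the *first* derivative of the
  band. `decompose_shape()` quantifies the energy shares of the three
  basis components and labels each difference `vse_broadening`,
  `reorientation_shift` or `mixed`. For oriented membrane-protein
  stacks (bacteriorhodopsin amide-I band at ~1665 cm⁻¹), dedicated
  helpers quantify the cos² orientation response, the apparent band
  displacement (`peak_shift()`), and the ~1760 cm⁻¹ carboxyl
  protonation marker (`window_features()`,
  `detect_protonation_marker()`).

A seeded synthetic-data generator (`sample_preset()`, `make_*_series()`)
reproduces the statistical structure of the acquisitions — band shapes,
bias ladders, repeat averaging, noise and baseline drift — so the whole
pipeline runs and is tested without instrument data.

## Worked example

A synthetic 55 nm PMMA series (C=O band at 1731 cm⁻¹; bias ladder
6/9/12/16.5 V; generated with Δμ = 6.5 × 10⁻² D; realistic noise,
10 repeats per level):

```r
library(starkir)
res <- run_pipeline(run_config(preset = "pmma55", seed = 42,
                               n_repeats = 10, output_dir = tempfile()))
res$stark
#> <stark_result> delta_mu = 0.06516 D [0.06447, 0.06585] (f = 1, chi = 0, zeta = 0)
#>   slope = 35.92 per (V/nm)^2, linearity r^2 = 0.9997
res$coefficients[, c("bias", "F_stat", "c2", "label")]
#>   bias    F_stat        c2          label
#> 1  6.0 0.1090909 0.3633135 vse_broadening
#> 2  9.0 0.1636364 0.9298709 vse_broadening
#> 3 12.0 0.2181818 1.7302208 vse_broadening
#> 4 16.5 0.3000000 3.2381365 vse_broadening
```

The recovered Δμ = 0.0652 D matches the generator value within its
confidence interval; c2 grows linearly in F² (r² > 0.999) as first-order
perturbation theory demands, and every difference is classified as
Stark broadening.

The bacteriorhodopsin preset at negative polarity shows the
protein-side phenomenology — an apparent amide-I displacement and the
protonation marker:

```r
ser <- make_br_series(sample_preset("br10"), n_repeats = 10,
                      polarity = -1, seed = 42)
an <- series_differences(ser)
peak_shift(an$differences[[1]], an$reference)$shift
#> [1] 8.99     # cm-1, against a configured 9 cm-1 at -3 V
window_features(an$differences[[1]])[, c("window", "integral", "flag")]
#>        window    integral  flag
#> 1     retinal -0.01768766 FALSE
#> 2     amide_I -2.51850824  TRUE
#> 3 protonation  0.46448671  TRUE
```

## Command line

```sh
inst/cli/starkir generate --preset pmma55 --seed 1 --out series/
inst/cli/starkir fit --dir series/ --thickness 55 --out results/
inst/cli/starkir run --config run.yaml
```

See the methods vignette (`vignettes/stark-difference-analysis.Rmd`)
for the model, its assumptions, parameter defaults and numerical
choices.
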