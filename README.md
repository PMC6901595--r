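# melphasor

Fit-free phasor analysis of two-photon FLIM and spectral-emission image
stacks, built to quantify eumelanin/pheomelanin mixtures in pigmented cells
(the motivating system is human choroidal melanocytes). It is aimed at
microscopists and image analysts who have per-pixel TCSPC decay histograms
and/or multi-channel emission spectra and want species maps and quantitative
melanin profiles without fitting decay models pixel by pixel.

## The method

Each pixel's decay `I(t)` is reduced to its first Fourier harmonic and
plotted as a phasor

```
g = Σ I(t_k) cos(hωt_k) / Σ I(t_k),   s = Σ I(t_k) sin(hωt_k) / Σ I(t_k),
ω = 2πf (laser repetition frequency)
```

Mono-exponential lifetimes lie on the universal circle
`(g − ½)² + s² = ¼` at `g = 1/(1+(ωτ)²)`, `s = ωτ/(1+(ωτ)²)`; mixtures are
intensity-weighted vector sums, so every mix of two species falls on the
chord between the pure-species phasors, and the position along the chord is
the photon fraction of each species. Emission spectra transform the same way
on the wavelength axis, with the phase angle encoding the spectrum's centre
of mass (and hence its peak wavelength) and the modulus its width.

On top of the two transforms the package provides: reference calibration
(rotation + scale from a dye of known lifetime), the E-filter (median
filtering of phasor coordinates with unfiltered image borders),
two-endmember fraction decomposition, circular-cursor segmentation of phasor
clusters back onto the image, the melanin ratio-fraction profile
(cluster pixels / total image pixels, for cursors ordered from eumelanin-like
short lifetimes to pheomelanin-like long lifetimes), region-level average
points with s-value t tests and linearity scoring, a two-exponential decay
fit with intensity-weighted average lifetime for comparison, and a synthetic
melanocyte scene generator with exact ground truth that makes the whole
pipeline testable without microscope data.

## Worked example

Simulate a small scene of four melanocytes spanning very-dark to very-light
pigmentation, transform, filter, segment with seven cursors on the
eumelanin–pheomelanin chord, and profile:

```r
library(melphasor)

acq    <- acquisition_config(image_shape = c(48, 48), n_time_bins = 128)
scene  <- melanocyte_scene(c(48, 48), n_cells = 4, seed = 2)
sim    <- generate_flim_stack(scene, acq = acq, seed = 3)
field  <- efilter(flim_phasor(sim$stack))
field
#> Phasor field (flim, harmonic 1): 48 x 48 px, 1199 unmasked (52.0%)
#>   mean g = 0.5154, mean s = 0.4390

pair    <- endmember_pair(endmember_phasor(endmember_eumelanin(), acq$omega),
                          endmember_phasor(endmember_pheomelanin(), acq$omega))
cursors <- place_cursors_on_segment(pair, k = 7, radius = 0.04)
melanin_profile(assign_pixels(field, cursors), field)
#> Melanin profile (flim), 7 clusters over 2304 px:
#>  cluster id fraction n_pixels mean_g mean_s
#>        i  1  0.06858      158 0.5986 0.4249
#>       ii  2  0.05252      121 0.5680 0.4313
#>      iii  3  0.07595      175 0.5408 0.4396
#>       iv  4  0.05122      118 0.5137 0.4444
#>        v  5  0.06250      144 0.4877 0.4470
#>       vi  6  0.05252      121 0.4587 0.4486
#>      vii  7  0.07292      168 0.4276 0.4546
```

Cluster *i* (largest `g`, smallest phase angle) is the shortest-lifetime,
eumelanin-rich end; cluster *vii* the longest-lifetime, pheomelanin-rich
end. The `fraction` column is each cluster's share of all 2304 image pixels
— about 44% of this image is melanin-segmented, the rest is background or
below the 20-photon intensity threshold. The cluster means march along a
straight chord in phasor space, the signature of a two-species mixture.

The same workflow runs end to end from a JSON config:

```r
run_pipeline(system.file("extdata", "demo_config.json", package = "melphasor"),
             out_dir = "demo_out")
```

writing the stack, phasor field, cursors, a 7-row melanin profile CSV,
region statistics, and a manifest of MD5 hashes that is byte-identical
across reruns with the same seed.

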