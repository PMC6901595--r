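---
title: "Fit-free phasor analysis of melanin FLIM and spectral images"
author: "melphasor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fit-free phasor analysis of melanin FLIM and spectral images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5,
                      fig.height = 4)
library(melphasor)
```

## The problem

Melanocytes store two chemically distinct melanin pigments in their
melanosomes: eumelanin (dark, brown-black) and pheomelanin (light,
yellow-red). Both are weakly autofluorescent under two-photon excitation,
with opposite signatures: eumelanin-rich material shows a *short*
fluorescence lifetime and *red-shifted* emission, pheomelanin-rich material a
*long* lifetime and *blue-shifted* emission. Quantifying the ratio of the two
species pixel by pixel — without extracting or degrading the tissue — is the
goal of this package. The reference use case is heterogeneously pigmented
human choroidal melanocytes, but nothing in the code is specific to the eye.

Because melanin decays are complex and multi-exponential, curve fitting every
pixel is fragile. The phasor approach is "fit-free": each pixel's decay (or
emission spectrum) is reduced to the first Fourier coefficient and displayed
as a point in a 2-D plot, where mixtures obey simple vector algebra.

## Lifetime phasors

For a TCSPC decay $I(t)$ acquired over one laser period $T = 1/f$ the phasor
coordinates at harmonic $h$ are

$$ g = \frac{\sum_k I(t_k)\cos(h\omega t_k)}{\sum_k I(t_k)}, \qquad
   s = \frac{\sum_k I(t_k)\sin(h\omega t_k)}{\sum_k I(t_k)}, \qquad
   \omega = 2\pi f, $$

with $t_k$ the *bin centres* (symmetric quadrature error; the discrete sums
converge to the continuous transform as the bin width shrinks). A
mono-exponential decay of lifetime $\tau$ maps to

$$ g = \frac{1}{1 + (h\omega\tau)^2},\qquad
   s = \frac{h\omega\tau}{1 + (h\omega\tau)^2}, $$

which lies exactly on the *universal circle* $(g-\tfrac12)^2 + s^2 =
\tfrac14$. Because $s/g = h\omega\tau$ is strictly increasing in $\tau$, the
phase angle orders species by lifetime. Mixtures are intensity-weighted
vector sums, so all mixtures of two species fall on the chord joining their
phasors — a *linear* phasor distribution is the signature of a two-fluorophore
system, and the position along the chord is the photon fraction of each
species. `fraction_decompose()` recovers that fraction by orthogonal
projection onto the endmember chord, reporting the perpendicular distance as
a residual so pixels contaminated by a third species can be flagged instead
of silently clipped.

```{r universal-circle}
acq <- acquisition_config()       # 80 MHz, 256 bins, 32 x 8.9 nm channels
w <- acq$omega
single_exp_phasor(1 / w, w)       # the (0.5, 0.5) symmetry point
```

Periodic excitation matters at 80 MHz: a 4 ns decay retains
$e^{-T/\tau} \approx 4\%$ of its initial amplitude at the end of the 12.5 ns
period, so the simulator wraps decays modulo the period (the "incomplete
decay" effect) and the analytic phasor above is exact for the wrapped decay —
the harmonic frequency is a Fourier frequency of the periodized signal.

## Spectral phasors

An emission spectrum binned into $n_{ch}$ channels with centres $\lambda_c$
transforms with argument $2\pi n(\lambda_c - \lambda_i)/(\lambda_{max} -
\lambda_{min})$. The phase angle grows counter-clockwise from $(1, 0)$ with
red shift, and for a narrow symmetric spectrum equals the spectrum's centre
of mass, so `peak_wavelength()` inverts it to nanometres. The modulus falls
with spectral width: an infinitely broad (background) spectrum lands at the
origin. Defaults follow the acquisition this package emulates: 32 channels of
8.9 nm covering 410–696 nm.

Two conventions are configuration rather than physics, because the acquiring
instrument does not define them: the initial wavelength $\lambda_i$ (default
$\lambda_{min}$) and the spectral harmonic $n$ (default 1, which keeps the
angle-to-wavelength inversion single-valued across the acquisition range).
The FLIM harmonic defaults to 1 for the same reason.

## Calibration and filtering

Instrument phase delay and demodulation are corrected by referencing: a dye
of known mono-exponential lifetime (ATTO 488 in water by convention; its
lifetime is configurable and defaults to 4.1 ns) is measured once, and the
unique rotation + scaling about the origin that maps the measured reference
phasor onto its analytic position is applied to every pixel.

Phasor coordinate images are denoised with the E-filter: a median convolution
filter applied to g and s independently (default 3×3, one pass), which
reduces phasor variance without degrading image resolution. Border pixels —
those within the kernel radius of an image edge — are deliberately left
unfiltered, matching the convention of the original FLIM software this
reimplements. Masked neighbours are excluded from each median, and the median
of an even neighbour count is the *lower* median, a deterministic tie-break.

## Cursor segmentation and the melanin profile

Segmentation is cursor-based and deliberately manual-equivalent: circular
selections in phasor space whose member pixels are painted back onto the
image. `place_cursors_on_segment()` reproduces programmatically the
seven-cluster scheme used for melanin work — seven cursors evenly spaced
along the eumelanin-to-pheomelanin chord, ordered from shortest to longest
lifetime (i &lt; ii &lt; … &lt; vii). Pixels inside several disks go to the
nearest centre, exact ties to the lowest id, so segmentation is
order-independent and pure. There is no automatic cluster discovery by
design: cursors are explicit, inspectable inputs.

The quantitative profile statistic is the *ratio fraction*:

$$ \frac{\text{pixels mapped to a segmented phasor cluster}}
        {\text{total image pixels in the sampled field}} $$

The denominator is the full image, masked pixels included — so fractions are
comparable across fields with different background coverage, and the sum over
cursors is at most 1.

```{r profile-demo}
acq <- acquisition_config(image_shape = c(48, 48), n_time_bins = 128)
scene <- melanocyte_scene(c(48, 48), n_cells = 4, seed = 2)
sim <- generate_flim_stack(scene, acq = acq, seed = 3)
field <- efilter(flim_phasor(sim$stack))
pair <- endmember_pair(endmember_phasor(endmember_eumelanin(), acq$omega),
                       endmember_phasor(endmember_pheomelanin(), acq$omega))
cursors <- place_cursors_on_segment(pair, k = 7, radius = 0.04)
melanin_profile(assign_pixels(field, cursors), field)
```

## Region statistics

`region_average_points()` computes the photon-weighted mean phasor of
explicit pixel regions (phasor estimators are photon-weighted by
construction; an unweighted flag exists). Populations of average points are
compared on their *s* coordinates with a two-sample t test — Welch's
unequal-variance form by default, since nothing guarantees equal cluster
variances; the pooled Student form is a flag away. Only *s* is tested,
mirroring the established practice for these phasor populations; no
multiple-testing correction is applied across cluster pairs, again mirroring
practice. `linearity_score()` quantifies the two-fluorophore linearity claim
by total least squares: the perpendicular RMS residual of cluster means
around the first principal direction.

Phasor scatter obeys shot noise: the SD of a pixel's phasor position scales
as $1/\sqrt{N}$ photons. `photon_scaling_check()` measures this directly and
fits the log-log slope, a useful health check on any simulated or measured
configuration.

## The synthetic scene generator

No real microscope data ships with this package; every stage is validated on
synthetic stacks with known ground truth. `melanocyte_scene()` emulates the
morphology that matters for segmentation: disk-shaped cell bodies with a
nuclear void, dense perinuclear melanosome granules, sparse granules along a
few radiating peripheral processes, and one eumelanin photon fraction per
cell. The two default endmembers carry the printed control values for this
system: eumelanin-like — biexponential decay with intensity-averaged lifetime
≈ 1.7 ns, emission peak 610 nm; pheomelanin-like — intensity-averaged
lifetime ≈ 2.4 ns, emission peak 589 nm. Both are biexponential so their
phasors sit *inside* the universal circle, as real melanin phasors do.
Published sources do not constrain melanosome granule geometry, emission
FWHM (60 nm here), or per-pixel photon budgets; those defaults were chosen
once as plausible for 2PM melanin imaging and are exposed in the
configuration rather than tuned.

Mixing is by photon (intensity) fraction, not molar fraction, because that is
what phasor decomposition recovers. Noise is Poisson per bin; a `noiseless`
mode returns exact expectations so tests can separate estimator bias from
shot noise. A `snr_scale < 1` on the spectral generator emulates the poorer
photon budget of descanned spectral detection relative to non-descanned FLIM
detection. Optional confounder species (NADH-like, ECM-like, heme-like) are
available for separation studies.

What the generator does **not** model — and therefore what passing tests do
not establish about real data: optical blur (no PSF), photobleaching and
photodamage kinetics, detector afterpulsing and dead time, wavelength-
dependent detector response, melanin packing/aggregation effects on quantum
yield, and spatial correlation of noise. Results on real tissue additionally
depend on correct instrument referencing, which here is exercised only
through simulated phase delays.

## Numerical choices

* Discrete transforms use bin/channel centres; quadrature error is
  $O(\Delta^2)$ and symmetric.
* Decay generation uses exact per-bin integrals of the wrapped exponential,
  not sampled densities, so expectations are exact at any bin count.
* The two-exponential fit (`fit_biexp()`) profiles the amplitudes out
  linearly and optimizes only the two lifetimes (variable projection), from
  the fixed start grid (0.3, 2), (0.5, 3), (1, 4) ns; best residual wins,
  ties go to the smaller short lifetime. Deterministic by construction.
* Fractions are clipped to [0, 1] after projection; the perpendicular
  residual, not the clipping, is the off-segment diagnostic.
* Intensity threshold defaults to 20 photons/pixel: below that the phasor
  scatter (SD ≈ $1/\sqrt{N}$ ≈ 0.22) is wider than typical cursor radii and
  assignment is meaningless.
* One R RNG stream per generated stack, seeded from the user seed; identical
  (configuration, seed) pairs reproduce stacks bit-exactly.
* On-disk stacks are multi-page TIFF, 16-bit unsigned; counts beyond 65535
  are promoted to 32-bit samples scaled into [0, 1] by a recorded power of
  two, which round-trips integer counts exactly.

## Problem sizes used in validation

The shipped tests and the acceptance script run entirely on synthetic data at
desk scale, chosen to keep each check statistically meaningful: 4096-bin
noiseless decays for quadrature accuracy; a 128×128 single-species image at
1000 photons/pixel for circle membership after calibration; a 64×64
eumelanin-to-pheomelanin ramp at 3000 photons/pixel for seven-cluster
linearity; 11 mixing fractions × 100 pixels at 5000 photons/pixel for
fraction recovery; 1000 reseeded repeats of 15-point populations for t-test
size and 200 for power; 500 replicates per photon level for the shot-noise
law. The demo pipeline runs a 64×64, six-cell scene end to end in seconds.

## Known limitations

* Unmixing is strictly two-endmember; three or more species are handled
  geometrically by cursors, not by inversion.
* Cursor radii are user configuration; no data-driven radius selection is
  provided.
* The E-filter is O(passes × pixels × kernel²) in plain R — fine for the
  image sizes here, but a compiled kernel would be warranted for 1024×1024
  production images.
* No reader for vendor FLIM formats (.sdt, .ptu, .lsm); the TIFF + JSON
  sidecar pair is the interchange format.
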