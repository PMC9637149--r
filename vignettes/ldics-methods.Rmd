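---
title: "Quantifying lipid droplets in label-free THG images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lipid droplets in label-free THG images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Third-harmonic generation (THG) microscopy produces label-free images of
living fungal hyphae in which lipid droplets (LDs) appear as bright,
quasi-circular puncta of roughly 0.3-1.6 µm diameter, about ten times
brighter than the chitinous cell wall that rims the cell. Two quantities
summarise the lipid state of a hypha: the droplet number density (droplets
per µm² of projected hypha area) and the mean droplet diameter. `ldics`
implements two independent estimators of both:

* **PSA** (particle size analysis): threshold, connected components, count
  and size each particle;
* **ICS** (image correlation spectroscopy): fit the central profile of the
  spatial intensity-fluctuation autocorrelation and convert its amplitude
  and width into a droplet count.

A synthetic hypha-image generator with exact ground truth (droplet
positions, diameters, wall geometry, hypha mask) backs every stage with
testable expectations.

## The model

For an image $I(x,y)$ with mean $\langle I\rangle$, the normalised
fluctuation autocorrelation is

$$G(\xi,\eta) \;=\; \frac{\langle \delta I(x,y)\,\delta I(x{+}\xi,\,y{+}\eta)\rangle}
{\langle I\rangle^2}, \qquad \delta I = I - \langle I\rangle ,$$

computed by forward/inverse FFT with periodic lags
(`autocorrelate()`). For a field of sparse bright particles, $G(0,0)$ is
inversely proportional to how many particles the frame contains, and the
width of the central lobe tracks the particle size. The central horizontal
profile (`extract_g_curve()`) is fitted with a Lorentzian plus offset
(`fit_lorentzian()`):

$$L(\xi) = G(0)\,\frac{w^2}{\xi^2+w^2} + \text{offset},$$

where $w$ is the half width at half maximum. With $r = \mathrm{FWHM}/2 = w$
(in pixels) and frame side $N_{pix}$, the droplet count is

$$N_{LD} \;=\; \frac{N_{pix}\cdot N_{pix}}{r^2\,\pi\; G(0)}$$

(`count_lds()`), the density is $N_{LD}$ divided by the hypha area, and the
reported ICS mean diameter is $\mathrm{FWHM}\times$ pixel size. The free
offset absorbs the slowly varying pedestal left by any residual
non-droplet structure; the zero-lag sample is excluded by default because
uncorrelated detector noise contributes a spike at zero lag only (both are
arguments).

Cross-channel colocalization (`iccs_fraction()`) computes $G_{aa}$,
$G_{bb}$ and the cross-correlation $G_{ab}$, fits all three profiles the
same way, and reports the interacting fraction of channel-a clusters as
$G_{ab}(0)/G_{bb}(0)$ (both directions are returned). Whole-mask Pearson
correlation and an above-threshold variant accompany it.

## Wall suppression: why the pipeline subtracts a fixed value

The wall rim is dim (about 10% of the droplet peak) but long, and it
corrupts the correlation with a strong anisotropic pedestal, so it must be
removed before ICS. The removal procedure is iterated background
subtraction with clipping: subtract the mean intensity of the region
outside the hypha mask from every pixel, clip negatives to zero, repeat
(20 times by default).

`subtract_background()` implements two variants of the iteration, and the
distinction matters more than it looks:

* **Re-estimated** (`mode = "reestimate"`): the outside mean is recomputed
  on the current image each round. After the first round the outside
  consists of clipped noise, whose mean decays like a Gaussian tail, so
  the *cumulative* subtraction saturates at roughly the background plus
  two noise standard deviations. A wall at five times the background can
  therefore never be driven to zero this way, and whatever survives
  (wall crest, elevated cytoplasm) inflates the image mean; since
  $G \propto 1/\langle I\rangle^2$, the droplet amplitude collapses and
  counts come out several-fold too high. We measured 5-10x overcounts on
  synthetic data with this variant.
* **Fixed** (`mode = "fixed"`): the outside mean is measured once and the
  same value is subtracted every round, for a cumulative removal of
  $20\,b$. Everything dimmer than that — medium noise, cytoplasm, the
  wall — becomes exactly zero, which is precisely the practical endpoint
  ("the wall disappears") the procedure is meant to reach, and is what
  integer image arithmetic in interactive tools effectively does.

The analysis pipelines (`ics_quantify()`, `coloc_quantify()`,
`auto_subtraction_count()`) therefore default to the fixed variant, while
`subtract_background()` itself defaults to re-estimation, which satisfies
the textbook fixed-point behaviour on noise-free input (one iteration
zeroes a constant outside level; further iterations change nothing).
`auto_subtraction_count()` offers the data-driven stopping rule — stop
when the ICS count changes by less than 5% per additional subtraction —
and emits the full count-versus-iteration trace.

As an alternative wall-removal route, `ics_quantify(crop_um = ...)`
erodes the mask and zeroes everything outside it ("manual cropping")
before subtracting; the background value is then taken from the uncropped
image, since cropping artificially zeroes the background region. On
synthetic data the two routes agree to within a few percent in the final
count.

## Segmentation

`estimate_hypha_mask()` smooths with a Gaussian (default sigma 0.6 µm —
large enough that smoothed pixel noise is well below the faint
hypha/medium contrast at any realistic pixel size, and far below the
~10 µm hypha width), then applies Otsu's threshold in two stages: the
first split isolates the bright droplet class; a second Otsu split of the
sub-droplet intensities separates hypha from medium. Isolated speckle is
removed by a small morphological opening before closing and hole-filling,
the largest connected component is kept, and the mask is eroded by 1.5
smoothing sigmas to undo the dilation incurred by thresholding low on the
flank of the smoothed wall rim. On synthetic capsules the resulting area
is within about ±2% of the true value (the package tests assert ±5%).

The droplet threshold for PSA (`psa_quantify()`) is Otsu computed on the
*in-hypha* intensity histogram — the region of interest an analyst would
threshold — because on the whole frame the dominant hypha/medium contrast
captures the split and returns the entire cell as one particle. Particle
labelling is 8-connected (the ImageJ convention); sizes are reported as
equivalent-circle diameters, and touching droplets are not split (no
watershed), a known bias at high density.

## The synthetic generator

`generate_hypha_image()` renders a capsule (stadium-shaped) hypha,
default 80 × 10 µm in a 1024² frame at 0.1 µm/pixel: a wall ribbon with a
Gaussian cross-profile (FWHM 0.3 µm) just inside the capsule boundary at
10% of the droplet peak; a faint uniform cytoplasm (1% of droplet peak);
hard-disk droplets with truncated-normal diameters (mean 0.74 µm, sd
0.2 µm, truncated to [0.2, 2] µm) placed uniformly inside the capsule at
least one radius from the wall, rasterized with area-weighted coverage;
Gaussian PSF blur (sigma = 0.3 µm FWHM / 2.355 ≈ 0.127 µm, the lateral
resolution of the imaging system emulated); a uniform background (0.02);
and noise. Droplet density defaults near 15 × 10⁻³ µm⁻², the
control-condition regime; nitrogen-starved regimes are emulated by
raising the density to ~24 × 10⁻³ µm⁻² and shifting diameters downwards.

Noise is Gaussian read noise (sd 2% of the droplet peak) by default,
standing in for analog photomultiplier detection with ~30-frame
averaging. A Poisson option exists, but at realistic low photon counts
its heavy discrete tail keeps the clipped outside mean high for tens of
iterations, which no subtraction schedule can overcome; the study
conditions the generator emulates are therefore defined with the Gaussian
model, and this choice is deliberately conservative about what the tests
can show (see limitations).

`generate_coloc_pair()` builds a two-channel pair in which channel B (a
pseudo lipid-stain fluorescence channel, rendered with the same wall and
optics) shares a chosen fraction of channel A's droplets and replaces the
rest with independent placements; with a shared fraction of 1 and no
noise the channels are identical.

What the generator does **not** emulate: 3D sectioning (droplets are
always exactly in focus and at full brightness), cytoplasmic organelle
texture, droplet brightness variability, optical aberrations, and
non-circular droplets. Tests passing on this generator show the
estimators behave correctly on their own model assumptions; they do not
certify performance on real images, where defocused and dim droplets
make both methods undercount relative to visual inspection.

## Numerical choices

* Correlations use periodic FFT lags with no zero-padding; only the
  central lobe (lags ≪ frame) informs the fit.
* Lorentzian fits run bounded Levenberg–Marquardt
  (`minpack.lm::nls.lm`) with $w \in (0, N/4]$, amplitude $\ge 0$, free
  offset; initial values are taken from the curve (peak above tail
  median, first half-crossing, tail median), and several fallback starts
  are tried, keeping the converged fit with the lowest deviance. An
  essentially zero amplitude (e.g. the cross-correlation of two channels
  with no shared structure) converges to the lower bound rather than
  failing.
* Degenerate inputs error eagerly: all-zero images, constant channels
  for Pearson, empty or full-frame masks, erosion that empties a mask.
* The coloc identity `iccs_fraction(a, a) = 1` holds exactly because all
  three correlation profiles are fitted with identical settings.

## Known limitations

The counting formula divides the frame area by $\pi r^2 G(0)$ with
$r = \mathrm{FWHM}/2$ of the fitted G curve. For a uniform disk of radius
$R$, the autocorrelation half-width is $0.81R$, so $\pi r^2 G(0)$
understates the droplet area share by ~35% and the formula *overestimates*
the count by ~1.5x (the analogous factor for Gaussian spots is 1.44). The
package's own acceptance experiments measure exactly this: median
recovered ICS density is 1.0x truth in the small-droplet regime
(0.46 µm, where clipping erosion of the droplet skirts offsets the bias)
but 1.5-1.6x in the 0.74-0.78 µm regimes, while PSA stays within ±10%
everywhere. Consistently, the ICS mean diameter is FWHM-based and comes
out at ~0.7x the PSA equivalent diameter — the same systematic ordering
the two methods display on real THG data. Users comparing conditions are
unaffected (the bias cancels in ratios and time courses — the
starved/control density ratio is recovered correctly by both methods),
but absolute ICS counts should be read with this factor in mind.

Test and acceptance problem sizes: recovery experiments use 20 synthetic
hyphae per regime at 1024² pixels; the ICS/PSA concordance batch uses 20
hyphae (five per control/starved group with varied geometry, per-image
counts ~8-50); colocalization uses 512² frames with 30 droplets per
channel. These sizes keep the full validation suite to a few minutes on
one CPU while leaving the medians stable to a few percent.
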