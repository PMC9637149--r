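# ldics

Quantification of lipid droplets in label-free third-harmonic-generation
(THG) microscopy images of fungal hyphae, by **image correlation
spectroscopy (ICS)** and **particle size analysis (PSA)**.

THG microscopy images living filamentous fungi without staining: lipid
droplets appear as bright sub-micron puncta (~10x brighter than the cell
wall rim) scattered through the hypha cytoplasm. Their number density
(droplets per µm² of hypha area) and mean diameter track the cell's lipid
metabolism, e.g. the transient droplet accumulation triggered by nitrogen
starvation. This package implements the full analysis chain for such
images, plus a synthetic hypha-image generator with exact ground truth
that validates every stage.

## What it computes

ICS estimates the droplet count from the spatial intensity-fluctuation
autocorrelation
G(ξ,η) = ⟨δI(x,y) δI(x+ξ,y+η)⟩ / ⟨I⟩²,
whose central profile is fitted with a Lorentzian
L(ξ) = G(0)·w²/(ξ²+w²) + offset. With r = FWHM/2 = w (pixels), the count
in an N_pix × N_pix frame is

    N_LD = N_pix² / (r² · π · G(0))

and the density is N_LD divided by the segmented hypha area. Before
correlation, the bright cell-wall rim is erased by iterated background
subtraction (outside-hypha mean, subtracted with clipping, 20 rounds by
default). PSA instead thresholds the image (Otsu on the in-hypha
histogram), labels 8-connected components and measures per-particle area,
equivalent diameter, centroid and circularity. Two-channel colocalization
(Pearson correlation and the ICCS interacting-cluster fraction
G_ab(0)/G_bb(0)) identifies THG puncta as lipid droplets against a
lipid-stain fluorescence channel.

## Worked example

```r
library(ldics)

# a synthetic control-condition hypha: 80 x 10 um capsule, 12 droplets,
# 1024 x 1024 px at 0.1 um/px, wall at 10% of droplet peak
spec <- synthetic_spec(seed = 42, n_droplets = 12)
sim  <- generate_hypha_image(spec)

mask <- estimate_hypha_mask(sim$image)
ics  <- ics_quantify(sim$image, mask = mask)   # 20 subtractions -> G fit
psa  <- psa_quantify(sim$image, mask = mask)   # Otsu -> particle analysis
```

Printing the results:

```
<hypha_mask> 1024 x 1024 px, 76696 in-mask px, area 767.0 um^2
<quant_result/ICS> N = 21.7, density = 0.0283 um^-2 (28.3 x 1e-3), mean diameter = 0.579 um
<lorentzian_params> G(0) = 1836, w = 2.893 px (FWHM 5.786 px), offset = 1.245
<quant_result/PSA> N = 12.0, density = 0.0156 um^-2 (15.6 x 1e-3), mean diameter = 0.944 um
ground truth: 12 droplets, density 15.4 x 1e-3 um^-2, mean diameter 0.89 um
```

Reading these numbers: the segmented area (767 µm²) is within 2% of the
true capsule area; PSA recovers the droplet count exactly and the density
(15.6 × 10⁻³ µm⁻²) to within 2%. The ICS count (21.7) overshoots —
the counting formula takes r from the G-curve FWHM, which for disk-like
droplets is ~0.8 of the true diameter, an intrinsic ~1.5x count bias that
cancels in condition-to-condition ratios (see the methods vignette). The
ICS mean diameter (FWHM-based, 0.58 µm) is correspondingly smaller than
the PSA equivalent diameter — the same ordering the two methods show on
real THG images.

Other entry points: `generate_coloc_pair()` + `coloc_quantify()` for
two-channel colocalization, `auto_subtraction_count()` for the
data-driven number of background subtractions (with the count-vs-
iteration trace), `crop_wall()`/`ics_quantify(crop_um=)` for the manual
wall-cropping route, `batch_run()` for config-driven batch tables, and
`diameter_histogram()`/`treatment_ratio()` for group summaries.

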