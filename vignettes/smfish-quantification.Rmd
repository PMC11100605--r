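---
title: "Per-cell smFISH quantification in islet tissue: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-cell smFISH quantification in islet tissue: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smfishq)
```

## The measurement problem

Single-molecule fluorescence in situ hybridization (smFISH, here the
RNAscope amplification chemistry) renders individual mRNA molecules as
diffraction-limited fluorescent foci. In pancreatic islet sections the
question is typically asked *per cell type*: how many copies of an
interferon-response transcript does an individual insulin-positive beta
cell carry, and what fraction of those transcripts sit in the nucleus
versus the cytoplasm? Answering it from a multi-channel image requires a
chain of inferences, each of which this package implements as a separate,
testable stage:

1. **Nucleus masks** from the DAPI channel (or supplied externally by any
   segmenter), post-processed by removing duplicates and objects smaller
   than `min_nucleus_area_px` (default 3000 px, about 2.7 micrometres
   squared at the default 0.03 micrometre pixel edge).
2. **Cell boundaries** predicted by extending each nuclear boundary
   radially: every background pixel within `cell_expansion_radius_px` of a
   nucleus joins the nearest nucleus's cell (a Voronoi-constrained
   dilation).
3. **Beta / non-beta classification** from the per-cell mean insulin
   intensity: a histogram of the per-cell means, Savitzky-Golay smoothing,
   and the local minimum between the two dominant modes as the intensity
   threshold.
4. **Spot detection** per mRNA channel with a multi-scale
   scale-normalized Laplacian-of-Gaussian (LoG) filter.
5. **Multi-mRNA focus deconvolution**: the intensity of a single mRNA,
   `I1`, is the median intensity in the modal intensity bin of all foci;
   a bright focus containing several co-located transcripts contributes
   `round(intensity / I1)` copies.
6. **Autofluorescence removal** with Tukey's upper fence on focus
   intensities (`Q3 + k * IQR`).
7. **Localization and statistics**: per-cell nuclear fraction
   (`nuclear / total`, zero-total cells excluded), group summaries as
   mean +/- SEM, and Mann-Whitney U tests between groups.

The package also provides two small companion estimators used alongside
imaging experiments: corrected total fluorescence (`ctcf()`, integrated
density minus area times mean background) and log2 signal-to-noise
normalization against the geometric mean of IgG negative controls
(`snr_normalize()`), the convention of spatial-proteomics panels.

## Coordinate and calibration conventions

All positions are row-major, 0-based, with pixel centers at integer
coordinates; sub-pixel focus positions are continuous in this frame. The
default calibration of 0.03 micrometres per pixel edge is back-derived
from the stated equivalence of the 3000-pixel area filter with roughly
2.7 micrometres squared; it is configurable and should be set from the
microscope metadata whenever known.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `min_nucleus_area_px` | 3000 | px | protocol's stated mask filter; strict `<` removal |
| `duplicate_iou_threshold` | 0.5 | — | standard overlap criterion for duplicate proposals |
| `cell_expansion_radius_px` | 10 | px | placeholder; **set per dataset**, there is no universal value |
| `histogram_bin_count` / `savgol_window_bins` / `savgol_polyorder` | 64 / 11 / 3 | bins | conventional smoothing of a few-hundred-cell histogram |
| `log_sigma_min_px` .. `log_sigma_max_px` | 1 .. 6 | px | must bracket the PSF *and* the largest blobs (see below) |
| `log_threshold` | 15 | response | a matched spot of peak amplitude A responds at about A/2; 15 admits spots above ~0.3 of the reference single-mRNA amplitude while rejecting smoothed noise |
| `aperture_radius_mult` | 2 | x scale | photometry disk radius; aperture-corrected (see below) |
| `tukey_k` | 1.5 | — | textbook fence; see the trade-off discussion |
| `count_clamp_min` | 1 | copies | a detected, retained focus is at least one mRNA |

## Numerical choices

**Focus photometry and aperture correction.** A focus's intensity is the
background-subtracted sum over a disk of radius `m = aperture_radius_mult`
times the detected scale, with the background taken as the median of the
surrounding annulus. A disk of radius `m * sigma` contains only
`1 - exp(-m^2 / 2)` of a Gaussian spot's mass (86.5% at m = 2), so the raw
sum is divided by that analytic fraction; `intensity` therefore estimates
the focus's *full* integrated intensity. The deconvolution ratio
`intensity / I1` is insensitive to this constant, but the absolute scale
of `I1` is then directly comparable to physical expectations
(`amplitude * 2 * pi * sigma^2` for a Gaussian PSF).

**Scale range and autofluorescent blobs.** Autofluorescent debris is
several times larger than the PSF. If the LoG scale ladder stops at the
PSF scale, a large blob fragments into several moderate-intensity foci
that can individually slip under any outlier fence. The default scale
range therefore extends to 6 px so that blobs are detected as single,
extremely bright foci, which the fence then removes. When adapting the
pipeline to other data, keep `log_sigma_max_px` comfortably above the
size of the brightest contiguous structures that are *not* transcripts.

**Mode finding on noisy histograms.** With a few hundred cells, the
insulin histogram is jagged and the two *highest* local maxima can both
sit on the same underlying mode. The threshold finder ranks candidate
modes by topological persistence (the height a peak survives before
merging into a larger one), which equals the naive two-highest-maxima
rule on clean bimodal histograms and is robust on jagged ones. Negative
smoothed counts are clipped to zero beforehand. Declaring bimodality from
sampling noise is unsafe, so a dip criterion is enforced: the valley
between the two candidate modes must fall below half the lower mode's
height, otherwise a `smfishq_unimodal_error` is raised (configurable
fallback: Otsu's threshold with a logged warning). Cells exactly at the
threshold are non-beta, a deterministic tie rule.

**Savitzky-Golay edges.** Edge bins are smoothed by evaluating the
first/last window's least-squares polynomial off-center (the "interp"
convention), which avoids manufacturing artificial boundary minima that a
zero-padded filter would create.

**Quantiles, rounding, ties.** Tukey's fence uses the linear-interpolation
quantile rule (the one under which {1, 2, 3, 4, 100} gives Q1 = 2,
Q3 = 4, so only 100 is flagged at k = 1.5). Only the upper fence is
applied: dim foci are already handled by the detection threshold, and the
fence's purpose is to prevent a bright blob from being counted as many
mRNAs. Count deconvolution rounds half to even and clamps retained foci
at `count_clamp_min`. Duplicate masks resolve ties toward the smaller
label id; equidistant pixels in the cell expansion go to the lower label
id; the modal intensity bin resolves ties toward lower intensity.

**The fence / multiplet trade-off.** The fence is a quantile rule on the
focus-intensity distribution. When intensities are tightly concentrated
(high signal-to-noise, as in the bundled simulator where the intensity CV
is a few percent), Q1 and Q3 both sit on the single-mRNA peak, and the
conventional k = 1.5 fence lands barely above `I1` — flagging every
genuine multi-mRNA focus. In that regime the fence must be sized from
what it is meant to separate: it should clear `k_max * I1` (the largest
credible multiplet) while staying below the autofluorescence scale, which
is orders of magnitude brighter in integrated intensity. The package's
synthetic validation uses `tukey_k = 400` for exactly this reason; with
broad real-world intensity distributions the conventional 1.5 is
appropriate. A per-cell-count variant of the fence is available via
`tukey_on = "cell_counts"`, flagging all foci of cells whose provisional
totals are beyond the fence.

**Order of operations.** Outliers are flagged before `I1` estimation and
counting, so autofluorescence can neither shift the modal bin nor be
counted; this matches the purpose stated for the fence (preventing
overcounting) even though prose descriptions of such pipelines often list
the fence last.

**Exact vs approximate Mann-Whitney.** For `n_a + n_b <= 12` without ties
the two-sided p-value is exact, computed from the classic counting
recursion for the null distribution of U; otherwise a normal
approximation with mid-ranks, tie-corrected variance and a 0.5 continuity
correction is used. Identical samples give p = 1. No multiple-testing
correction is applied; per-gene p-values are reported as-is and the
report states this explicitly.

## The synthetic world

`sim_params()` describes the reference world the test-suite validates
against; every default was chosen once, from the biology and optics being
emulated, and is documented here rather than tuned:

* **Geometry.** 200 cells on a 2048 x 2048 px field; elliptical nuclei
  with semi-axes 33-40 px placed without overlap; cells are the 22-px
  Voronoi-constrained dilation of their nuclei. Nuclear areas (~3400-5000
  px) sit just above the 3000-px mask filter, mirroring the scale the
  filter was designed for, and cell areas (~10,000 px) make 20 transcripts
  per cell optically resolvable at a 1.5-px PSF — the density regime real
  tissue sections occupy.
* **Cell identity.** 70% beta cells (the typical mouse-islet fraction);
  per-cell insulin intensity N(150, 15) for beta vs N(40, 8) for non-beta,
  a cleanly bimodal population.
* **Transcripts.** Per-gene Poisson counts (default mean 20 per beta
  cell, 2 per non-beta cell); 15% of foci are multiplets of 2 or 3
  co-located mRNAs (probabilities 0.7 / 0.3); a configurable fraction
  (default 0.3) of foci is placed uniformly in the nucleus, the rest
  uniformly in the cytoplasmic ring.
* **Optics.** Isotropic Gaussian PSF, sd 1.5 px; single-mRNA peak
  amplitude 100; flat background 10; additive Gaussian read noise sd 5
  (5% of the unit amplitude); rendering truncated at 4 sigma (<0.1% mass
  loss). Per mRNA channel, 5 autofluorescent blobs at 10x amplitude and
  3x spatial extent.

**What the simulator does not emulate** — and hence what a green test
does *not* establish: shot (Poisson) noise and detector gain structure,
optical aberrations and z-defocus, tissue autofluorescence *texture*
(only discrete blobs are modelled), probe-specific amplification
variability (real RNAscope focus intensities have much larger CVs),
segmentation errors from crowded or overlapping nuclei, and any spatial
pattern of transcripts beyond uniform-within-compartment. Recovery
results on this world demonstrate the correctness of the algorithmic
chain, not field performance on real sections.

## Design decisions that were genuinely open

* The foundation-model segmenter used upstream of pipelines like this one
  is deliberately out of scope; the package accepts externally produced
  label masks as first-class input and provides a classical fallback
  (Otsu threshold + marker-based watershed on the distance transform).
  The downstream mathematics is agnostic to the mask source.
* "Duplicate mask" is quantified as IoU >= 0.5 (configurable); duplicates
  can only exist among overlapping mask *proposals*, so the IoU rule
  applies to list input, while a flat label image only undergoes the area
  filter.
* The radial expansion radius has no stated universal value; the default
  (10 px) is an explicit placeholder and the simulator's world uses its
  own true value (22 px), which analysis configs must match — as they
  would for a real dataset, where the radius is chosen from cell
  morphology.
* Whether the fence applies to focus intensities or per-cell counts is
  ambiguous in prose descriptions of this pipeline family; intensities
  are the default here, the count variant is behind a flag, and no claim
  is made about which the original authors used.
* The Mann-Whitney unit of analysis (cell vs islet) is left to the
  caller: per-cell tables carry everything needed for either aggregation;
  absent an islet mask the field is treated as one islet.

## Known limitations

* 2D only: no z-stacks, no 3D PSF, no time series, no barcoded multi-round
  FISH.
* The TIFF layer reads and writes only uncompressed grayscale baseline
  TIFF (multi-page, 8/16-bit unsigned or 32/64-bit float); compressed or
  proprietary microscope formats must be converted upstream.
* The LoG detector does not attempt sub-PSF multi-emitter splitting;
  co-located transcripts are resolved by intensity only, which is exactly
  the deconvolution model described above.
* `I1` is estimated per image and per gene (staining intensity varies
  between sections); pooling across images, if desired, must be done by
  the caller.
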