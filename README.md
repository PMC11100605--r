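# smfishq

Per-cell quantification of single-molecule FISH (smFISH / RNAscope) in
pancreatic islet tissue sections.

## The problem

smFISH renders individual mRNA molecules as diffraction-limited
fluorescent foci. In islet biology the readouts of interest are
*per cell type*: the mRNA copy number of interferon-response transcripts
(e.g. *Cd274*, *Mx1*, *Cxcl10*, *Stat1*) in individual insulin-positive
beta cells, and the nuclear vs cytoplasmic localization of those
transcripts. Getting there from a four-channel image (DAPI, insulin
protein, two mRNA channels) requires nucleus-mask post-processing,
cell-boundary prediction, marker-based cell typing, spot detection,
deconvolution of bright multi-mRNA foci, autofluorescence removal, and
group statistics. `smfishq` implements that chain as a tested, reusable
pipeline, plus a synthetic islet-image simulator with complete ground
truth so every stage is verifiable without microscope data.

## The model in brief

* **Segmentation**: nuclei from any external segmenter (integer-label
  TIFF/PNG) or the built-in Otsu + watershed fallback; masks with area
  < 3000 px (about 2.7 um^2 at 0.03 um/px) and IoU-duplicates removed;
  cells predicted by radial expansion of the nuclear boundary (nearest
  nucleus within a radius, ties to the lower label).
* **Cell typing**: per-cell mean insulin intensity -> histogram ->
  Savitzky-Golay smoothing -> threshold at the local minimum between the
  two dominant (most persistent) modes; `> threshold` is a beta cell.
* **Spot counting**: scale-normalized multi-scale Laplacian-of-Gaussian
  detection; per-focus intensity = aperture-corrected,
  background-subtracted disk sum; Tukey's upper fence
  (`Q3 + k * IQR`) flags autofluorescent outliers; the single-mRNA
  intensity `I1` is the median of the modal intensity bin, and a focus
  carries `max(1, round(intensity / I1))` mRNAs.
* **Statistics**: per-cell per-gene totals with nuclear/cytoplasmic
  split; nuclear fraction = nuclear/total (zero-total cells excluded),
  reported as mean +/- SEM; Mann-Whitney U (exact by enumeration for
  n_a + n_b <= 12 without ties, otherwise tie-corrected normal
  approximation with continuity correction). Companion estimators:
  corrected total fluorescence `ctcf()` and GeoMx-style
  `snr_normalize()` (log2 of counts over the geometric mean of IgG
  controls).

See `vignettes/smfish-quantification.Rmd` for the full account of the
model, parameter choices and limitations.

## Worked example

Simulate a 40-cell field and quantify it end-to-end:

```r
library(smfishq)
params <- sim_params(field_shape_px = c(1024, 1024), n_cells = 40,
                     gene_means_beta = c(Cd274 = 20, Mx1 = 20),
                     gene_means_nonbeta = c(Cd274 = 2, Mx1 = 2),
                     seed = 7)
field <- generate_field(params)
config <- pipeline_config(cell_expansion_radius_px = 22, tukey_k = 400)
run <- quantify_field(field$stack, config, verbose = TRUE)
#> [segment] 40 nuclei in, 40 after area/duplicate filter (min area 3000 px)
#> [celltype] insulin threshold 77.40952; 29 beta / 11 non-beta
#> [spots] Cd274: 496 foci detected
#> [spots] Cd274: 5 outliers flagged; I1 = 1381.276
#> [spots] Mx1: 476 foci detected
#> [spots] Mx1: 5 outliers flagged; I1 = 1368.054
run
#> <smfish_run> field 'sim000007': 40 cells (29 beta), 972 foci across 2 gene(s)
```

The insulin threshold (77.4) separates the bimodal per-cell intensity
histogram; all 5 simulated autofluorescent blobs per channel are caught
by the fence; the recovered single-mRNA intensity `I1` (1381 and 1368)
sits within 4% of the true integrated spot intensity
(100 x 2 pi x 1.5^2 = 1413.7). Per-group localization and statistics:

```r
run$localization$groups
#>    gene cell_class n_cells mean_nuclear_fraction        sem
#> 1 Cd274       beta      29             0.2702185 0.02456682
#> 3 Cd274   non_beta       9             0.4444444 0.13321754
#> 2   Mx1       beta      29             0.3092861 0.02056892
#> 4   Mx1   non_beta      10             0.2000000 0.11055416
```

The simulated nuclear fraction is 0.30; the beta-cell estimates (0.27,
0.31) recover it, while the small non-beta groups (9-10 cells with ~2
transcripts each) are accordingly noisy. Beta vs non-beta copy-number
comparison (Mann-Whitney, per-cell totals; medians 19 vs 2):

```r
smfishq:::group_stats(run$counts)
#>    gene n_a n_b U_statistic      p_value median_a median_b method
#> 1 Cd274  29  11         319 1.381068e-06       19        2 normal
#> 2   Mx1  29  11         319 1.329827e-06       19        2 normal
```

Ground truth for comparison: `truth_summary(field$truth)` reports true
beta means of 19.8 and 19.4 copies/cell for the two genes — the pipeline
estimates above are within a fraction of a transcript.

Everything is also scriptable from the shell:

```sh
Rscript -e 'smfishq::smfishq_cli()' simulate --params params.yaml --out sim/
Rscript -e 'smfishq::smfishq_cli()' quantify --image sim/stack.tif \
    --channels nucleus,insulin,Cd274,Mx1 --config config.yaml --out run/ \
    --nucleus-mask sim/nuclei.tif
Rscript -e 'smfishq::smfishq_cli()' report --run run/
```

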