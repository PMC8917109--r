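# bvdetect

Automated blood-vessel detection and morphometry for immunofluorescence
(IF) histology in R.

Quantifying angiogenesis — how many vessels, how large, where — is a
routine need in tissue engineering, regenerative medicine and tumor
biology, and is still mostly done by hand. `bvdetect` analyzes RGB
images of IF-stained sections (e.g. CD31 for endothelium, αSMA for the
smooth-muscle layer) and returns, per image, a labeled set of vessel
regions with full morphometric descriptors, plus batch-level summaries,
spatial density maps and detector-evaluation statistics. It is aimed at
researchers who have stained sections and want unbiased, reproducible
vessel counts and morphology without training data or manual outlining.

## The algorithm

Detection is a classical, fully deterministic pipeline:

1. **Normalization** — the raster is min–max normalized to [0, 1] with a
   single global map across channels, preserving relative channel
   intensities.
2. **Channel selection** — the red or green channel is analyzed
   (vessel stains project onto these two); the choice is explicit.
3. **Smoothing** — a 3×3 mean filter (replicate padding) raises SNR.
4. **Thresholding** — Otsu's method on a 256-bin histogram suggests the
   intensity threshold T that minimizes intra-class variance; T can be
   overridden manually. Foreground is intensity > T.
5. **Components & area filter** — maximal 8-connected components are
   extracted and kept when their area lies in
   [`min_area_px`, `max_area_px`] (defaults 50 px and 10 % of the image).
6. **Lumen recovery** — the area filter drops small vessels that are
   mostly lumen. A circular Hough transform finds round structures; a
   removed component is reintroduced when it overlaps a detected circle
   and encloses a hollow region, inside that circle, strictly larger
   than 12.5 % of the component area.
7. **Closing & filling** — morphological closing (3×3 square) bridges
   small wall gaps, then enclosed background (4-connected hole
   definition) is filled, so lumina become part of the vessel region.
8. **Morphometry** — per relabeled vessel: area, perimeter (traced
   boundary contour), centroid, moment-equivalent ellipse axes
   (4·√eigenvalue with the +1/12 unit-square pixel correction),
   eccentricity, orientation, equivalent diameter; in µm/µm² when a
   pixel size is supplied.

Evaluation follows the standard detector metrics — precision
TP/(TP+FP), recall TP/(TP+FN), and their harmonic mean
F = 2PR/(P+R) — after greedy one-to-one centroid matching, plus
Bland–Altman agreement (bias, bias ± 1.96·SD limits), z-score
standardization, and corrected total glomerular fluorescence
(CTGF = integrated density − ROI area × mean background).

A parametric phantom generator renders vessel-like objects (solid
blobs, annuli with lumina, bent elongated profiles) on a black
background with exact ground truth, so the whole pipeline is testable
with no external data.

## Worked example

```r
library(bvdetect)

ph  <- generate_phantom(phantom_spec(n_vessels = 20, seed = 42))
det <- detect_vessels(ph$image, detection_params(channel = "red"))
det
#> vessel_detection: 20 vessels in 512 x 512 image (T = 0.3789, channel red)
#>   vascular area fraction: 0.0836
#>   equivalent diameter (px): median 28.1, range 10.6-59.8

precision_recall_f(match_detections(det, ph$truth))
#> precision 100.0%, recall 100.0%, F-measure 100.0%
```

The suggested threshold T = 0.3789 separates the noisy black background
from the stained objects; all 20 rendered vessels are found, none
hallucinated, and the vascular area fraction is the vessel-pixel share
of the frame. `det$vessels` holds the per-vessel descriptor table, and
`summarize_image()` / `build_density_map()` aggregate counts, density
per mm², diameter/area histograms and smoothed centroid heatmaps.

## Command line

A thin CLI over the same functions lives in `inst/cli/bvd.R`:

```sh
Rscript inst/cli/bvd.R detect  --input 'sections/*.png' --out results \
                               --channel red --min-area 50
Rscript inst/cli/bvd.R phantom --out phantoms --n-images 10 --seed 100
Rscript inst/cli/bvd.R eval    --detections det.csv --truth truth.csv --out m.json
Rscript inst/cli/bvd.R map     --centroids s1.csv,s2.csv --height 994 \
                               --width 742 --out topology
Rscript inst/cli/bvd.R ctgf    --table glomeruli.csv --out ctgf.csv
```

`detect` writes, per image, a vessel CSV, a JSON summary, a 16-bit
label mask (TIFF) and an overlay PNG with white outlines and arrows,
plus an aggregate `batch_report.json` recording the threshold and
parameters used for every image.

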