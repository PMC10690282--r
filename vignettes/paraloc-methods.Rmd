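---
title: "Quantifying paralog protein redistribution from single-cell images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying paralog protein redistribution from single-cell images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paraloc)
```

## The problem

Whole-genome-duplication (WGD) paralogs in budding yeast are retained for
hundreds of millions of years, and one unresolved question is how the two
sister proteins divide or share their ancestral role. A direct way to probe
this is perturbation imaging: tag one protein with GFP, image it in a
wild-type background and in a background where its paralog has been
deleted, and ask whether the protein *redistributes* — changes its
subcellular localization, its abundance, or both. A protein that responds
to paralog loss by moving into the sister's compartment or by increasing
its abundance is a candidate for **compensation**; one that loses its
native localization or abundance shows **dependency**.

`paraloc` implements this analysis end to end for single-plane
fluorescence micrographs: segmentation of single cells, per-cell feature
extraction, a centroid-distance *redistribution score* with ROC-based
threshold selection, per-protein abundance statistics, interaction-network
feature tests, and a two-channel ER/cytoplasm validation assay. Because no
public imaging archive accompanies the original screen at desk scale, the
package ships a synthetic micrograph generator that produces images with
known ground truth, so every stage is testable without any download.

## Synthetic micrographs

`generate_scene()` renders a field of non-overlapping elliptical cells on
a noisy background. Each cell carries one localization class; the class's
*render rule* assigns a relative weight to every interior pixel as a
function of the normalized elliptical radius $u$ (0 at the center, 1 at
the membrane):

| class | render rule |
|---|---|
| cytoplasm | uniform over $u > 0.5$ (interior outside the vacuole) |
| nucleus | disk $u \le 0.3$ |
| vacuole | disk $u \le 0.5$ |
| ER | perinuclear annulus $0.25 \le u \le 0.55$ |
| mitochondria | three radial spoke bands (tubule-like) |
| Golgi / punctate | 3 / 6 small puncta |

Weights are normalized to sum to one per cell, so the total foreground
intensity of a cell equals its programmed abundance exactly when noise is
off. The ER rule is deliberately perinuclear-only: a cortical-rim
component would overlap the cytoplasm support, and the relocalization
mixing rule below would then vacate the rim, which distorts
compartment-level medians. Cortical ER is a real feature of yeast cells
that this renderer does not emulate.

A deletion-background `effect_spec()` programs two responses:

* an abundance log2 fold change (`abundance_lfc`), which scales the
  foreground signal by $2^{\mathrm{lfc}}$; and
* a relocalized fraction `reloc_fraction` $f$ with a target class. The
  mixed weight map is $(1-f)\,\tilde w_{\text{own}} + f\,\tilde
  w_{\text{target}}$, where $\tilde w_{\text{own}}$ is the own-class rule
  with the target's support masked out and renormalized. The masking makes
  the fraction of cell intensity inside the target region equal $f$
  exactly, which is what the recovery tests assert.

Noise is additive Gaussian background (mean 100, sd 8, arbitrary units)
plus a multiplicative shot term with per-pixel sd
$0.5\sqrt{\text{signal}}$, clipped at zero. Per-cell mean intensity is
log-normal around 300 with CV 0.15. None of these values is stated by any
reference; they were chosen once as plausible for spinning-disk confocal
data and are exposed as arguments. The default field is 512 x 512 px with
50-100 cells per field — the acquisition density of the screen — and cell
areas of 400-1200 px. (Cell areas up to 4000 px are supported, but 50-100
cells of mean area 2200 px cannot pack into one field without overlap, so
the default area range stays in the lower half.)

`generate_strain_panel()` emulates the screen design: four strains per
paralog pair (each GFP gene in wild-type and deletion background), three
replicates, four fields per replicate, plus negative-control pairs with
null effects that emulate randomly paired genes. All randomness flows from
one integer master seed through derived per-scene seeds; identical seed
and configuration give bit-identical panels.

What the generator does **not** emulate: budding morphology and
cell-cycle heterogeneity, 3-D structure, photobleaching, spectral
cross-talk, and biologically realistic texture inside compartments.
Passing recovery tests on these images therefore demonstrates that the
pipeline's statistics behave correctly under the programmed effects; they
do not certify segmentation or feature performance on real micrographs.

## Preprocessing

The background reference is the per-pixel **median across all images of a
dataset**, which removes uneven illumination and fixed-pattern read-out
noise; it is subtracted with clipping at zero (residuals below the median
background carry no abundance information). With an even image count the
median is the mean of the two central values. For segmentation the
subtracted image is transformed as $x' = \ln(x+1)$ and standardized to
mean 0, sd 1 over the whole image (population sd — this is a
normalization, not an inference), which compresses the enormous dynamic
range between dim and bright proteins. Constant images are rejected as
degenerate rather than silently returned.

Replicate-level quality filtering drops replicates with fewer than
`min_cells` cells (default 50, matching the lower end of the per-field
density; no published cutoff exists) and anything on a user-supplied
exclusion list. The original screen excluded genes with mismatched
localization and images with artifacts by visual inspection, so exclusion
is expressed as an explicit list with logged reasons, not automated
detection.

## Segmentation

The segmentation model is pluggable behind a one-call contract: image in,
per-pixel object probability in $[0,1]$ out. The package provides two
reference backends — an *oracle* mode that converts ground-truth labels
into the training-target transform (exact on synthetic data) and an
*intensity* mode (Otsu threshold plus normalized in-mask distance
transform) needing no ground truth. A learned model can be dropped in
behind the same contract; training one is out of scope.

The bespoke pieces are the target transform and the post-processing:

1. **Stencil erosion.** Each labelled cell is eroded with the minimal
   cross: a pixel becomes background if any of its 4-neighbors lies
   outside its own label (out-of-image counts as background). Per-label
   erosion makes touching cells separate.
2. **Target transform.** The eroded binary $B$ is Euclidean
   distance-transformed, clipped at 20 px, scaled to $[0,1]$ ($D'$), and
   combined as $T = 0.8\,B + 0.2\,D'$. Border pixels of eroded stencils
   read $0.81$ — 0.8 at one decimal — rising to exactly 1 where the
   interior distance reaches the 20 px clip. The weight is applied to the
   binary component; that is the only reading consistent with a border
   value of 0.8 and a maximum of 1. Note that an object must erode to an
   interior radius of at least 20 px to reach 1.0; a 40 x 40 square peaks
   at 0.99.
3. **Seeded watershed.** Connected components (4-connectivity) of pixels
   with probability $\ge 0.8$ seed a priority-flood region growing on the
   negated probability map, restricted to the $\ge 0.5$ support. The
   flood is implemented in C++ with a max-heap keyed on probability and
   FIFO insertion order as the deterministic tie-break. Objects strictly
   smaller than 256 px or strictly larger than 8192 px are removed
   (bounds themselves retained) and labels renumbered consecutively.

4-connectivity is used throughout, consistent with the cross erosion; the
Euclidean (not city-block) metric matches the target's construction.

## Single-cell features

Each retained object yields a 64 x 64 frame centered on its centroid
(rounded to the nearest pixel; the frame spans
$[\text{centroid}-32, \text{centroid}+32)$, zero-padded at image edges).
Abundance uses frames cut from the raw background-subtracted image;
features use frames from the standardized image, mirroring the screen's
convention of feeding the network normalized images while measuring
abundance on raw intensities.

The screen's learned embedding contract — 128 features per frame — is
honored by a deterministic reference extractor with a fixed, versioned
block layout: intensity moments and order statistics, 16 quantiles, a
16-ring radial profile (raw and per-frame mean-centered), a 16-sector
angular profile, gradient-magnitude statistics, local 3 x 3 texture with
lag autocorrelations, and binarized-shape moments with radial mask
occupancy. These features are interpretable rather than learned; on
synthetic panels they separate localization classes cleanly (a held-out
nearest-centroid classifier exceeds 90% accuracy in the test suite), but
they are not a substitute for a trained embedding on real data.

## Redistribution score and threshold

All cells of one strain, pooled across replicates, are averaged
coordinate-wise into a centroid; the **redistribution score** of a protein
is the Euclidean distance between its wild-type and deletion-background
centroids. Pooling (rather than per-replicate centroids averaged after)
follows the screen's wording; a per-replicate mode exists for sensitivity
analysis. Scores feed a strictly-greater threshold classification. The
threshold is selected by ROC analysis against labelled true cases and the
negative-control pairs: candidate cuts are midpoints between consecutive
sorted unique scores plus sentinels (midpoints avoid the ambiguity of a
data point equal to the cut under the strict rule), and the cut with
minimal false positive rate wins, ties broken by maximal true positive
rate, then by the smallest cut. The published screen's numeric threshold
(4.73) depends on its trained embedding and is not reproducible here; the
procedure is.

z-scored PCA embeddings (`pca_view()`) are provided for visualization
only — raw features feed the score. The principal-component sign is fixed
by making the largest-magnitude loading positive, so embeddings are
deterministic.

## Abundance statistics

The abundance score of a condition is the grand mean raw pixel intensity
over every pixel of every frame (pixel-weighted, including non-cell
pixels — exactly the screen's convention; a masked mode exists but is off
by default). Relative change is $\log_2(s_{\Delta}+1) -
\log_2(s_{wt}+1)$, oriented deletion-minus-wild-type so positive values
mark the compensation direction. Significance uses the two-sided
Mann-Whitney U test on per-cell frame means pooled across replicates
(exact for tie-free samples with $n_x+n_y \le 12$, normal approximation
with tie and continuity correction otherwise), corrected across genes by
Benjamini-Hochberg. Calls use $|\mathrm{lfc}| \ge 0.2$ (inclusive) and $q
< 0.05$ (strict). `call_comp_dep()` encodes the response logic:
compensation = increase or relocalization into the paralog's wild-type
compartment; dependency = decrease or relocalization to a third
compartment; conflicting signals are flagged rather than silently
resolved.

Because frame means include background pixels, the measured lfc is mildly
compressed toward zero relative to the programmed foreground change (the
pseudocount and residual background add a non-scaling offset). Frame
means also cross-contaminate in dense fields: a 64 x 64 frame reaches
32 px beyond its cell's centroid, so neighboring cells' peripheral signal
leaks in. The leak is asymmetric between backgrounds when a protein
relocalizes between the cell center and the periphery — for a nucleus to
cytoplasm move at 15-30% field fill we measure an lfc bias of about
+0.1 (frame-capture ratios 1.23 vs 1.29) — and it shrinks but does not
vanish at lower density, because random packing still produces close
pairs. This is a property of the whole-frame abundance convention, not of
the synthetic data; the masked-mean mode avoids it at the cost of
depending on segmentation quality.

## Network features

Interaction edge tables (physical and genetic) are cleaned into an
undirected network: self-loops dropped, duplicates collapsed keeping the
strongest evidence (smallest p, then largest $|\epsilon|$); physical
edges can be filtered to physical, high-throughput evidence by column.
Genetic-interaction stringency classes follow the published thresholds:
lenient ($p<0.05$), intermediate ($p<0.05$, $|\epsilon|>0.08$), stringent
($p<0.05$ and $\epsilon>0.16$ or $\epsilon<-0.12$), stringent-negative
($\epsilon<-0.12$), synthetic-lethal ($\epsilon<-0.35$). Pair features:
shared-interactor counts binned against the cohort median (ties at the
median go to "low", since "fewer or more than the median" excludes
equality), shortest-path bins "1" vs "1+" (disconnected pairs are "1+",
the only compatible bin), colocalization Jaccard
$100\,|A\cap B|/|A\cup B|$ with the inclusive $\ge 50$ rule, and
enrichment of private interactors in the sister's compartment via a 2 x 2
Fisher exact test (odds ratio reported as the cross-product ratio, with a
0.5 Haldane correction only when a cell is zero, and reported as such).
Boxplot summaries use linearly interpolated quartiles and $1.5\,$IQR
whiskers.

## Two-channel compartment quantification

The ER/cytoplasm validation assay mirrors the screen's confocal follow-up:
cells within the median major-axis length of the image border are removed;
images with background intensity outside mean $\pm$ sd within a replicate
are discarded (population sd, inclusive bounds); within each cell the
reporter channel's 0.975 quantile marks ER pixels ($\ge$) and the 0.973
quantile marks cytoplasm ($<$), leaving the thin band between unassigned
exactly as stated — no silent merge; cells with fewer than 100 ER pixels
are dropped; and compartment abundances are median GFP over the
compartment divided by the image background (median of non-cell pixels —
no published definition exists, so this is surfaced as a convention).
Quantiles use linear interpolation between order statistics throughout
the package. Abundances are invariant to rescaling both channels and the
background by one constant.

## Numerical conventions and degenerate inputs

* Even-count medians: mean of the two central values.
* Quantiles: R type 7 (linear interpolation).
* Population sd for image standardization and background QC; sample sd
  elsewhere.
* Constant images, empty feature sets, empty samples, zero-margin
  contingency tables and constant-intensity cells raise explicit errors
  or flags; nothing degenerate is silently imputed.
* Watershed tie-break: FIFO among equal probabilities; label order is the
  raster order of seed components, so results are machine-independent.
* All randomness descends from one integer seed; derived seeds stay below
  $2^{31}$.

## Problem sizes in the test suite

The fixed-seed suites use: 8-pair panels (4 programmed-effect + 4
negative-control pairs, both members responding with lfc $\pm 0.5$ and
relocalized fraction 0.6) at 42 cells/field, 3 replicates x 4 fields,
512 x 512 px fields (~11% fill) for screen-level recovery. Effect-pair
classes are (cytoplasm, nucleus), (nucleus, ER), (ER, cytoplasm) and
(vacuole, cytoplasm) — supports geometrically distinct, as the screen
selected paralogs with distinct localizations — and the programmed moves
mix compensation (into the paralog's compartment) with one
dependency-style move into a third compartment (nucleus to ER), keeping
the panel free of the extreme center-to-periphery contamination
differential described above. Segmentation recall uses 5 forty-cell
scenes; the two-channel assay uses 3 replicates x 3 fields x 17 large
cells
(4400-5200 px, so that 2.5% of a cell clears the 100-ER-pixel filter) per
condition for the two-channel assay, with the Cue4-like deletion effect
programmed as lfc 1.0 plus 0.3 relocalization to cytoplasm. With 0.3 of
the signal leaving the ER, an abundance increase must exceed
$\log_2(1/0.7) \approx 0.51$ for ER intensity to rise at all; 1.0 matches
the strong compensatory increase this scenario describes.

## Known limitations

* The reference feature extractor is interpretable but weaker than a
  trained embedding; absolute redistribution scores are not comparable to
  the published ones, and the published 4.73 cut and hit counts
  (32/164 redistributed, 30 abundance hits) are not reproducible without
  the original images and network weights.
* The intensity segmentation backend assumes bright-on-dark, roughly
  convex cells; it is a baseline, not a competitor to a trained model.
* Frame means include neighboring cells' pixels in dense fields; the
  masked-mean mode trades that contamination for sensitivity to
  segmentation quality.
* The synthetic generator's idealized geometry means classifier-grade
  performance claims do not transfer to real data (see above).

## A minimal run

```{r, eval = FALSE}
pairs <- list(
  paralog_pair("GGA1", "GGA2", class1 = "cytoplasm",
               class2 = "mitochondria", lfc1 = 0, lfc2 = -0.5,
               reloc1 = 0.6, reloc2 = 0),
  paralog_pair("CTL1", "CTL2", control = TRUE))
panel <- generate_strain_panel(pairs, seed = 1, shape = c(320L, 320L),
                               n_cells = c(40L, 44L),
                               cell_area = c(400, 1000))
res <- run_screen(panel, run_config())
make_report(res)
```
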