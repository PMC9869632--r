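---
title: "Methods: tile-based slide classification for bladder-cancer grading and staging"
author: "wsipath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tile-based slide classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Transurethral resection specimens of bladder cancer are fragmented and
often lack a complete muscle layer, which makes the two decisions that
drive treatment — is the tumour muscle-invasive, and is it high grade —
error-prone even for experienced pathologists. `wsipath` implements a
patch-based pipeline that takes a whole-slide image (WSI) through
background removal, dense six-class patch classification and a
slide-level confidence score over the three diagnostic categories:

* **HGMI** — high-grade tumour with muscle invasion,
* **HGNMI** — high-grade tumour without muscle,
* **LGNMI** — low-grade tumour without muscle,

plus three auxiliary patch classes that carry no diagnostic weight:
illegible (blurred) area **IA**, normal interstitial area **NIA**, and
non-cellular noise area **NA**. The fixed channel order is HGMI, HGNMI,
LGNMI, IA, NIA, NA throughout.

## Pipeline stages and their models

### Background removal

WSIs are mostly white background. The slide is converted to Rec.601
luminance, a single Otsu threshold is taken from the whole-slide
histogram (maximizing between-class variance; ties broken toward the
smallest threshold, and a split is only a candidate when both classes
are non-empty), and the slide is tiled into 2048 px ROIs. An ROI is
retained when the fraction of pixels at or below the threshold reaches
`min_fraction`. Numerical choices made here, all configurable:

* `min_fraction = 0.1`. The tissue-proportion cutoff is a free
  parameter of the method; 0.1 errs toward keeping tissue.
* One global threshold per slide rather than per ROI: the simpler
  reading of an "adaptive threshold for the image", and it makes
  retained-ROI sets monotone in `min_fraction`.
* `white_floor = 243`: Otsu assumes a bimodal histogram. On a slide
  with no tissue at all it would split the white noise peak and call
  half of the background "tissue", so a slide whose threshold lands
  above the floor is treated as tissue-free. Synthetic backgrounds sit
  at 248 and tissue luminance below ~235, so real (synthetic) tissue
  slides are unaffected.

### Patch sampling

Training patches are 256 px squares at full resolution (the patch side
is a free parameter; 256 is consistent with one heatmap point per 32 px
of slide). The five region-pure classes are sampled by sliding a
window over each annotation polygon and keeping a patch only when its
full rectangle lies inside the polygon, so every patch contains a
single kind of tissue. HGMI patches cannot be region-pure — the class
is *defined* by the co-occurrence of tumour and muscle — so they are
sampled centered on points marked along the tumour–muscle junction
(every 256 px of shared border, at least one per border, clamped
inward at slide edges rather than discarded, because junction examples
are scarce).

Slides are split into fit and tune subsets 4:1, stratified by slide
category and always by slide, never by patch.

### The patch classifier

The classifier is a contract: any function mapping a patch to a
six-class probability vector can be plugged in. The reference
implementation is a compact convolutional network chosen to be
trainable on one CPU in minutes:

* a **stem** reduces the 256 px patch to a 32 × 32 grid of block
  statistics — the mean *and* the standard deviation of each RGB
  channel over each 8 × 8 block (six input channels). Means carry
  stain color; SDs carry local texture energy. The SD channel is what
  lets the network tell sharp high-grade tumour from its blurred IA
  counterpart and see muscle striping after pooling — block means
  alone erase sub-block texture entirely;
* two 3 × 3 valid convolutions (8 and 16 filters, ReLU), each followed
  by 2 × 2 max pooling;
* global average pooling and a dense softmax layer (~1.5k parameters).

Training follows the published recipe exactly: cross-entropy loss, SGD
with momentum 0.9 and weight decay 1e-4 (weights only), initial
learning rate 0.01 multiplied by 0.1 at the 18th and 24th epochs, 30
epochs. Choices the recipe leaves open, fixed here: batch size 64;
class-uniform batch sampling (each batch slot draws a class uniformly,
then a patch of that class) because junction-sampled HGMI patches are
far scarcer than sliding-window patches; the final-epoch model is
kept. Augmentation applies translation (≤10% of the side, edge
replication), quarter-turn rotation, scaling 0.9–1.1, flips and colour
jitter (per-channel gain 0.95–1.05, brightness offset ≤8). Because
jitter interacts with class identity — the high-grade and low-grade
base stains differ by a few intensity percent — stronger jitter
measurably washes out the grade distinction. Augmentation operates at
the network input resolution (on the stem statistics); this keeps the
training set in memory at ~40 MB where raw 256 px patches would need
gigabytes, and every family is well-defined on the statistic planes
(the brightness offset is not applied to SD channels).

Weight initialization is He-normal from a fixed seed; ImageNet-scale
pretraining is deliberately out of scope for a desk-scale reference
network. Training is bit-deterministic for a fixed seed.

### Dense inference and the heatmap

For every 32 px grid point of the slide whose center falls in a
retained ROI, the model evaluates the 256 px patch centered there
(clamped at slide borders) — producing a 6-channel probability field
at 1/32 of slide scale with a coverage mask. Points outside retained
ROIs are uncovered and hold zeros.

Because the convolutions are valid (no padding), per-patch features
are translation-consistent, so the implementation computes the
convolutional features once over the whole pooled slide and reads each
point's prediction out of the shared feature maps, with the global
average pool realized as a 6 × 6 box sum via integral images (both
max-pool phases are computed so every even patch offset aligns). This
is an optimization, not a semantic: it matches the naive
patch-by-patch loop to ~1e-15 and falls back to that loop whenever
offsets do not align with the stem grid. Overlapping outputs are never
averaged; each heatmap point is exactly one patch prediction.

The decision map takes the argmax channel per covered point, ties
broken toward the lowest channel index; uncovered points carry -1.

### Slide-level confidence

For each class, the connected components ("contours") of its decision
region are extracted with 8-connectivity on the heatmap grid, in
scanline order, with minimum area one point. Each contour `i`
contributes its area $a_i$ (points) and the mean probability $p_i$ of
its class channel. The class score is the area-weighted mean

$$P_k = \frac{\sum_{i=1}^{m} a_i\,p_i}{\sum_{i=1}^{m} a_i},$$

and the slide-level confidence is the softmax

$$\mathrm{Prob}_k = \frac{e^{P_k}}{\sum_k^{n} e^{P_k}}.$$

Two points the formulas leave open, resolved as package design
decisions:

* the softmax runs over the **three diagnostic classes only**
  (`n ≤ 3`): slide categories are three, and letting IA/NIA/NA compete
  could not produce a three-way slide label. IA/NIA/NA contours are
  still extracted and reported;
* a diagnostic class with **no contours is excluded** from the softmax
  and receives probability 0, rather than being scored $P_k = 0$ —
  $e^0$ would grant an absent class substantial baseline weight,
  turning absence of evidence into evidence.

The predicted label is the argmax of $\mathrm{Prob}_k$; the derived
binary scores are `mibc_score` $= \mathrm{Prob}_{HGMI}$ (muscle
invasion) and `high_grade_score`
$= \mathrm{Prob}_{HGMI} + \mathrm{Prob}_{HGNMI}$ (grading; all
muscle-invasive disease is high-grade). A slide with no retained
tissue or no diagnostic contour raises a classification-failure error
rather than guessing.

### Evaluation

Hard-label metrics (accuracy, sensitivity, specificity, PPV, NPV; per
class one-vs-rest and for the two binary tasks) carry exact
Clopper–Pearson 95% intervals from beta quantiles. ROC AUC is the
Mann–Whitney concordance probability with half credit for ties,
computed per class one-vs-rest from $\mathrm{Prob}_k$; the "overall"
AUC is the macro average (the pooling rule is not dictated by the
formulas; a micro-averaged AUC is also reported). AUC intervals, when
requested, come from a stratified bootstrap (2000 resamples by
default, seeded) since Clopper–Pearson applies only to proportions.

## The synthetic slide generator

No clinical images ship with the package; every test runs on synthetic
slides with known ground truth. A slide is a 2048 × 2048 8-bit RGB
cartoon of an H&E section: near-white background (248 ± 3), rectangular
tissue regions with class-specific textures — nucleus density, radius
and stain color for tumour grades and NIA; eosinophilic fibers with
sinusoidal striping for muscle; Gaussian-blurred tumour texture for
IA; saturated dark stain blobs without nuclei for NA — plus Gaussian
pixel noise. Texture luminances (tissue ≲ 235, nuclei ≥ ~90) are chosen
so that the slide histogram is genuinely bimodal: tissue below, white
above, the regime Otsu assumes. All randomness derives from one
integer seed per slide; cohorts derive per-slide seeds from a cohort
seed, so generation is bit-reproducible.

Muscle-invasive slides place a high-grade tumour band *between* two
muscle bands (each one eighth of the slide wide), emulating invasive
nests within the muscularis propria. With 256 px patches this has a
deliberate consequence: essentially every patch inside the diagnostic
block contains both tumour and muscle tissue, so the HGMI evidence is
strong and spatially extensive, while no pure-tumour patch exists to
build a confident competing HGNMI region — which is exactly the
situation the area-weighted mean-probability aggregation resolves
well. Non-invasive slides carry one large tumour square instead.
Every slide also carries one NIA, one IA and one NA region, so all six
patch classes are trainable from any cohort.

What the generator does **not** emulate: real nuclear morphology and
chromatin, staining variation between labs, pen marks and tissue
folds, fragmented specimens, carcinoma in situ, and muscle that
appears without adjacent tumour. Passing the end-to-end tests
therefore shows the pipeline machinery is correct and that the method
recovers categories whose visual separations hold at the patch level;
it says nothing about performance on clinical slides.

## Problem sizes and determinism

The end-to-end experiment used by the acceptance checks generates 60
training slides (20 per category; split 48 fit / 12 tune) and 30 test
slides (10 per category) at 2048 px, trains the reference network for
the full 30-epoch recipe, and classifies every test slide. This size
keeps a complete run in single-digit minutes on one CPU while leaving
every pipeline stage at its production setting (full slide size, full
recipe). Equation-level oracles run on 20 additional 512 px slides;
distributional checks use 1000 random histograms (Otsu), 200 random
instances (AUC) and 2000 binomial simulations (interval coverage).

Everything stochastic — generation, splits, initialization, batch
order, augmentation, bootstraps — flows from explicit integer seeds,
and runs are bit-reproducible apart from floating-point noise below
1e-6 introduced by the stitched inference path.

## Known limitations

* The reference network is a texture classifier; it has no capacity
  for the cytologic detail real grading requires and is meant as a
  working stand-in behind the classifier contract.
* Heatmaps persist at float32; analyses that must agree to better than
  ~1e-7 should recompute both sides from the persisted file (as the
  package's own checks do).
* Junction detection handles straight shared borders between polygons,
  sufficient for rectangular synthetic layouts; curved invasion fronts
  would need a rasterized border trace.
* `read_heatmap` reconstructs slide dimensions as multiples of 32; the
  original dimensions are not stored in the TIFF.
* Otsu-based background removal assumes tissue is darker than the
  background; slides dominated by very pale tissue would need a darker
  `white_floor` or a per-ROI threshold.
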