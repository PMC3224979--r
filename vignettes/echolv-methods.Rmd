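---
title: "Left-ventricle segmentation and area variation analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Left-ventricle segmentation and area variation analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`echolv` segments the left-ventricular (LV) cavity in apical
four-chamber 2D-echocardiography sequences over one complete cardiac
cycle and derives the area variation curve (AVC) and area variation
fraction (AVF). This vignette documents the model behind each stage,
the tunable parameters, the numerical conventions, and what the
package's synthetic phantom does and does not establish about real
data.

## Pipeline overview

For every frame index $k$ of the first cardiac cycle:

1. **Temporal averaging.** The working image is the pixelwise mean of
   four frames — $k$ and $k{+}1$ from each of two consecutive cycles,
   aligned on the ECG R wave. Speckle is incoherent between the four
   exposures while anatomy is nearly static, so the composite roughly
   halves the noise standard deviation at the cost of temporal
   resolution (23 ms to 46 ms at 44 frames/s). For the last frame of a
   cycle, $k{+}1$ wraps to the cycle's first frame: cardiac periodicity
   makes the wrapped frame the natural continuation. If the second
   cycle is shorter than the first, trailing frames fall back to the
   two-frame within-cycle mean.

2. **Shift-invariant wavelet denoising** (optional, on by default).
   An undecimated (à trous) 2D transform with the order-12 Daubechies
   pair, 4 levels, all convolutions circular. Every detail band is
   soft-thresholded. The noise scale $\hat\sigma$ is the median
   absolute deviation of the finest diagonal band divided by 0.6745;
   each band is shrunk at the Bayes-adaptive threshold
   $\hat\sigma^2/\hat\sigma_x$, where $\hat\sigma_x^2$ is the band's
   estimated signal variance. We chose the Bayes-adaptive rule over the
   universal threshold $\hat\sigma\sqrt{2\log n}$ deliberately: in a
   redundant transform the universal threshold is so conservative that
   on edge-dominated images it can *increase* the mean squared error
   relative to the noisy input, which defeats the stage's purpose; the
   adaptive rule is the standard alternative and improves MSE across
   the noise levels we simulate. Circular convolutions make the stage
   exactly equivariant under integer circular shifts, which the tests
   assert.

3. **Edge enhancement.** $m_b = \mathrm{clip}(m - \alpha\,(\nabla^2
   G_\sigma * m))$, with $\alpha = 1$, $\sigma = 2$ px, kernel
   truncated at $4\sigma$, reflective borders. Subtracting the
   Laplacian-of-Gaussian response overshoots on the bright side of each
   step and undershoots on the dark side ("self-reinforcing"
   sharpening). This matters structurally: the overshoot ridge along
   the endocardial border is where the watershed dam later settles, so
   sharpening pulls the segmentation towards the true interface. The
   kernel is evaluated as the separable sum $G''(x)G(y) + G(x)G''(y)$;
   the 1D second-derivative taps are recentred to sum to zero so a
   constant image passes through unchanged to machine precision.

4. **Morphological smoothing.** Grayscale closing then opening with a
   Euclidean disk of radius 1 (the set of offsets with
   $i^2 + j^2 \le r^2$ — a 4-neighbour cross at $r = 1$, not a box),
   then closing with a disk of radius 3. This removes isolated
   extrema that would seed spurious basins. The closing–opening pair
   is an alternating filter and hence idempotent, which the tests
   check.

5. **Homotopy modification.** With $T$ the lower-median pixel
   intensity, every regional minimum below $T$ is eliminated by
   grayscale reconstruction-by-erosion of $\max(m, T)$ above $m$: the
   sub-median basins of one connected dark pool merge into a single
   plateau, while shallower minima above $T$ survive. The surviving
   minima are returned as the watershed markers. Both halves of this
   behaviour are load-bearing: merging makes each blood pool a single
   seed (otherwise speckle dimples shatter the cavity into hundreds of
   basins), and the *surviving* supra-median minima inside the
   myocardium seed the small peripheral basins whose floods confine
   the ventricle basin at the wall — without them the cavity flood
   claims half the muscle before any opposing flood reaches it. The
   median rule encodes the assumption that dark blood pools and the
   area outside the scan sector together cover about half the frame,
   which holds for clinical four-chamber views and for the phantom.

6. **Atrioventricular barrier and watershed.** The barrier — placed by
   the operator on frame 0 across the mitral valve, and afterwards
   moved automatically to the row of the lowest foreground pixel of
   the previous frame's watershed mask, keeping its original column
   range — is rasterized at intensity 1.0 immediately before flooding,
   and barrier pixels are also removed from the marker mask so that a
   marker straddling the open valve is severed into ventricular and
   atrial components. The watershed itself is Meyer's immersion with
   explicit dam pixels: 8-connected basins grow in order of intensity
   (ties first-in-first-out, initial frontier in raster order), and a
   pixel adjacent to two distinct basins becomes a dam. The ventricle
   is selected as the largest basin whose centroid lies in the central
   window (middle half of each dimension) or that contains the
   reference point (barrier midpoint raised by a quarter of the image
   height). Barrier pixels are excluded from masks and area counts.

7. **Contour correction.** The watershed contour sits on the
   sharpening ridge, i.e. slightly inside the myocardium. The
   correction thresholds the basin (on the *time-averaged* image, whose
   intensities are still tissue-meaningful — the edge-enhanced image
   would distort them) at half the mean intensity along the watershed
   contour, smooths the resulting muscle mask (binary closing then
   opening, disk 3), subtracts it, smooths the remaining cavity
   (closing then opening, disk 9), clamps to the watershed mask and
   keeps the largest component. Containment (corrected ⊆ watershed) is
   asserted exactly in the tests.

Frame-level failures are flagged and skipped, not fatal; the run only
aborts if more than half the frames fail. Missing frames stay missing
in the AVC (no interpolation), and end-systole is the argmin over
present areas (earliest on ties); end-diastole is the first present
frame strictly after the R wave.

## Agreement metrics

For masks $A$ (automatic) and $M$ (manual): CCC is the Pearson
correlation of the mean-removed binary images; PE is
$100\,\lvert|A|-|M|\rvert/|M|$; ES is
$100\,(|A\cap\bar M| + |\bar A\cap M|)/|M|$. RMSd re-roots both
contours at their minimal-$(y,x)$ pixel, orients them clockwise,
evenly decimates the longer to the length $N$ of the shorter (indices
$\mathrm{round}(iL/N)$, half rounding up), and takes the root mean
squared distance over index-paired points. Index pairing after common
re-rooting is a fixed, deterministic convention; no optimal assignment
is attempted. ES = PE exactly when one mask contains the other, a
property the tests exercise on nested masks.

## The phantom

`generate_phantom()` emulates the acquisition this pipeline targets:
256×256 frames at 44 frames/s, 37 frames per cycle, two consecutive
cycles with R waves at frames 0 and 37. The LV cavity is a truncated
ellipse (cut at $0.88\,b$, giving a flat mitral annulus) whose area
follows a two-phase cosine profile between 20% (end-diastole) and
12.8% (end-systole) of the frame — a true AVF near 36%, in the healthy
range. Shape change is predominantly longitudinal
($b \propto u^{0.7}$, $a \propto u^{0.3}$ for area ratio $u$). The
scene also contains: a left atrium below a thin (8 px) echogenic
leaflet band, whose roof follows the annulus and which swells as the
ventricle contracts (atria fill during ventricular systole); right
ventricle and right atrium; a specular endocardial rim straddling the
blood–muscle interface; and an ultrasound scan sector (60° half-angle,
feathered edge) outside which the image is near-black. During the
valve-open window (cycle fraction 0.55–0.95) an anechoic gap of 10 px
pierces the band and connects cavity to atrium. Frames are blurred
(Gaussian, σ 1.5 px) and multiplied by i.i.d. unit-mean gamma speckle
with dispersion 0.15; cycle 2 repeats the geometry with independent
noise and a ±0.02 intensity offset. One RNG substream per frame makes
any frame reproducible independently of evaluation order.

Scene proportions are not arbitrary: the sector and pool areas keep
the median intensity between pool and muscle levels on every frame, so
the homotopy threshold always marks whole blood pools without leaking
through thin walls — the same property the median rule relies on in
clinical four-chamber views. The bright leaflet band is what separates
the ventricular and atrial markers while the valve is closed; its
brightness (0.15–0.30 above muscle) reflects the strong specular
reflection of closed mitral leaflets.

What passing phantom tests shows: the pipeline's mechanisms work —
pool merging, barrier damming and tracking, ridge-seeking dams,
contour correction, AVF recovery within a few percentage points at
realistic speckle, and insensitivity to barrier placement jitter. What
it does not show: performance under intensity inhomogeneity, rib
shadowing, dropout, probe motion, arrhythmia, or pathological wall
motion — none of which the phantom models.

## Numerical conventions and degenerate inputs

* Coordinates in contours, barriers and reference points are 0-based
  $(x, y)$ with $y$ growing downward; "lowest" always means largest
  row index.
* Lower median (the $\lceil n/2\rceil$-th order statistic) everywhere a
  median is taken; earliest-index tie-breaks for end-systole and
  largest-component selection; FIFO tie-breaks in the watershed flood.
* Minima imposition uses reconstruction by erosion via duality with an
  exact hybrid (raster + queue) reconstruction-by-dilation.
* Constant images: every preprocessing stage is the identity;
  homotopy modification returns the full-image plateau as its marker.
* A barrier that would erase every marker pixel, an empty cavity after
  muscle subtraction, or a reference point on a dam with no central
  basin raise classed errors (`echolv_segmentation_error`), which the
  sequence driver converts into per-frame failures.
* Problem sizes in the test suite: oracle equivalences run on 16×16
  images (200 mask pairs, 100 watersheds); parameter recovery and the
  jitter experiment run on the default 256×256, 37-frame phantom, with
  structural tests on a 128×128, 12-frame phantom.

## Design choices made where the design was open

* **Wavelet threshold rule**: Bayes-adaptive instead of universal, for
  the reason given above.
* **Homotopy modification** acts on the preprocessed intensity image
  (the stage-4 output), not on an explicit gradient image; the
  watershed then floods intensity basins directly. Blood pools are
  intensity minima here, so intensity flooding and gradient flooding
  coincide in the regime this pipeline targets, and the intensity
  formulation keeps the median threshold meaningful.
* **Barrier order**: the barrier is rasterized after preprocessing,
  immediately before the watershed, and also severs the marker mask.
  Rasterizing earlier would distort the denoising and morphology
  around the valve; severing markers is required for the barrier to
  have any effect once the open valve has merged the pools into one
  marker.
* **Contour-correction intensity source**: the time-averaged image.
* **ED convention**: strictly after the R wave (`detect_ed_es()`
  exposes the R-wave frame as an argument, so at-R behaviour is one
  call away).
* **Selection rule** for "largest central region": centroid in the
  middle half of each dimension, or containing the reference point;
  the disjunction keeps the rule usable both with and without a
  barrier-derived reference.

## Known limitations

* The barrier tracks one row per frame from the previous mask; a valve
  plane moving faster than the basal dam can momentarily lag it. With
  severe dropout at the valve this could admit transient atrial
  leakage; clinical use would place the optional static secondary
  barrier there.
* The correction step's muscle mask is smoothed with a disk of radius
  3; when the watershed dam already hugs the interface, the muscle
  rind inside the basin is thinner than the disk and the correction is
  a near no-op — harmless here, but on low-contrast data the corrected
  contour inherits whatever bias the dam has.
* Index-paired RMSd depends on the common re-rooting convention; it
  upper-bounds the assignment-optimal distance.
* The AVF inherits a small negative bias (1–2 percentage points on the
  phantom) because residual over-segmentation is relatively larger at
  end-systole than at end-diastole.
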