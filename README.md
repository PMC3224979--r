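# echolv

Semi-automatic segmentation of the left-ventricular (LV) cavity in
dynamic two-dimensional echocardiography, over a complete cardiac
cycle, with construction of the **area variation curve** (AVC) and the
**area variation fraction** (AVF).

## The problem

Evaluating global LV systolic function from apical four-chamber 2D-echo
video normally requires a specialist to trace the blood–endocardium
interface frame by frame — slow and operator-dependent. Automating the
tracing is hard for two reasons: ultrasound speckle fragments any naive
segmentation, and during diastole the open mitral valve merges the dark
blood pools of ventricle and atrium into one region.

`echolv` implements a watershed-based pipeline that addresses both.
Each analysed frame is first composited as the ECG-synchronized mean of
four frames (frames *k*, *k*+1 of two consecutive cycles, aligned on the
R wave), then denoised with a shift-invariant Daubechies-12 wavelet
transform, edge-enhanced with a self-reinforcing Laplacian-of-Gaussian
filter ( m − α·(LoG<sub>σ</sub> ∗ m) ), smoothed morphologically
(closing/opening, disk r = 1, then closing, disk r = 3), and
homotopy-modified: every regional minimum below the median pixel
intensity is flooded shut, so each dark blood pool becomes a single
watershed seed. A user-supplied **atrioventricular barrier** — a
horizontal segment of maximal intensity across the mitral valve, placed
once on the first frame and re-positioned automatically afterwards from
the previous frame's mask — dams the watershed flood at the valve plane.
The marker-controlled watershed (immersion with explicit dam pixels)
yields the ventricular basin as the largest central region; a contour
correction step thresholds the basin at half the mean intensity along
its watershed contour to strip the myocardial rind, leaving the cavity.

Per-frame cavity areas (pixel count × pixel area, in cm²) give the AVC,
and

```
AVF = 100 · (A − E) / A
```

with `A` the end-diastolic (first frame after the R wave) and `E` the
end-systolic (minimal) area — a surrogate for global systolic function.

Segmentations are compared with reference masks using four metrics:
root-mean-squared distance between paired contour points (RMSd),
cross-correlation of the mean-removed binary masks (CCC), percent area
error (PE), and edge error sum (ES).

Because no clinical image bank ships with the package, a synthetic
beating-heart phantom (`generate_phantom()`) provides sequences with
exact ground truth: a vertically elongated cavity with a smooth
two-phase area profile, an atrium that connects through an open mitral
gap during diastole, echogenic valve leaflets, an ultrasound scan
sector, and unit-mean multiplicative gamma speckle.

## Worked example

```r
library(echolv)

ph   <- generate_phantom(phantom_params(seed = 1))   # 74 frames, 44 fps
b    <- true_initial_barrier(ph$truth)               # the one manual step
seg  <- segment_sequence(ph$sequence, b)
seg
#> <lv_segmentation> 37 frames, 37 segmented, 0 failed
#>   barrier rows: 162 .. 173

avc <- build_avc(seg, ph$sequence)
avf_report(avc)
#> AVF = 34.5%  (ED frame 1: 33.540 cm^2; ES frame 13: 21.957 cm^2)
ph$truth$true_avf
#> [1] 35.71209

evaluate_pair(seg$results[[10]]$corrected_mask, ph$truth$masks[[10]])
#> RMSd 2.503 px | CCC 0.9809 | PE 3.17% | ES 3.34% (N = 312)

plot(avc)    # the area variation curve over the cycle
```

The measured AVF recovers the phantom's true value to about one
percentage point; per-frame percent area error stays in single digits at
the default speckle level (0.15).

A command-line wrapper with `simulate`, `preprocess`, `segment`, `avc`,
`evaluate` and `variability` subcommands is installed under
`inst/cli/echolv.R`.

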