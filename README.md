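# mammoseg

Quantifying how the placement of the initial contour changes level-set
segmentation of mass lesions in digital mammograms — and how much of that
change propagates into the boundary-based shape descriptors used by
benign/malignant classifiers.

Mass margins in direct digital mammography are often obscured, and many
masses contain interior low-signal areas. Region-based level sets converge
to local minima, so two reasonable initializations of the same mass can
yield different boundaries. This package implements the full measurement
chain to study that effect:

* **Weighted TV scale-space smoothing** — minimizes
  `∫ g|∇I| + λ|I − I0|` with the edge indicator
  `g = 1/(1 + Υ|∇G_θ∗I0|²)`, so noise and fine detail vanish while mass
  margins survive (`weighted_tv_flow`, `tv_scale_space`).
* **Iso-level search space** — thresholds `T = I_max·W` at equally spaced
  weights, marching-squares boundaries of the sub-level regions
  `R(t) = {I ≤ t}`, their nesting forest, and the dense nested band of
  contours that localizes the mass margin (`iso_level_map`,
  `extract_search_band`).
* **Proposed initial contour** — radial rays from the innermost band
  contour's centroid, maximum-gradient intersections with the band, and
  statistical clipping `r_i ← r_ave` where `r_i ≥ r_ave + n·r_std`
  (`radial_profile`, `clip_profile`, `profile_to_contour`).
* **Level-set evolution** — the Chan-Vese piecewise-constant model
  `φ_t = δ_ε(φ)[μκ − ν − λ1(I−c1)² + λ2(I−c2)²]` (defaults μ = 0.2,
  λ1 = 2.5, λ2 = 1) and the selective local/global signed-pressure-force
  model `φ_t = spf(I)·α|∇φ|` with binary penalty and Gaussian
  regularization (α = 5) (`evolve_chan_vese`, `evolve_sbgfrls`).
* **Shape descriptors** — centroid distance function `r(n)`, boundary
  moments `F1 = √μ2/m1`, `F2 = μ4^{1/4}/m1`, `F3 = |F1 − F2|`, 60
  DC-normalized Fourier descriptors `FD_i = |a_i|/|a_0|`, convexity
  (area / convex-hull area) and rectangularity (area / minimum-area
  enclosing rectangle) (`describe_mask`).
* **Agreement metrics** — Jaccard overlap, percentage differences,
  Fourier-descriptor distance, Bland-Altman limits of agreement, Pearson
  regression (`compare_pair`, `bland_altman`, `pearson_regression`).
* **Phantoms** — a deterministic generator of mammography-like masses in
  two margin classes (distinct vs ill-defined with interior low-signal
  areas) on textured backgrounds, with ground truth, plus the cohort
  initialization-sensitivity experiment (`make_phantom`,
  `sensitivity_experiment`).

The methods vignette (`vignettes/mass-segmentation-methods.Rmd`) explains
the models, every numerical choice, and what the phantom experiments do
and do not demonstrate.

## Worked example

Segment one ill-defined phantom from both initializations and compare the
outcomes:

```r
library(mammoseg)

spec <- phantom_spec(margin = "ill_defined", seed = 11)
ph   <- make_phantom(spec)                       # image + ground truth
sm   <- weighted_tv_flow(ph$image, tv_params(lam = 0.05))
prop <- propose_initial_contour(sm)              # radial max-gradient init
man  <- make_manual_init(ph$truth_contour, 10, spec$size)  # loose ROI

segY <- segment_from_contour(sm, prop$contour, "chanvese")
segX <- segment_from_contour(sm, man, "chanvese")
compare_pair(segX$mask, segY$mask)
```

```
JSC=0.690  DF=0.0154
%dF1=33.4  %dF2=11.5  %dF3=68.3  %dSC=2.4  %dSR=4.8
```

Read: on this blurred, hole-ridden mass the two initializations agree on
only 69% of the segmented area (Jaccard), and the boundary moments swing
by 33–68% while convexity and rectangularity move by under 5% — the
moments are the fragile descriptors, the region-shape ratios the robust
ones. On distinct-margin phantoms the same pipeline gives Jaccard values
around 0.98 (Chan-Vese) to 0.99 (SPF) with correspondingly small
descriptor shifts;
`sensitivity_experiment()` runs whole cohorts of both classes and
summarizes the agreement per descriptor.

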