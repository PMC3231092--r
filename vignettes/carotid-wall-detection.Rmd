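---
title: "Detecting carotid artery wall boundaries in dynamic B-mode sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting carotid artery wall boundaries in dynamic B-mode sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cawall)
```

## The problem

A longitudinal B-mode scan of the common carotid artery (CCA) shows the
vessel as a dark lumen bounded by two layered walls.  On each wall the
intima and the adventitia appear as bright echo bands separated by the
dark media; the distance between the lumen–intima and media–adventitia
interfaces is the intima–media thickness (IMT), an established early
marker of atherosclerosis, and the distance between the two intima lines
is the lumen diameter (LD), whose pulsation over the cardiac cycle
carries the information needed for distensibility and stiffness
estimates.  Tracing these four interfaces manually on every frame of a
dynamic sequence is impractical, so `cawall` automates it: given a
directory of frames, a rectangular region of interest (ROI) spanning
both walls, and a pixel-size calibration, it returns per-frame, per-column
boundary traces and the lumen-diameter waveform.

Dynamic sequences add three difficulties that static IMT tools do not
face: speckle noise (including a transient echogenic clutter layer that
can appear under the near-wall intima during systole), pulsatile changes
of lumen diameter and IMT, and bulk vertical motion of the artery.  The
package addresses them with, respectively, directional feature filtering,
a constrained dual dynamic-programming optimizer, and template tracking.

## Boundary evidence

Within a (normalized, $0 \le I \le 1$) ROI sub-image the boundary
feature is

$$F = \sum_{\theta} |I \ast f_M(\theta)| + I \ast f_x,$$

where $f_M$ is the MacLeod oriented edge kernel

$$f_M(x, y) = e^{-(x^2+y^2)/d_c^2}\left[ e^{-\left(\frac{d_{xy}+d_{pk}}{d_{pk}}\right)^2} - e^{-\left(\frac{d_{xy}-d_{pk}}{d_{pk}}\right)^2} \right],
\qquad d_{xy} = x\sin\theta - y\cos\theta,$$

evaluated at the four orientations $\theta = 0, \pi/4, \pi/2, 3\pi/4$,
and $f_x$ is a wall-specific 7×7 enhancement kernel holding three $-1$
entries stacked above the anchor and three $+1$ entries below (one
column apart); the near-wall variant is its 180° rotation.  The kernel
size matches the ≈5-pixel IMT at ≈0.1 mm/pixel.  Kernels are applied in
correlation orientation (no flip) with replicate border padding, and $F$
is min–max normalized to $[0,1]$.  Both choices are deliberate:

* *Correlation vs. convolution.*  The two conventions differ only by a
  180° kernel rotation, which for these antisymmetric kernels flips the
  detected edge polarity.  Under the correlation convention the far-wall
  kernel responds at dark-above/bright-below transitions — the leading
  edges of the far-wall echo bands — and its negation (used for the near
  wall) at bright-above/dark-below transitions, which is where the
  near-wall interfaces lie.  A `flip_kernels` switch exposes the other
  convention.
* *Replicate padding* avoids manufacturing artificial edges at the ROI
  border that the optimizer would latch onto.
* *Orientation pooling.*  The magnitude responses of the four MacLeod
  orientations are summed (a `max` combine is available); summing uses
  all four angles without favoring one.
* *Degenerate inputs.*  If a map is constant, min–max normalization is
  undefined; the package returns the constant 0.5 map so downstream
  optimization still receives a neutral, feasible cost surface.

For the near wall a second feature rewards rows with bright tissue
directly beneath them:

$$H(y, x) = 1 - \frac{1}{r}\sum_{i=y+1}^{y+r} I(i, x),
\qquad y_{outer}(x) < y < M - r,$$

with the neutral value 1 outside that band.  The outer-wall line
$y_{outer}$ is found first (see below) precisely so that $H$ does not
amplify the outer wall itself.  $H$ encodes the observation that under
both near-wall interfaces there are large gray values: the bright intima
band lies under the adventitia–media interface, and during systole the
sub-intima clutter lies under the intima–lumen interface — whereas the
spurious clutter–lumen boundary has only dark lumen beneath it.  The
combined near-wall cost is $1 - F + cH$, normalized to $[0,1]$, with low
values marking boundary evidence.

## Dual dynamic programming

The two interfaces of one wall are extracted jointly as the pair of
curves $(y_1(x), y_2(x))$ minimizing

$$J = \sum_x \left[ C(x, y_1) + C(x, y_2) \right]
 + \sum_x \left[ \alpha\,\Delta\omega_x + \beta\,(|j_1| + |j_2|) \right]$$

subject to $1 \le y_1 \le y_2 \le M$,
$d_{min} \le y_2 - y_1 \le d_{max}$ (minimum/maximum thickness), and
per-column steps $|j_1|, |j_2| \le k$ (smoothness), where
$\Delta\omega_x = |j_2 - j_1|$ is the change of the inter-line distance.
For $k = 1$ the transition penalty forms the 3×3 matrix with $0$ at the
centre, $2\beta$ on the main-diagonal corners and $2(\alpha+\beta)$ on
the anti-diagonal corners (`penalty_matrix()`).

The optimizer (`run_ddp()`, Rcpp) performs the exact forward recursion
over all feasible $(y_1, y_2)$ states, stores predecessor coordinates,
selects the minimum of the final column and backtracks.  Numerical
choices:

* infeasible states/transitions carry $+\infty$ rather than being
  skipped structurally (equivalent and simpler);
* tie-breaks are deterministic: equal-cost predecessors prefer the
  offset $(0,0)$, then the smallest $|j_1|+|j_2|$, then lexicographic
  $(j_1, j_2)$; equal-cost terminal states prefer the smallest
  $(y_1, y_2)$;
* the core is a *minimizer*; an `orientation = "maximize_feature"`
  flag flips a feature map to $1 - \text{map}$ first;
* predecessor tables are stored densely ($M \times M \times N$); ROI
  grids are at most on the order of a hundred rows, so exactness is
  cheap.

The test suite verifies the optimizer against an independent exhaustive
path enumeration (every partial path kept explicitly, no state
collapsing) on more than a hundred seeded random grids with varied
constraints for $k \in \{1, 2\}$.

A single curve (the outer wall) is extracted by the same machinery with
the degenerate separation band $[0, 1]$ (`run_single_dp()`); the upper
curve is reported.  The outer-wall cost is $1$ minus the normalized
*signed* response to the 9×1 step kernel $(-1,-1,-1,-1,0,1,1,1,1)$ —
signed, because the magnitude response is larger at the adventitia–media
edge than at the outer wall itself, and the sign selects the correct
polarity.

## Tracking and the full pipeline

The artery moves mostly vertically.  For each wall, the first-frame
half-ROI is fixed as template $T_0$; on every later frame the normalized
cross-correlation (Pearson correlation of pixel sets) is evaluated at
every integer vertical offset $s \in [-\Delta s, \Delta s]$ relative to
the previous frame's position, and the best offset accumulates
(`track_frame()`).  The template is never updated, ties prefer the
smallest $|s|$ (then negative $s$), and sub-pixel tracking is not
attempted.  $\Delta s$ defaults to 10 px (≈1 mm — the near wall commonly
moves about that much over a cycle).

`cawall_run()` executes the seven-step procedure: split the ROI into an
upper (near-wall) and lower (far-wall) half (odd heights give the extra
row to the upper half); per frame, near wall: outer-wall line → $F$ with
$f_x = -f_{IMT(far)}$ → $H$ below the outer wall → combined cost → DDP
with $d_{min} = 4$ px, $d_{max} = 0.9M$, $k = 1$; far wall: $F$ with
$f_x = f_{IMT(far)}$, cost $1 - F$, same constraints; tracking between
frames (independently per wall — the two walls move differently);
sub-pixel refinement; column smoothing (5-column moving average with
shrinking edges); and lumen-diameter assembly (far intima minus near
intima per column, column means per frame, reported in px and mm).
$d_{min} = 4$ px ≈ 0.42 mm at 0.106 mm/px, just under a normal IMT.

*Sub-pixel refinement* (`refine_traces()`).  The DDP localizes each
boundary to an integer row, and the discrete argmax of a 7×7 kernel over
a thin echo band sits systematically one row inside the lumen when the
band is thinner than the kernel's 3-pixel triplets.  Each detected row
is therefore moved to the sub-pixel position of the nearest intensity
transition of the wall's polarity: the steepest one-pixel step within
±3 rows is found and the edge is placed at the parabolic vertex of the
rectified vertical gradient around it.  This is the standard
leading-edge localization practice; columns where refinement would
violate the $d_{min}$ separation keep their integer rows.  Refinement is
on by default (`cawall_params(refine = FALSE)` disables it).

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `alpha` | 0.3 | per px of $\Delta\omega$ | thickness-change smoothness |
| `beta` | 0.15 | per px of step | single-line smoothness |
| `k` | 1 | px | maximum per-column step |
| `d_min` | 4 | px | minimum intima–adventitia separation |
| `d_max_frac` | 0.9 | of half-ROI height | maximum separation |
| `c` | 0.5 | — | weight of $H$ in the near-wall cost |
| `r` | 5 | px | $H$ averaging depth (≈0.5 mm) |
| `d_c`, `d_pk` | 2, 2 | px | MacLeod radial decay / peak offset |
| `macleod_size` | 7 | px | MacLeod kernel side |
| `delta_s` | 10 | px | tracking search half-range |
| `smooth_window` | 5 | columns | trace moving-average window |
| `pixel_size_mm` | 0.106 | mm/px | calibration |

$\alpha$, $\beta$ and $c$ are not fixed by the method's description;
the defaults were chosen on phantom benchmarks (costs live in $[0,1]$,
so the penalties are commensurate with one-column cost differences) and
are deliberately mild — the evidence terms, not the smoothness terms,
should decide where a boundary lies.  Larger `c` is counter-productive:
it attracts lines to any row with bright tissue below, not only to
interfaces.

## The phantom

`generate_sequence()` renders a longitudinal CCA look-alike with exact
sub-pixel ground truth: a dark lumen (level 0.05) bounded by bright
intima bands (0.80, 2 px), dark media (0.10), bright adventitia bands
(0.90, 3 px) and moderate tissue (0.30), with every interface drawn as a
logistic transition of width 0.7 px so that sub-pixel truth is
meaningful.  The lumen diameter follows
$\mathrm{LD}(t) = \mathrm{baseline} + A\sin(2\pi t / T)$ (defaults 48 +
4 px over a 40-frame cycle, ≈3 s at typical frame rates), a bulk
vertical drift of the same period moves both walls together (default
1 px), and speckle is applied as a clamped multiplicative Rayleigh
factor $1 + s(R - 1)$, $E[R] = 1$, quantized to 8 bits;
$s = 0.25$ (≈13 % multiplicative standard deviation) is the package's
"moderate" level.  Optional components reproduce the two classic failure
modes: a raised-cosine plaque thickening the intima into the lumen, and
a sub-intima clutter layer under the near-wall intima during the
systolic (expansion) frames, rendered with a sharp proximal boundary but
a diffuse distal fade — incoherent echo clutter has no anatomical
distal interface.

What the phantom does *not* emulate: point-spread functions, attenuation
and time-gain compensation, anisotropic speckle correlation, horizontal
artery motion, curved or oblique vessels, and calcification shadows.
Passing the phantom suite therefore demonstrates correctness of the
optimization/tracking machinery and robustness to first-order speckle
and clutter, not clinical-grade performance on scanner data — on real
sequences the filter parameters must be re-tuned per device, as any
IMT tool requires.

The truth tables use the interface (not band-centre) convention: near
wall rows are the adventitia–media and intima–lumen interfaces, far
wall rows the lumen–intima and media–adventitia interfaces, so the
per-column lumen diameter equals far intima minus near intima exactly.

## Accuracy accounting

`frame_error()` implements the per-frame mean absolute (unsigned) and
mean raw (signed) row difference between a detected and a reference
line; `sequence_error()` averages frames; `error_summary()` pools the
intima and adventitia layers of a wall.  When a reference is sparse
(e.g. a manual tracing with a few points per frame), `interp_reference()`
fills the gaps linearly.  Distensibility and stiffness follow
$\mathrm{CDist} = \Delta A / (A\,\Delta P)$ and
$\mathrm{CS} = \mathrm{CDist}^{-1/2}$, with areas derived from mean
diameters under a circular-lumen assumption (a documented approximation
— the method measures diameters, not areas).

Problem sizes in the shipped tests were chosen to keep the default
suite fast while preserving coverage: enumeration oracles run on grids
of up to 6×6 (the exhaustive path count grows exponentially), phantom
end-to-end checks use 128×160-px frames with 80 frames for the headline
error bounds and 8–20 frames elsewhere.

## Known limitations

* Only vertical wall motion is tracked; horizontal drift shifts the
  column correspondence silently.
* The DDP state space is $O(M^2)$ per column; very tall ROIs (many
  hundreds of rows) would need a banded-state variant.
* The reconstructed lumen-diameter enhancement kernels (`ld_far`,
  `ld_near`) are an analogous design, not a published matrix; the
  pipeline's wall phases use the IMT kernels.
* Boundary ordering at plaques assumes the adventitia keeps its
  baseline position; dissecting or outward-remodelling geometries are
  out of scope.

```{r demo, eval = FALSE}
ph <- generate_sequence(phantom_config())
roi <- default_roi(ph, "lumen")
res <- cawall_run(ph, roi)
error_summary(wall_error(res$far, ph$truth))
autoplot(res$lumen)
```
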