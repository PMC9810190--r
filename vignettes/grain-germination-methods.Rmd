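---
title: "Counting grains and germs by area division: methods and design"
author: "grainGerm"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Counting grains and germs by area division: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grainGerm)
```

## The problem

Rice seed quality is assessed by the germination rate: grains are
cultured in a dark container with a little water for one to two days
and the fraction showing an emerged white germ (radicle) is recorded.
In a photograph taken from above, three pixel populations matter: the
near-black background and container, the yellow grain bodies, and the
bright white germs and water reflections. Two counting problems follow:
grains touch each other in clusters, and germs must be attributed to
grains without confusing them with reflections.

`grainGerm` implements a pipeline that sidesteps the classical
cluster-splitting step (watershed, concave-point matching): it divides
each connected region's area by an automatically estimated single-grain
area. The price is a set of assumptions made explicit below.

## Pipeline and assumptions

### Coarse segmentation

Pixels are mapped to the feature pair $(r_b, g_b)$, where $r_b = 30$ if
$R - B \ge 60$ and $R - B$ otherwise, and $g_b$ analogously from
$G - B$. The clip compresses the wide spread of the difference across a
grain body — sunlit core, dimmer flanks — onto one point, so that the
subsequent two-center k-means does not cut grains apart by brightness.
Negative differences pass through: they only push a pixel further
toward the background center, which is the intent.

Lloyd iterations run with squared-Euclidean distance from the fixed
initial centers $(0,0)$ (background/white) and $(40,40)$ (grain).
Fixing the centers removes all run-to-run randomness: the pipeline is
bit-reproducible. Pixels equidistant from both centers go to the
background (conservative); an empty cluster keeps its stale center so
monochrome images degrade gracefully; iteration stops when assignments
stop changing, with a cap of 100 to guard against oscillation.
Internally the update runs over unique feature pairs weighted by their
pixel counts, which is algebraically identical to per-pixel Lloyd but
roughly two orders of magnitude faster on photographs.

*Assumption:* grains are yellow against a dark, low-reflectivity
background. White or near-white grains violate the clip condition and
are lost (a documented error source of the approach).

### Refinement

The shadow ring around each grain is closer in hue to the grain than to
the background, so k-means keeps it. Its red values, however, sit in a
clearly lower band (border peak around 85) than the grain core (peak
around 234). The red histogram of the foreground is smoothed with a
unit-sum Gaussian kernel (nominal size 100, $\sigma = 7.5$), a quintic
$f(x) = ax^5 + \dots + f$ is fitted by least squares, and the valley of
the fitted trend between its two dominant maxima becomes the threshold
$d$: foreground pixels with $R < d$ return to the background. When the
trend has fewer than two interior maxima there is no border/core
structure and refinement is skipped — a valid outcome, not an error.

Numerical choices:

* "size 100" is read as a centered, symmetric 101-tap kernel; an even
  kernel has no center tap and would shift the histogram by half a bin.
* At the histogram edges the truncated kernel is renormalized (so a
  uniform histogram is a fixed point) and the result is rescaled by one
  global factor so that total mass is preserved exactly. Without the
  rescale, mass near the edges would leak by the truncated tail.
* The quintic is fitted on a rescaled abscissa $x/255$ and the
  coefficients mapped back, keeping the normal equations
  well-conditioned; fitted values are identical either way.
* One global histogram and one global threshold are used by default;
  `pipelineConfig(perRegionThreshold = TRUE)` computes a threshold per
  coarse region instead. The global variant is simpler and the two
  agree on evenly lit scenes; per-region thresholds help under strong
  illumination gradients.
* If the quintic still has several interior minima between the chosen
  peaks, the global minimum between them is taken.

### Grain counting on the area curve

Connected regions of the refined mask are labeled with 8-connectivity
(grains touching corner-to-corner should merge; labeling is EBImage's
4-connected `bwlabel` plus a union–find merge over diagonal contacts).
Region areas are sorted ascending, smoothed with a 3-tap Gaussian
($\sigma = 0.65$), and differentiated twice with the discrete Laplacian
$g(x) = f(x+1) + f(x-1) - 2f(x)$ (endpoints 0).

The curve has three parts: near-zero noise regions, a stable
single-grain plateau, and a steep tail of multi-grain clusters. Point A
ends the noise run; point B ends the plateau.

**Point A.** The noise-to-plateau jump appears in $g$ as a sharp
positive spike followed by a negative dip and a rise back through zero.
The locator works in two stages, both scaled by
$0.05 \cdot \mathrm{median}(f)$ (config key `pointAMinDip`):

1. the first contiguous run of $g$ above the threshold marks the jump;
   A is the first index after it — the first plateau region;
2. failing that, the first index where $g$ rises through zero
   ($g(i-1) < 0 < g(i+1)$, increasing) whose preceding negative run
   dips below the threshold.

The threshold is essential: the sorted areas of jittered single grains
wiggle by a few pixels, and an unguarded sign-pattern scan fires on
those wiggles, discarding real grains as noise — or, on a noise-free
curve, fires at the singles-to-clusters jump and destroys the estimate
entirely. The median of the smoothed curve is a robust, scale-free
yardstick: genuine jumps are of the order of a grain area, plateau
wiggles are not. Setting `pointAMinDip = 0` recovers the bare
sign-pattern scan for study. Regions below A are excluded from counting
and from germ adjacency; with the fractional rule they would mostly
count zero anyway, but they must not pollute the candidate window for
the single-grain area.

**Point B.** Scanning the raw sorted areas upward from A, the first
index $i$ with $s_{i+3}/s_i > 1.2$ marks the start of the cluster tail;
B is that $i$, the last stable point (`pointBConvention = "post-jump"`
selects $i+3$ instead; both are defensible readings and the choice is
config-switchable). The scan uses the raw areas because smoothing near
the A boundary drags plateau values toward the noise run and distorts
the ratio. If the condition never fires, every region holds one grain
and B is the last index.

**Optimal single-grain area.** Over the candidate areas between A and B
inclusive, $s_{\mathrm{opt}}$ is the candidate minimizing
$\sum_j |1 - s_j / s_i|$ — an exhaustive search, ties broken by the
first minimizer. A region of area $s$ then holds
$\lfloor s/s_{\mathrm{opt}} \rfloor$ grains, plus one when the
fractional part exceeds 0.4.

*Assumptions:* grain sizes are roughly uniform (the plateau exists);
enough isolated grains are present (with fewer than about ten single
grains, the three-step ratio window spans too much of the plateau and
the estimate destabilizes — the method is designed for images of 20–80
grains); clusters touch rather than overlap (overlap loses area and
undercounts — a documented failure mode).

### Germ detection

Candidate germs are the 8-connected components of
$\{\text{gray} > 160\} \setminus \text{grain}$, with gray the Rec.601
luminance $0.299R + 0.587G + 0.114B$ rounded half-up (the gray
transform is monotone in every channel, so the threshold is
illumination-consistent). A candidate of area $s_{bud}$ survives when

* $s_{\mathrm{opt}}/50 < s_{bud} < s_{\mathrm{opt}}/3$ (both strict) —
  smaller blobs are invisible noise, larger ones are grain-sized
  reflections;
* it touches at least one grain region; and
* $l/p < 0.4$, where $p$ counts candidate pixels with a 4-neighbor
  outside the candidate (image borders count as outside) and $l$ counts
  those boundary pixels with an 8-neighbor in grain foreground.

$p$ is a discrete inner-boundary count rather than a Crofton-style
perimeter so that $l$ and $p$ are commensurable and $l/p \in [0,1]$.
"Touches" means $l \ge 1$ — direct contact, no gap tolerance; the
synthetic generator therefore draws no shadow rim where a germ emerges,
mirroring real photographs in which the germ abuts bright grain tissue.
A fully emerged germ has a small contact ratio; a germ still inside the
hull has a large one and is (correctly, per the protocol) not counted.
Each candidate counts at most once however many grains it touches, and
two germs merged into one component count once at most — both
documented behaviors of the counting scheme, reproduced rather than
repaired. The rate is $n_{bud}/n_{grain}$, undefined (flagged `NA`)
when no grains were found.

## The synthetic generator

Real photographs of the acquisition protocol are not distributable with
the package, so every end-to-end claim is validated on synthetic scenes
with known ground truth. `sceneSpec()` describes a scene; the defaults
are the package's study conditions and are deliberately boring:

* grain semi-axes 24 × 9 px (aspect about 2.7:1, typical of rice),
  ±10% area jitter drawn once per grain (both semi-axes scale by the
  square root of the factor);
* a 2 px shadow rim per grain at red ≈ 85 versus a core at red ≈ 225,
  reproducing the bimodal red histogram the refinement step expects;
  rims are drawn around each grain individually — crevices between
  touching grains are shadowed in real scenes — and omitted where a
  germ emerges;
* 30% of grains in touching clusters of 2–4, stacked along the minor
  axis deeply enough that the bright cores still touch after
  refinement;
* white germs (gray ≈ 235) as 10 × 3.5 px ellipses attached at a grain
  tip with a small contact ratio, area about one-fifth of a grain core
  — inside the detection window by construction;
* background (12,12,12) with σ = 3 Gaussian noise everywhere, three
  detached white reflection blobs, and five tiny grain-colored dust
  specks. The specks matter: the area-curve method expects a near-zero
  noise run at the start of the sorted curve (real photographs always
  have one), and a curve without it has no turning-point structure for
  A to find.

Placement uses a seeded, jittered grid of non-overlapping cells, so
generation is deterministic, guaranteed to terminate, and errors
cleanly when a requested grain count cannot fit a fixed image size.
Rendering is hard-edged by default so that area assertions are exact;
`antialias = TRUE` renders at 2× and averages down for soft-edge
robustness checks. `generateAdversarial()` produces the four documented
failure scenarios (droplet on a grain edge, intertwined germs, germ
hidden beneath its grain, heavily overlapping grains) for directional
error checks.

What the generator does **not** emulate: perspective and lens
distortion, specular gradients across the container, partially
submerged grains, husk texture, and color variation between rice
varieties. Passing tests therefore demonstrate the pipeline's
correctness under its stated assumptions, not its accuracy on any
particular camera or variety.

## Verification strategy and problem sizes

The test suite checks three layers, chosen to stay within a desk-scale
compute budget:

* exact oracle equivalences — segmentation assignments against a naive
  per-pixel Lloyd reference on instances up to 900 pixels, the optimal
  area search against a literal double loop on 100 random candidate
  sets, the quintic valley against a brute-force integer-bin scan on 50
  random bimodal curves;
* invariants — refinement anti-extensivity, histogram mass
  conservation to 1e-6, grain-count invariance under 90°/180°/270°
  rotation of ten seeded scenes, invariance under doubling the linear
  resolution, end-to-end determinism, and a germination rate inside
  [0,1] on benign scenes;
* parameter recovery — 50 scenes of 20–80 grains under the default
  conditions with germination fractions 0.5–0.95; the mean grain-count
  relative error must stay within 2% and the mean germination-rate
  absolute error within 3 percentage points. `scripts/acceptance.R`
  recomputes exactly this study from a command-line seed.

```{r example}
scene <- generateScene(sceneSpec(seed = 42, nGrains = 40,
                                 germinationFraction = 0.7))
report <- runPipeline(scene$image)
report
```

## Known limitations

* Counting degrades below roughly 15 grains per image: the plateau is
  too short for the ratio-based point B and the exhaustive area search
  may lock onto a cluster.
* Grains larger than about 1.4 × s_opt inflate the count; overlap
  deflates it. Germ-germ contact merges candidates. These are inherent
  to area division and reproduced by the adversarial scenes.
* Bright droplets touching a grain with a small contact ratio are
  indistinguishable from germs to this rule set.
* The color thresholds assume yellow grains; other crops or lighting
  setups need the constants in `pipelineConfig()` revisited.
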