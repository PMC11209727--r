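---
title: "Methods: bottom-up pod phenotyping with a structural prior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bottom-up pod phenotyping with a structural prior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(podkit)
```

## The model

A mature soybean plant carries tens of pods that touch, overlap and
point in every direction. `podkit` follows the bottom-up pose-estimation
reading of this problem: a pod is an unbranched chain of up to five
seeds, ordered from the pod base, and detection proceeds by finding
seeds everywhere and grouping them into chains. Three assumptions
underpin everything downstream:

1. **Chains, not graphs.** A pod has no branches; ordinals 1..n count
   from the base, and a pod with n < 5 seeds has its slots n+1..5
   *sealed* — treated as invisible and masked from supervision rather
   than marked absent.
2. **Rigid geometry.** Seeds of one pod are nearly collinear with
   roughly uniform spacing, so the chain's shape is informative:
   partial observations of the same pod from two crop windows look
   alike (this is what the DTW merge exploits), and the ordinal of a
   seed correlates with its local appearance (basal seeds sit in the
   widest part of the pod).
3. **Feature coherence.** Seeds of one pod should have more similar
   deep features than seeds of different pods; the structural prior
   turns that belief into a training signal.

### Detection head

The detector predicts, on an output grid at 1/4 input resolution, six
heatmaps (channels 1–5 are seed types, channel 6 is background, defined
as one minus the max over type channels) and a ten-channel offset field
that stores, at a supervised cell, the displacement to each of its
pod's five seeds. Decoding takes the 3×3 local maxima of
(1 − background) above `heatmap_thresh` as candidates, regresses five
seeds per candidate through the offset vector, keeps a regressed seed
only if its type channel at the regressed location reaches
`heatmap_thresh`, and truncates the pod at the first failing ordinal
(interior gaps are not representable in the label grammar, so the chain
is a prefix). The pod score is the mean surviving confidence, and a
pose-level NMS removes lower-scoring pods whose mean per-ordinal seed
distance to a kept pod falls below `nms_radius`.

One design point deserves emphasis. Because the "centerness" map is
defined through the background channel, candidates arise at *seed*
peaks, not at pod centroids. Offset supervision therefore covers a disk
of radius `offset_radius` around **each seed and the centroid** (cells
contested between pods go to the nearest anchor): every possible
candidate cell carries its own pod's offsets. An earlier variant that
supervised only a centroid-centred disk failed in crowded scenes — a
seed cell could inherit a neighbouring pod's offsets — and was replaced
after the render→decode round-trip exposed it.

### The structural prior

Let F ∈ R^(H×W×C) be a feature map and v_i the C-vector at seed i's
cell (nearest-cell lookup after dividing coordinates by the stride;
bilinear sampling is an opt-in flag, since the point vector is defined
as the feature *at* the seed's position). The affinity matrix

A_ij = v_i·v_j / (‖v_i‖‖v_j‖ + ε),  ε = 1e−8,

is compared with the binary same-pod matrix A′ through
L_SPrior = ‖A − A′‖²_F. The ε guard makes the cosine of a zero vector 0
instead of NaN; the loss is reported unnormalised by default (a
`normalize` flag divides by N², which the toy trainer uses for scale
stability across images with different seed counts). The total
objective is

L = l_heatmaps + γ·l_p + ρ·L_SPrior,

with γ = 0.03 and ρ = 0.2 by default; ρ = 0.2 is where the prior's
benefit peaks in ablation, and ρ = 0 gives the plain detector. The
prior is a training-time-only branch: no inference path evaluates it.
Where exactly the prior taps the network is an open choice; the toy
trainer taps the trunk output that also feeds the heads, which keeps
the prior's gradient on the features the decoder consumes.

### Pod-adapted OKS

Keypoint detectors are scored by object-keypoint similarity. For pods,
the bounding-box area that normalises the original OKS grows with the
seed count, which flatters many-seeded pods. The pod variant

OKS_pod = (1/n) · Σ_i exp(−d_i² / (2 λ_n s² k²))

corrects this with λ_n, the mean ratio of 3-seeded to n-seeded box
areas measured on annotated images (defaults 4.752, 1.353, 1, 0.782,
0.673; λ_3 = 1 by construction, and `estimate_lambda()` re-measures the
vector on any annotation set). The falloff constant is k = 2σ, where
σ² = E[d²/s²] is the relative annotation error; no relabelled subset
ships with the package, so σ defaults to 0.05 and `estimate_sigma()`
calibrates it from any refined/original position pairs. A ground-truth
seed with no prediction contributes exp(−∞) = 0 rather than shrinking
n, keeping the normalisation stable. The object scale s of a
point-annotated pod is the square root of its seed bounding rectangle
expanded by one nominal seed radius (6 px) per side — point sets have
no native box, so the padding supplies the missing extent.

AP follows the COCO convention the metric descends from: greedy
score-ordered matching (ties toward the lower ground-truth index),
all-point PR interpolation, AP50 at OKS_pod ≥ 0.50 and AP as the mean
over thresholds 0.50:0.05:0.95 — both are reported since either reading
of "AP" appears in practice. Per-type AP restricts the ground truth to
n-seeded pods; detections retained for type n are those matched to an
n-seeded pod plus unmatched detections whose detected count is n.
Count-level agreement is summarised by MAE and Pearson correlation.
Reported tables round half-up to two decimals.

## Crop and merge geometry

Training crops are 400×400 px (most plants fit in 400 px of width):
the pod's minimum bounding rectangle is expanded to the crop size with
the horizontal and vertical slack split uniformly at random, then
shifted inward at image borders — never shrunk or padded, because the
model input is fixed. Pods cut by the window keep their declared n with
the missing seeds sealed. Plants are split into train/test *before*
cropping so no pod appears on both sides.

Inference tiles the full image at stride 300 (100 px overlap on a
400 px window; the overlap comfortably exceeds one seed spacing so
every boundary pod is whole in some window or recoverable by merging).
Merging then proceeds: (1) dedup — pods with equal seed counts and all
ordinal-wise distances below `dist_thresh` (10 px) form transitive
duplicate groups of which only the highest-scoring member survives;
(2) candidate pairs — pods from different windows that each have a
seed inside the shared border band (band width defaults to the window
overlap); (3) gate — a pair with a seed pair closer than `dist_thresh`
merges directly if either pod is 1-seeded, otherwise iff the
path-normalised DTW distance of the two chains is below
`shape_thresh`; (4) merge — DTW path pairs closer than `dist_thresh`
are score-weighted averaged, remaining seeds concatenate in the
orientation with the smallest junction gap, the base end goes to the
part whose first seed scored higher, ordinals renumber 1..n and n caps
at 5 (lowest-confidence extras dropped with a warning). Pairs are
processed in ascending seed-pair distance and the whole pass iterates
to a fixed point; both choices are for determinism and
order-invariance, and make `merge_full()` idempotent.

`shape_thresh` defaults to 25 px, calibrated on the synthetic
benchmark: a duplicate pair in which one observation overhangs the
other by two seeds costs up to ~23 px under full-path DTW at the
spacing-jitter tail (~30 px spacing), while crossing or diverging pods
measure upwards of ~40 px. DTW distance is path-normalised (optimal
path cost over path length) so one threshold serves all pod lengths.

## What the generator emulates — and what it does not

`generate_scene()` renders pods as chains of Gaussian blobs:
orientations uniform, spacing 25 ± 3 px, perpendicular jitter 2 px,
blob radius 6 px, additive pixel noise, and pod-type frequencies
proportional to a large field census (≈ 19.7 / 29.8 / 40.5 / 10.0 /
0.02 % for 1–5 seeds — 5-seeded pods are genuinely rare). Blob radius
and peak intensity taper from base to tip (16 % and 12 % per ordinal),
mirroring the basal thickening of real pods; the taper is what makes
seed ordinals locally decodable, and its strength was chosen so a
small network can in fact learn the cue. `perturb_annotation()` turns
ground truth into detection fixtures with Rayleigh-mean coordinate
jitter, seed/pod dropout, spurious pods and a logistic-normal score
model. `synthesize_features()` plants unit vectors with exact
within-/between-pod cosine targets (orthonormal pod identities via QR
while pods + 1 ≤ channels, random unit identities beyond).

The generator does **not** emulate photometric realism: no pod walls,
stems, leaves, specular highlights, camera blur, or correlated
backgrounds, and overlap is opt-in (`overlap_fraction`) rather than
pervasive as on a real plant. Green tests therefore certify the
machinery — losses, decoding, metrics, merging — under the stated
geometry and noise, not field-level accuracy; real-data performance
depends on a real backbone and real training data, both out of scope
here.

## The toy trainer

The training harness exists to exercise the full objective, not to
reproduce a high-resolution backbone. It is a pure-R convolutional
network (im2col + BLAS, hand-derived gradients, Adam): two stride-2
convolutions then three dilated 3×3 convolutions (dilations 2, 4, 8)
giving a ~137 px receptive field at stride 4 — enough to regress every
seed of a 4–5-seeded pod (~75–100 px) from a candidate cell at either
chain end — and one shared 5×5 head convolution sliced into the six
sigmoid heatmaps and ten linear offsets (mathematically two parallel
heads with a single input gather). ~27k parameters.

Numerical choices that matter:

- **Heatmap weighting.** Positive cells are sparse, so the squared
  error is up-weighted by `1 + 25·blob` where `blob` is the max over
  type channels — over the *whole blob support on every type channel*,
  not per-channel positives. Per-channel weighting makes a false peak
  on the wrong ordinal 26× cheaper than a missed peak and collapses
  the type channels into generic blob detectors.
- **Loss balance.** The heatmap term is normalised by total weight and
  the offset smooth-L1 by active entries; those normalisations leave
  the two terms on very different scales at the reference γ, so the
  trainer applies a fixed `offset_loss_scale` (30) inside the combined
  objective. The offset head also carries a fixed output gain of 8 so
  its weights work in O(1) units; per-pod scale normalisation enters
  through the offset mask (entries 1/Z, Z the pod scale in cells).
- **Schedule.** Adam at 4e-3, halved at 1/2 and 3/4 of the epochs;
  horizontal flips are the only augmentation (pods must stay intact,
  and ordinals are positional along the chain, so flipping never swaps
  them). Training is deterministic given the seed.
- **Refinement.** After decoding, each surviving seed snaps to the
  local argmax of its type channel and a 1-D log-parabola fit per axis
  recovers the sub-cell peak; a second pose-NMS pass then removes
  chains that refinement pulled onto the same blobs.

Desk-scale problem sizes used throughout the tests and the acceptance
script: 200 training crops of 128×128 px with ~2 pods each, 40 epochs,
20 held-out scenes — chosen so a full ρ ∈ {0, 0.2} ablation runs in a
few minutes on one CPU while still clearing AP50 0.5 on held-out
scenes. The ablation's directional claim is deliberately modest: the
ρ = 0.2 model attains a lower held-out structural-prior loss than the
ρ = 0 model (the prior shapes the features it supervises); with a toy
backbone and synthetic scenes, an AP improvement is not asserted.

## Degenerate inputs and tie-breaks

Zero-seed pods are rejected at construction; pods with missing
ordinals are kept and flagged truncated (crops legitimately produce
them). The label grammar caps n at 5 and rejects larger declarations.
Zero feature vectors get cosine 0 (ε guard). An all-zero offset mask
defines l_p = 0. Greedy matching breaks OKS ties toward the lower
ground-truth index; DTW backtracking prefers the diagonal step, which
yields a shortest optimal path; `decode()` on an empty or sub-threshold
heatmap returns an empty detection tibble rather than an error; images
smaller than the crop size tile to a single full-image window with a
warning. `estimate_lambda()` keeps the default coefficient (with a
message) for any n lacking a qualifying image and pins λ_3 = 1.

## Known limitations

- The decoder implements the pixel-wise offset-regression reading of
  seed grouping. Descriptions of this family of models sometimes
  invoke associative-embedding clustering instead; those are different
  mechanisms, and only the regression one is implemented.
- Truly adjacent parallel pods closer than `dist_thresh` with similar
  shapes are indistinguishable from duplicate observations by the
  merge gate — an inherent limit of distance-plus-shape evidence.
- The per-type AP convention for unmatched detections (counted against
  the type of their detected seed count) is one of several defensible
  choices; with no matching convention published for pods, the
  COCO-style one implemented here is stated rather than argued.
- The toy backbone underfits small or crowded scenes (1-seeded pods
  and tight pairs dominate its errors); its role is to validate the
  objective and the decode/merge/evaluate chain, not to set accuracy
  expectations for a production backbone.
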