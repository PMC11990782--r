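# herdtrack

Multi-object tracking of animals in aerial drone video, for ecologists
and computer-vision researchers who need identity-stable trajectories of
herding ungulates (or any small, numerous, mutually occluding targets)
from UAV footage, given per-frame detections from any detector.

Drone footage breaks the two assumptions ordinary trackers lean on: the
camera itself translates, rolls and zooms between frames, so every target
appears to jump even when standing still; and herd members occlude one
another constantly, so detections flicker between high and very low
confidence. `herdtrack` is an online tracking-by-detection pipeline in
the Deep SORT tradition with two additions aimed at those failure modes,
plus the evaluation stack and a synthetic scenario generator to test it
all end to end.

## The method

Each target carries an 8-dimensional constant-velocity Kalman state
`(x, y, γ, h, ẋ, ẏ, γ̇, ḣ)` — box centre, aspect ratio `γ = w/h`, height,
and their per-frame rates — with noise standard deviations proportional
to box height. Detections are associated to predicted tracks by the cost

```
c(i,j) = λ · d₁(i,j) + (1 − λ) · d₂(i,j)
```

where `d₁` is the squared Mahalanobis distance to the track's predicted
measurement distribution (gated at the χ²₄ 0.95 quantile, 9.4877) and
`d₂ = min_k (1 − rⱼᵀ r⁽ⁱ⁾ₖ)` is the minimum cosine distance to the
track's gallery of recent unit appearance descriptors. Assignment is a
Hungarian solve inside the standard age-ordered matching cascade.

On top of this baseline:

* **Camera motion compensation (CMC).** Each frame pair yields a
  background affine `A = [M | T]` estimated from FAST/BRIEF keypoints —
  restricted to static regions below a gradient-detected horizon and
  outside dilated detection boxes — matched by 2-NN Hamming with Lowe's
  ratio test and fit by RANSAC. Every predicted state is warped,
  `x̂' = M̂ x̂ + T̂`, `P' = M̂ P M̂ᵀ + Qₙ`, before association.
* **Confidence-tiered association (COS).** Detections are stratified at
  confidence 0.6 / 0.3 / 0.1 into high, medium and low tiers and matched
  in that priority order with tier-specific ceilings — strict (0.2) for
  reliable boxes, looser (0.3) for partially occluded ones, and overlap
  only (IoU ≥ 0.5) for the low tier, whose boxes never spawn new tracks.
  Occluded animals keep their identity instead of resurfacing under a
  new one.

The package also provides the CARAFE content-aware reassembly operator
(softmax-normalized per-location kernels, dot-product reassembly at
upsampling factor σ) as a standalone numeric primitive, and CLEAR-MOT /
IDF1 / AP evaluation: `MOTA = 1 − (ΣFN + ΣFP + ΣIDSW)/ΣGT`,
`MOTP = Σd/Σc` with `d` the matched-pair IoU,
`IDF1 = 2·IDTP/(2·IDTP + IDFP + IDFN)`.

## A worked example

Simulate a 6-animal scene with camera jitter, render its frames, track
with the full pipeline, and score against ground truth:

```r
library(herdtrack)

sc <- simulate_scenario(scenario_config(n_targets = 6, n_frames = 40, seed = 42))
sc
#> <mot_scenario> 6 targets, 40 frames, 250 detections

frames <- render_frames(sc)
set.seed(42)
res <- track(sc$detections, tracker_config(),
             frames = frames, descriptors = sc$descriptors)
res
#> <mot_tracking> 199 boxes, 7 identities, frames 1 - 40

evaluate_tracking(sc$gt, res)
#> MOT evaluation (IoU >= 0.50)
#>   MOTA   82.5%   MOTP   88.6%   IDF1   87.0%
#>   FP 0   FN 41   IDs 1   (GT boxes 240)
```

Six animals produced seven track identities (one occlusion episode split
a track once); MOTA counts every miss, false alarm and identity switch
against the 240 ground-truth boxes, and MOTP says matched boxes overlap
truth at 0.886 IoU on average. The same detections without camera motion
compensation collapse to MOTA 63.8% with 6 identity switches:

```r
glance(evaluate_tracking(sc$gt,
  track(sc$detections, tracker_config(use_cmc = FALSE),
        descriptors = sc$descriptors)))
#> # A tibble: 1 × 8
#>    mota  motp  idf1    fp    fn   ids  n_gt iou_min
#>   <dbl> <dbl> <dbl> <int> <int> <int> <int>   <dbl>
#> 1 0.638 0.845 0.617     0    81     6   240     0.5
```

Results are tibbles throughout (`tidy()`, `glance()`, `autoplot()` on
every result type), and MOTChallenge-format files are read and written by
`read_mot_detections()` / `write_mot_results()` and friends. A thin
command-line front end covers the same pipeline from a shell:

```sh
Rscript inst/cli/herdtrack simulate --out sim --seed 5 --render
Rscript inst/cli/herdtrack track --det sim/det.txt --frames sim/frames \
    --descriptors sim/descriptors.csv --out results.txt --seed 5
Rscript inst/cli/herdtrack evaluate --gt sim/gt.txt --results results.txt --out report.csv
```

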