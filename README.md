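# vestrack

Single-particle tracking for 2D time-lapse fluorescence movies of small,
fast-moving carriers — typically post-Golgi vesicles imaged in tissues
where the channel also contains much brighter nuisance structure (Golgi
ministacks, diffuse ER signal, out-of-focus blobs). The package covers the
whole workflow: movie I/O, a synthetic movie generator with ground truth,
preprocessing, detection, two-step track linking, per-track analytics, and
a tracking-performance metric suite.

## The method

**Detection.** After temporal background subtraction (per-pixel mean over a
centered window of *m* frames) and contrast-limited adaptive histogram
equalization, each frame runs through a multiscale spot-enhancing filter:
iteratively over a scale ladder σ¹ < … < σᴷ,

    f(x, y, σᵏ) = LoG(σᵏ) ∗ (b(x, y, σᵏ⁻¹) · g(x, y)),   b(σ⁰) ≡ 1
    Tᵏ = μᵏ + c·ςᵏ

with the binary mask *b* updated to *f > Tᵏ* after every iteration
(μᵏ, ςᵏ: mean and SD of the response). Local maxima of the final response
form a deliberately permissive candidate pool; a small trained CNN
(3×3×16 conv → ReLU → 3×3×32 conv → ReLU → 2×2 max-pool → 64 dense →
softmax, trained with binary cross-entropy, RMSprop and ×6
rotation/flip augmentation on a few hundred 16×16 ROIs) prunes it, and
iterative center-of-mass refinement gives subpixel positions.

**Linking.** Detections become short tracklets by gated Hungarian
assignment on frame-to-frame distance. A discrete Bayesian network then
scores every nearby tracklet pair — evidence: intensity similarity *I*,
orientation *Oᵣ*, speed *Sₚ*, end-to-start distance *D*, frame gap *G*,
and a sequence node with order/overlap parents *O_d*, *O_v* — giving the
connectivity probability

    P_c = P(CS = True | I, Oᵣ, Sₚ, O_d, O_v, G, D)

by exact enumeration. A second Hungarian pass over 1 − P_c assembles
tracklets into tracks; linking can run in multiple passes (small distance
gate first for slow particles, larger gate for fast ones).

**Analytics and evaluation.** Per-track measures (total/net/maximum
distance, trajectory time, net orientation, normalized brightness,
curvilinear and straight-line speeds, sliding-window maximum speed,
MSD-based moving segments), quadrant classification against a tissue axis,
10° polar histograms normalized to tracks/minute, axis displacement, and
per-frame Pearson correlation between channels. Estimated tracks are
scored against ground truth with α, β, point- and track-level Jaccard
coefficients, RMSE and γ (the fraction of ground-truth tracks recovered).

## Worked example

```r
library(vestrack)

# 1. simulate a movie: 5 vesicles, 3 Golgi-like blobs, Poisson SNR 7
par <- scenario_params(T = 40, H = 128, W = 128, n_particles = 5,
                       snr = 7, n_distractors = 3, seed = 7)
sim <- simulate_movie(par)

# 2. train the patch classifier on a matching scenario
tp <- render_training_patches(scenario_params(T = 40, H = 128, W = 128,
                                              n_particles = 8, snr = 7,
                                              n_distractors = 3, seed = 8),
                              n_pos = 150, n_neg = 150)
model <- train_classifier(tp$patches, tp$labels, epochs = 15, seed = 0)

# 3. track end to end and score against the ground truth
run <- track_movie(sim$sequence, model, min_points = 3, seed = 1)
str(run$manifest$counts)
#> List of 5
#>  $ candidates         : int 3331
#>  $ accepted_detections: int 187
#>  $ tracklets          : int 26
#>  $ tracks             : int 10
#>  $ filtered_tracks    : int 6
compute_metrics(sim$ground_truth, run$tracks,
                pair_tracks(sim$ground_truth, run$tracks))
#> evaluation: alpha 0.829  beta 0.817  JSC 0.877  JSC_theta 0.833  RMSE 0.486 px  gamma 1.000
```

The manifest shows the funnel: ~83 noisy filter candidates per frame are
pruned by the classifier to ~4.7 accepted detections per frame (the movie
contains 5 vesicles), which link into 6 final tracks. All 5 true tracks
are recovered (γ = 1; the extra track is a spurious fragment), matched
points localize to ≈ 0.5 px (RMSE), and α ≈ 0.83 reflects the remaining
detection gaps in this small quick-start run.

Per-track measures use physical units from the sequence metadata
(100 nm pixels, 4 frames/s here):

```r
longest <- which.max(sapply(run$tracks$tracks, function(t) nrow(t$det)))
m <- track_measures(run$tracks$tracks[[longest]], frame_interval_s = 0.25,
                    pixel_size_nm = 100)
unlist(m[c("d_total_um", "d_net_um", "t_traj_s", "v_curvilinear_um_s")])
#>   d_total_um     d_net_um     t_traj_s  v_curvilinear_um_s
#>    6.979041     3.637213     9.750000       0.715799
```

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/vestrack.R simulate --preset snr7-low --seed 7 --out demo/
Rscript inst/cli/vestrack.R train    --out classifier.json
Rscript inst/cli/vestrack.R track    --model classifier.json --in demo/movie.tif --out tracks.json
Rscript inst/cli/vestrack.R evaluate --gt demo/ground_truth.json --est tracks.json
```

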