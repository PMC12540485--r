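---
title: "Modelling location-emotion trajectories with emotraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling location-emotion trajectories with emotraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(emotraj)
```

## The problem

Geotagged social-media posts carry two coupled signals: *where* a user is
and *how they feel*. When an affect-recognition front end has scored each
posted image as a point on the Russell circumplex — valence $x \in [-1,1]$
(pleasantness) and intensity $y \in [-1,1]$ (activation) — every post
becomes a timestamped (location, emotion) observation. `emotraj` models
the joint dynamics of these observations and predicts, for each user, the
next *stay area* and the next *emotional quadrant* together. This vignette
explains each stage's model, its assumptions, the parameters that matter,
and what the package's synthetic validation does and does not establish.

## Stage models and assumptions

### Stay areas by density peaks

Check-in coordinates are unevenly dense — a few hotspots and long sparse
tails — which defeats fixed-radius or fixed-k methods. We use the
density-peak scheme: local density
$\rho_i = \sum_{j \ne i} \exp(-(d_{ij}/h)^2)$ with haversine distances
$d_{ij}$ (no map projection needed at city scale), $\delta_i$ the distance
to the nearest strictly denser point, centers the $n$ points with largest
$\gamma_i = \rho_i \delta_i$, and all other points inheriting the label of
their nearest denser neighbor in one pass down the density ordering.
Points in the lowest density percentile (`noise_quantile`, default 1%)
that are more than $3h$ from any denser neighbor are noise.

Parameters: bandwidth $h$ (meters; default 500, a city-block-to-district
scale) and the number of areas (the method takes it as given, in the
spirit of operating ranges of 100–500 areas on metropolitan data; the
package treats it as the exact number of centers). Density ties and
$\gamma$ ties break toward the lower point index, making the procedure
deterministic and permutation-invariant up to label identity. The
implementation is the $O(n^2)$ all-pairs form, adequate for the
$10^3$–$10^4$ points used here; a spatial index would be the next step for
larger data.

### Emotional quadrants

A post's emotion is the **raw componentwise sum** of its image readings
(a deliberate choice: the aggregate magnitude grows with the number of
images; an optional mean mode exists but is off by default, matching the
additive definition of the post-level emotion). The quadrant map is
I $(x>0, y>0)$, II $(x\le 0, y>0)$, III $(x\le0, y\le0)$, IV
$(x>0, y\le0)$: values exactly on an axis count as *low*. Online data
over-represents positive emotion, so the conservative tie direction avoids
inflating the positive classes. Intensity is modelled on a signed axis
about a neutral midpoint; a front end that emits arousal in $[0,1]$ should
be adapted with $a \mapsto 2a - 1$ before ingestion.

### The emotional interaction graph

Vertices are (stay area, quadrant) pairs. For one user whose consecutive
posts fall on vertices $V_i \to V_j$ with gap $\Delta t = t_j - t_i > 0$,
the edge gains

$$g(\Delta t) = \frac{1}{1 + e^{-T_{max} / (\alpha\,\Delta t)}},$$

where $T_{max}$ is that user's largest inter-post gap and $\alpha$
(default 10) regulates the decay. $g$ is strictly decreasing in
$\Delta t$ with range $(0.5, 1)$: short gaps bind states strongly, and
even that user's longest gap retains weight $\sigma(1/\alpha) \approx
0.525$. Edge weights sum over users. Design choices worth knowing:

* Edges are directed by temporal succession; self-loops are kept (staying
  put in the same emotional state is informative).
* Equal timestamps are separated by shifting the later post (file order)
  forward one second, since the decay requires $\Delta t > 0$.
* A user with a single gap has $T_{max}$ equal to that gap, contributing
  $\sigma(1/\alpha)$.
* The normalization is per-user ($T_{max}$), so users with different
  posting rhythms contribute comparable weights.

### Vertex embedding

The graph is embedded in the LINE family: the *first-order* objective
pulls directly connected vertices together; the *second-order* objective
(weighted by the vertex's out-degree $\lambda_i$, i.e. its importance)
matches each vertex's conditional out-neighborhood distribution via a
context-vector factorization — vertices visited in similar contexts land
near each other even without a direct edge. The default trains both on
`dim/2` coordinates each and concatenates (default `dim = 64`).

Optimization: edges sampled proportional to weight (R's weighted
`sample()`, the same distribution an alias table draws from), 5 negatives
per positive from a noise distribution $\propto \lambda^{3/4}$,
initialization uniform in $[-0.5/d, 0.5/d]$, learning rate 0.025 decaying
linearly to $10^{-4}$ over `n_samples` draws (default $10^5$). Gradients
are aggregated over mini-batches of 128 draws before each update; under a
fixed seed the result is bitwise reproducible. The exact second-order
objective and its analytic gradient are implemented separately for the
test suite's finite-difference check. Vertices with no incident edges stay
at initialization and are flagged.

### The joint predictor

For a user with trajectory $V_1 \dots V_m$, the matrix
$F = [u_1; \dots; u_{m-1}]$ of embedding vectors (time order) is the
input and $(C_m, E_m)$ the target. Sinusoidal positional encodings
$PE(pos, 2i) = \sin(pos/10000^{2i/d})$,
$PE(pos, 2i+1) = \cos(pos/10000^{2i/d})$ are added elementwise. Positions
count the step's place in the matrix anchored at the *most recent* step
(last row = position 0): prediction conditions on the latest state, and
anchoring there gives that state a window-length-independent code while
preserving the ordering of the history. Two branches read the encoded
sequence in parallel:

* **multi-head scaled dot-product attention**
  $\mathrm{softmax}(QK^\top/\sqrt{d_k})V$ (default 4 heads), taken at the
  final time step — the prediction conditions on the most recent state
  attending over the history;
* **a BiLSTM** (default 64 units per direction), final state of each
  direction.

The branch outputs are concatenated into one shared fully connected ReLU
trunk. Two output factorizations are implemented: the default two softmax
heads (areas; quadrants) trained with the summed per-head cross-entropies
$L = -\frac1N \sum_i \sum_c y_{ic} \log p_{ic}$, and a `joint_head`
variant — one softmax over the (area × quadrant) vertex classes whose
marginals provide the per-head probabilities. Two marginal heads scale
linearly in the class counts and keep each loss interpretable; the joint
head guarantees the predicted (area, quadrant) pair is a coherent vertex,
which measurably helps joint accuracy when both signals come from the same
transition structure — the pipeline's default config uses it. The headline
metric ("both heads correct") is identical under either factorization. A
plain-BiLSTM ablation (`use_attention = FALSE`) exists for directional
comparison.

Batching right-aligns sequences with zero pre-padding and masks padded
steps in both branches (softmax exclusion; state carry-through), so padded
and unpadded presentations of the same sequence give identical outputs.
The whole network — forward, backpropagation, Adam — is implemented in
vectorized base R; the test suite verifies the analytic gradients against
central finite differences and the attention operator against a
scalar-loop oracle.

Defaults: Adam at $10^{-3}$, dropout 0.1 on the trunk, batch 64, 256
epochs, trunk width 1024 — at 64-dimensional input, 100 areas and these
sizes the model has roughly 390K trainable parameters, in the intended
"lightweight, under half a million" regime. Training is seeded and
CPU-deterministic. With `keep_best = TRUE` and a validation split, the
returned parameters are those of the epoch with the best validation joint
accuracy — the overfitting guard used by the pipeline.

Training samples: every trajectory step with at least one predecessor
yields a sliding-window sample (the most recent `max_seq_len = 20` steps),
so a length-$m$ trajectory contributes $m-1$ samples; the full-trajectory
window is exactly the trajectory matrix above. Splits are **by user**, not
by sample, so no user's history straddles train and test.

## What the synthetic generator emulates

`simulate_world()` / `simulate_users()` generate check-ins with known
ground truth, emulating the structure reported for metropolitan microblog
data:

* spatially uneven stay areas (Gaussian scatter, default $\sigma = 150$ m,
  around centers at least 2 km apart in a city-scale bounding box);
* bursty inter-post gaps, log-normal with median 24 h and $\sigma = 1.2$
  log-hours — days to weeks between posts, chosen qualitatively, not
  fitted;
* quadrant imbalance: default mix $(0.45, 0.127, 0.139, 0.284)$, i.e.
  73.4% positive (I+IV) and 12.7% in quadrant II;
* sequence lengths uniform on 10–51 check-ins;
* first-order Markov transitions over (area, quadrant) states: the
  designated successor of each state carries `stickiness` (default 0.8),
  the remainder spreads over other states uniformly across areas and
  proportionally to the quadrant mix across quadrants. The remainder
  follows the mix (rather than being flat) because a flat remainder
  cannot, in general, hold the stationary quadrant marginal at an
  imbalanced target; successor draws are re-sampled until the stationary
  marginal is within 0.05 of the mix.

Because the designated successor is excluded from the remainder, the
optimal predictor's accuracy is exactly the stickiness, and
`bayes_rate()` computes it as $\sum_v \pi(v) \max_w P(w\,|\,v)$ from the
stationary distribution $\pi$.

A first-order chain is the minimal generative model under which the
prediction task is well-posed and its ceiling computable; real data has
unknown order and non-stationarity. Passing the end-to-end test therefore
shows that the pipeline *recovers known structure at the right level* —
areas (ARI $\ge 0.9$), quadrant labels, and next-state predictability up
to the Bayes ceiling — not that any particular accuracy transfers to real
social-media data. Boundary noise (`boundary_noise`) optionally pushes a
fraction of posts' readings across a quadrant boundary to emulate
front-end measurement error; the default study condition keeps it at 0 so
the ceiling stays exact.

## Numerical and engineering choices

* **Problem sizes.** The default pipeline trains on 20 areas × 4 quadrants,
  200 users (≈6,000 check-ins, ≈4,200 training windows) for 25 epochs with
  batch 128, a 256-wide trunk, dropout 0.2 and the joint-vertex head —
  a few minutes on one CPU, with best-epoch selection on a 10% train-side
  split. The pipeline trains two models from different derived seeds and
  averages their class probabilities (`n_models`), a standard variance
  reducer for small networks on modest data. These are the package's
  desk-scale defaults; every size is a config field.
* **Determinism.** One pipeline seed fans out to per-stage seeds through a
  hash-based derivation (all below $2^{31}$), so stages can be re-run
  independently and a full re-run reproduces `metrics.json` byte for byte.
* **Ties.** Density and $\gamma$ ties break by point index; axis-exact
  emotions classify as the low quadrant; equal timestamps shift +1 s in
  file order; argmax ties in prediction take the first class.
* **Degenerate inputs.** A single point gets $\rho = \delta = 0$ and is its
  own density peak; trajectories shorter than 2 surviving steps are flagged
  unusable and contribute no edges; vertices without edges keep their
  random embedding and are reported; an all-noise or single-class training
  set is rejected with a clear error.
* **Metrics.** Joint accuracy requires both heads correct; macro
  precision/recall/F1 exclude classes absent from the truth (with a
  warning); per-quadrant tables report joint accuracy by true quadrant;
  length-binned accuracy stratifies by the number of check-ins up to the
  target (bins 10–50). k-fold cross-validation (`evaluate_model(...,
  k_folds = k)`) refits per fold and averages; the default evaluation is a
  user-level holdout.

## Known limitations

* The density-peak implementation is quadratic in the number of points;
  beyond ~$10^5$ points it needs a spatial index.
* The simulator does not model social influence between users, periodic
  (daily/weekly) rhythms, or drift in the transition structure.
* Embedding quality degrades for vertices visited only a handful of times;
  downstream accuracy on rare states is bounded by their sample counts,
  which is why held-out accuracy sits slightly below the Bayes ceiling at
  the default sample sizes.
* The intensity sign convention assumes a front end calibrated around a
  neutral midpoint; miscalibrated arousal scales shift the quadrant
  boundary.
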