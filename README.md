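# emotraj

Joint prediction of *where a user will check in next* and *how they will
feel there*, from geotagged social-media posts with per-image emotion
readings.

Urban-emotion studies increasingly work from streams of geotagged posts
whose images have been scored by an affect-recognition front end as points
on the Russell circumplex — a valence (pleasantness) axis *x* and an
intensity (activation) axis *y*, both in [-1, 1]. `emotraj` implements a
complete modelling pipeline over such data, for researchers in affective
computing and spatio-temporal behaviour modelling:

1. **Stay areas** — density-peak clustering of check-in coordinates:
   local density ρᵢ = Σⱼ exp(−(dᵢⱼ/h)²) with haversine distances, δᵢ the
   distance to the nearest denser point, centers ranked by γᵢ = ρᵢδᵢ,
   labels propagated down the density ordering, low-density isolated
   points filtered as noise.
2. **Emotional quadrants** — per-post emotion is the raw sum of its image
   readings, `dimension = Σᵢ (xᵢ, yᵢ)`, classified into quadrant
   I (+,+), II (−,+), III (−,−) or IV (+,−); axis ties count as "low".
3. **Emotional interaction graph** — vertices are (stay area, quadrant)
   states; each user's consecutive check-ins contribute a directed edge
   with time-decay weight `g(Δt) = σ(T_max / (α·Δt))` (σ the logistic
   function, `T_max` that user's largest inter-post gap, α = 10), summed
   over users.
4. **Vertex embedding** — LINE-style first- plus second-order
   proximity-preserving embeddings trained by weighted edge sampling with
   negative sampling (noise distribution ∝ out-degree^¾).
5. **Joint predictor** — each user's trajectory matrix
   `F = [u₁ … u_{m−1}]` plus sinusoidal positional encoding feeds two
   parallel branches, multi-head scaled dot-product attention
   `softmax(QKᵀ/√d_k)V` and a BiLSTM; their final-step outputs are
   concatenated into a shared fully connected trunk with two softmax
   heads, trained with the summed cross-entropies
   `L = −(1/N) Σᵢ Σ_c y_ic log p_ic`. The network (forward, backprop,
   Adam) is implemented in vectorized base R inside the package.
6. **Synthetic worlds** — a seeded Markov-chain check-in simulator with a
   closed-form optimal accuracy (`bayes_rate()`), so the pipeline's
   recovery of known structure is testable end to end without any
   proprietary data.

## Worked example

```r
library(emotraj)

res <- run_pipeline(default_pipeline_config(), out_dir = "demo_run", seed = 1)

m <- res$metrics
round(c(joint = m$joint_accuracy, area = m$area_accuracy,
        quadrant = m$quadrant_accuracy, bayes = m$bayes_rate,
        ari = m$clustering_ari), 4)
#>    joint     area quadrant    bayes      ari
#>   0.7752   0.7826   0.8485   0.8000   1.0000
```

The default configuration simulates 200 users over 20 stay areas with
stickiness 0.8 (so the best achievable joint accuracy — the Bayes rate —
is 0.80), recovers the generating areas perfectly (adjusted Rand index 1),
and trains the predictor to a held-out joint accuracy within a few points
of that ceiling. `res$model` is an S3 model object with `print()`,
`summary()`, `coef()`, `plot()` (loss history) and `predict()` methods:

```r
print(res$model)
#> Attention-BiLSTM location-emotion predictor
#>   input dim 64 | 4 heads | LSTM hidden 64/dir | trunk 256
#>   classes: 20 stay areas x 4 quadrants | 152,464 parameters
#>   trained 25 epochs | final train loss 0.6224

predict(res$model, res$samples[res$is_val][1:3])$top_quadrant
#> [1] "I"  "IV" "IV"
```

Each stage is also exposed directly (`cluster_stay_areas()`,
`label_checkins()`, `build_graph()`, `line_embed()`,
`fit_emotion_model()`, …) and as subcommands of the thin CLI at
`inst/cli/emotraj.R`. Real data enters through `read_checkins()`, a CSV
reader with configurable column mapping that accepts both ISO-8601 and the
legacy microblog timestamp dialect.

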