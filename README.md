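# dasnet

Forecasting disease activity for patients with chronic inflammatory joint
diseases (rheumatoid arthritis, axial spondyloarthritis, psoriatic and
undifferentiated arthritis) from heterogeneous longitudinal registry
journeys — and explaining the forecasts through attention weights and
case-based patient similarity.

Registry journeys mix four information sources: demographics (static),
clinical measures (per-visit labs, joint counts and the composite disease
activity scores DAS28 and ASDAS), medication start/stop events, and
patient-reported outcomes. Visits are irregular, features are missing, and
different patients record different scores. `dasnet` implements:

* a **multi-task attention network**: per-source MLP encoders into a common
  embedding size *q*; one LSTM + local-attention temporal block per
  time-related source, aggregating each source's history into
  *H(ev) = Σᵢ aᵢˡᵒᶜ L(eᵢ)*; a global-attention representation block mixing
  the sources and demographics into *P = Σ aᵍˡᵒᵇ(ev) H(ev)*; the latent
  representation *R = [P, t]* (with *t* the time to prediction); and two
  independent MLP heads predicting the next DAS28 and ASDAS. The training
  objective sums, over a pair of score-specific patient batches, the
  per-batch mean squared error over all targets of the sampled patients
  (AdamW, batch sizes proportional to the per-score target counts, early
  stopping on held-out patients);
* **patient-similarity retrieval**: L1 k-nearest-neighbour search (k = 50)
  over the latent representations, with a k-NN regression model plus
  raw-feature-space and random-subset baselines;
* **case-based feature importance**: average absolute distance (AAD) and
  standardised AAD for continuous features; prior vs adjusted category
  probabilities for categorical features;
* **attention summaries**: global weights by history length and by
  ≥20%-improvement status, local clinical-measure weights by recency;
* **baselines**: naive last-value carry-forward, a feed-forward net on
  last available feature values, a single concatenated-sequence LSTM;
* a **synthetic registry generator** with a known AR(1) latent disease
  process (medication and demographic effects, irregular Poisson visit
  times, realistic missingness), providing ground truth and exact Bayes
  error floors so the whole pipeline is testable without any clinical data.

All network forward *and* backward passes are hand-written matrix algebra
(no autodiff framework); the analytic gradients are verified against finite
differences in the test suite.

## Worked example

```r
library(dasnet)

reg <- simulate_registry(sim_config(seed = 1)) |>  # 600-patient default cohort
  filter_patients() |>
  select_medications()
sp  <- stratified_split(reg, seed = 1)
fit <- dasnet(reg, sp, control = dasnet_control(seed = 1))
fit
#> <dasnet> latent size 13 | 7398 parameters | best epoch 75 (val loss 0.3185)

test_ids <- sp$patient_id[sp$split == "test"]
pred  <- predict(fit, reg, test_ids) |> dplyr::mutate(model = "dasnet")
naive <- naive_baseline(reg) |> dplyr::filter(patient_id %in% test_ids)
compare_models(dplyr::bind_rows(pred, naive))
#> # A tibble: 4 × 6
#>   model  score_kind   mse mse_sd     n  rank
#>   <chr>  <chr>      <dbl>  <dbl> <int> <int>
#> 1 naive  asdas      0.148     NA   669     1
#> 2 dasnet asdas      0.158     NA   678     2
#> 3 dasnet das28      0.379     NA   613     1
#> 4 naive  das28      0.402     NA   607     2
```

Each row is one model's test-set mean squared error for one score. On this
cohort the network clearly beats carrying the last DAS28 forward; for ASDAS
the naive predictor is close to the generator's Bayes floor by construction
and the two are nearly tied (the methods vignette discusses why the
synthetic process makes the naive baseline unusually strong). The latent
space then powers retrieval and explanation:

```r
idx <- build_embedding_index(fit, reg, sp)
knn_regress(idx, k = 50)
#> <das_knn> k = 50
#> # A tibble: 2 × 3
#>   score_kind   mse     n
#>   <chr>      <dbl> <int>
#> 1 asdas      0.196   678
#> 2 das28      0.476   613

head(feature_importance_report(idx, k = 50)$continuous, 4)
#> # A tibble: 4 × 4
#>   feature       aad aad_std     n
#>   <chr>       <dbl>   <dbl> <int>
#> 1 das28       0.305   0.209   607
#> 2 asdas       0.208   0.220   669
#> 3 radai_score 0.723   0.437  1252
#> 4 crp         0.689   0.452  1259
```

The feature-importance report ranks the two disease activity scores as the
features most strongly preserved within retrieved neighbourhoods (lowest
standardised AAD) — neighbours really are patients at a similar disease
stage. `summarise_attention(fit, reg, test_ids)` summarises which
information sources the model attends to as histories grow, and
`classify_active(idx, mode = "logistic")` evaluates active-disease
classification (DAS28 > 2.6, ASDAS > 2.0) from the embeddings.

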