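# emgadapt

Active-learning adaptation of surface-EMG activity classifiers to unseen
subjects.

## The problem

Classifiers that decode human activity from surface electromyography
(sEMG) lose much of their accuracy on people they were not trained on:
electrode placement, skin impedance, anatomy and movement style all shift
the signal distribution between subjects. Re-collecting a large labeled
dataset for every new user is impractical; the question this package
addresses is how to adapt a pre-trained model to a new subject with a
*small, deliberately chosen* labeling budget. It is aimed at researchers
in wearable sensing, myoelectric control and domain adaptation who want a
complete, testable reference implementation of discrepancy-driven active
adaptation — plus a controllable synthetic cohort generator, so every
claim can be reproduced without access to proprietary recordings.

## The method

The classifier is a twin **relation network**. A query window
`x` (`1 × N × L`: `N` channels × `L = 200` samples, a 200 ms window) and a
**template set** `T` of `K` labeled windows per class are passed through a
shared convolutional feature extractor `G`; for each class `c` the query
map and the summed template maps are concatenated into a relation matrix,
and a relation head turns each matrix into a similarity score
`r_c ∈ (0,1)`. Prediction is `argmax_c r_c`.

Two auxiliary heads `F1, F2` (same topology as the main head `F`) are
trained with

    min_{F1,F2}  CE(F1) + CE(F2) − L_dis,
    L_dis = E_x [ d(r1, r) + d(r2, r) + d(r1, r2) ],
    d(a, b) = (1/C) Σ_c |a_c − b_c|,

so they stay accurate on the source while disagreeing maximally on
unlabeled target windows. Each target window is then scored by its total
classifier discrepancy `D(x) = d(r1,r2) + d(r,r1) + d(r,r2)` and the
acquisition function `S(x) = D(x) − mean_source(D)`. The top-`n1` windows
("important" — near the decision boundary) are labeled and used to
fine-tune `G` and `F` (backward strategy); the bottom-`n2` windows
("confident" — near the domain centre) are labeled and distilled into a
new template set by PCA to 3 dimensions plus per-class K-means, taking
each cluster's central real window (forward strategy).

## A worked example

One leave-one-subject-out fold on the default synthetic gait cohort
(4 subjects, 4 gait-phase classes, 9 channels at 1 kHz):

```r
library(emgadapt)

# simulate the default 4-subject gait cohort; subject 4 is the unseen target
cohort <- generate_cohort(cohort_config(seed = 7))
windows <- lapply(cohort$recordings, prepare_windows)
source_ws <- ws_bind(windows[1:3])
target_ws <- windows[[4]]

# pre-train the twin relation network on the three source subjects
cfg <- train_config(seed = 1)                      # "stable" preset
model <- init_model(model_config(n_channels = 9, window_len = 200,
                                 n_classes = 4), seed = 1)
templates <- init_templates(source_ws, n_classes = 4, shots = 5, seed = 1)
model <- pretrain(model, source_ws, templates, cfg)

pool <- target_ws
pool$labels <- rep(NA_integer_, n_windows(pool))   # target arrives unlabeled
oracle <- make_oracle(target_ws)                   # simulated annotator

before <- mean(predict(model, target_ws, templates) == target_ws$labels)
res <- adapt(model, pool, source_ws, oracle, templates, cfg)
after <- mean(predict(res$model, target_ws, res$templates) == target_ws$labels)

cat(sprintf("source-only target accuracy: %.1f%%\n", 100 * before))
cat(sprintf("adapted target accuracy:     %.1f%% (%d labels spent)\n",
            100 * after, oracle_budget(oracle)))
```

which prints:

```
source-only target accuracy: 47.0%
adapted target accuracy:     97.4% (450 labels spent)
```

Before adaptation the model is near chance on this subject (the cohort
generator deliberately injects subject-specific channel weightings,
gains, electrode-shift mixing and timing shifts); after one adaptation
round — 250 "important" windows for fine-tuning plus 200 "confident"
windows distilled into 5 target templates per class — it recovers to
97.4%. The adaptation report also records that the mean target-pool
discrepancy rose from 0.024 to 0.52 during auxiliary training, i.e. the
auxiliary boundaries tightened as intended.

The experiment harness automates the full designs:
`loso_run()` (leave-one-subject-out comparison of `source_only`,
`random_sampling`, `importance_sampling`, `full_framework`),
`template_count_study()` (1/5/10-shot accuracy and timing),
`ablation_templates()` (important vs random vs confident templates) and
`ablation_budget()` (importance vs random sampling across labeling
budgets). A thin command-line front end lives in `inst/cli/emgadapt.R`
(verbs `simulate`, `loso`, `ablate-templates`, `ablate-budget`).

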