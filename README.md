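# harkit

An R toolkit for wearable-sensor **human activity recognition (HAR)**
research, built around two questions that dominate HAR study design:

* **Where should the sensors go?** Every 2D pose keypoint from a camera is
  treated as a *virtual accelerometer*. For a candidate location set
  $S$ and activities $i = 1,\dots,n$, the flattened positional trace
  $A^S_i$ of each activity is compared with every other via the
  cross-validated cosine-distance score
  $$D_S = \sum_{i<j}\Bigl|\,1 - \tfrac{A^S_i \cdot A^S_j}{\lVert A^S_i\rVert\,\lVert A^S_j\rVert}\Bigr|,$$
  and the $2^5-1 = 31$ subsets of the five candidates (wrists, ankles,
  pelvis) are ranked by descending $D_S$ — no physical sensors or model
  training required, just 500+ pose frames per activity.
* **How should modalities be combined?** 10 Hz pose keypoints are
  synchronized with 60 Hz IMU streams (linear interpolation, −1 sentinel
  across gaps), cut into labeled fixed windows (600 samples = 10 s), and fed
  to small trainable classifiers (CNN-LSTM, ResNet-style, DeepConvLSTM)
  under k-fold, leave-recordings-out and leave-one-subject-out protocols,
  with last-layer transfer learning for per-subject personalization.

Everything runs on synthetic data from a built-in generator that emulates a
multimodal nursing-activity study (10 subjects, 13 activities, 17-keypoint
pose at 10 Hz, five 14-channel IMUs at 60 Hz), so the full pipeline is
testable on a laptop with no hardware and no downloads. See
`vignettes/harkit-methods.Rmd` for the model, parameters and limitations.

## Worked example: recover a planted sensor location

A planted-keypoint protocol makes all activities identical everywhere except
the right wrist — ground truth the ranking must recover:

```r
library(harkit)

protocol <- planted_keypoint_scenario(n_activities = 3,
                                      discriminative_keypoint = "right_wrist",
                                      seed = 42)
rec <- simulate_recording(protocol, "subj01", protocol$activities,
                          with_imu = FALSE)
rec
#> <recording> subj01_rec1 (subject subj01): 0 IMU stream(s), pose 1800 frames, 3 label interval(s)

ranking <- rank_placements(rec)
print(ranking, n = 5)
#> <placement_ranking> 31 subsets, 3 activities, 5 folds
#>    1. right_wrist                                   D = 0.0118728  [best with 1]
#>    2. left_wrist+right_wrist                        D = 0.00845538  [best with 2]
#>    3. right_wrist+pelvis                            D = 0.00645534
#>    4. left_wrist+right_wrist+pelvis                 D = 0.00549602  [best with 3]
#>    5. right_wrist+left_ankle                        D = 0.00440543
#>   ...
best_subset_of_size(ranking, 1)
#> [1] "right_wrist"
```

The planted wrist tops the ranking (D ≈ 0.012, an order of magnitude above
the noise-only scores of the other locations), and every flagged
per-size optimum contains it. `write_ranking()` saves the report as JSON.

## Worked example: on-device-style personalization

Pretrain a CNN-LSTM on three subjects, then fine-tune only the softmax head
on 80% of a held-out subject's recordings (10 epochs, batch 7) and compare
held-out accuracy before and after:

```r
r <- personalization_experiment(seed = 3)
r$report_before
#> <eval_report> n = 24, accuracy = 0.667, macro F1 = 0.593
r$report_after
#> <eval_report> n = 24, accuracy = 0.750, macro F1 = 0.738
```

The printed reports include row-normalized confusion matrices (cells below
0.05 are suppressed), the before/after view used to spot poorly recognized
activities worth re-recording.

## Command line

A thin CLI over the same functions lives at `inst/cli/harkit.R`
(`system.file("cli", "harkit.R", package = "harkit")` after installation):

```sh
Rscript harkit.R simulate --out recs/ --subjects 2 --seed 1
Rscript harkit.R place    --recordings recs/ --out ranking.json
Rscript harkit.R fuse     --recording recs/subj01_rec1/manifest.json --out ds
Rscript harkit.R evaluate --dataset ds --scheme kfold --out report.json
Rscript harkit.R finetune --model m.json --data ds --out m2.json
Rscript harkit.R stats    --recordings recs/ --out stats.csv
```

Each command also accepts `--config file.yaml` with defaults that flags
override; logs go level-tagged to stderr.

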