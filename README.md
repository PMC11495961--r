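# peristartle

Quantifies startle responses of signal receivers during courtship from
2-D pose-estimation keypoint tracks, and tests whether courter status
(bower owner vs subordinate male) changes how strongly receivers react.

Behavioural ecologists increasingly record courtship in the field and
track body keypoints (beak tip, feet, inter-tarsal joints) with
pose-estimation software. Receiver startles — rapid reflexive head
movements inside the bower — are too subtle for manual coding but are
visible in the coordinate stream. `peristartle` provides the full
analysis path from exported per-bout coordinate CSVs to calibrated
peri-event statistics:

1. **Cleaning** — per-bout body height (beak-to-ITJ vertical extent);
   removal of keypoints jumping more than 0.5 body heights per frame,
   flagging of the 0.25–0.5 band.
2. **Relative displacement (RD)** — per frame,
   `RD(t) = ||beak(t) − beak(t−1)|| / mean body height`, so RD = 0.15
   is a head movement of 15% of body size in one frame.
3. **Peri-event deltas** — around each display-element onset `s`, with
   baseline `b` and post `w` frames sharing the occurrence frame:
   `Δ_mean = mean(RD[s … s+w−1]) − mean(RD[s−b+1 … s])`, and the
   analogous `Δ_max`; group statistic = unweighted mean of per-male
   means.
4. **Individual-balanced bootstrap null** — per replicate each male
   contributes Δ at as many random eligible frames as he contributed
   elements; 1000 replicates give the 2.5/97.5% band and an add-one
   empirical p-value. Window (post 4–50) and baseline (5/10/15/20)
   sweeps plus leave-one-out stability probe robustness.
5. **Bower exits** — exits attributed to the most recent preceding
   element; status effect tested by an exactly-enumerable cluster
   permutation over males (binomial GLMM available as an alternative).
6. **Synthetic data** — a generator emulating the recording design
   (static pose, keypoint jitter, mis-detections, element streams,
   startle pulses, exits) so the whole pipeline is testable without
   field data.

## Worked example

```r
library(peristartle)

cfg <- sim_config(n_owners = 3, n_subordinates = 3,
                  bouts_per_male = c(4, 6),
                  bout_length_frames = c(300, 500))
dataset <- simulate_dataset(cfg, seed = 1)
dataset
#> <startle_dataset>
#>   bouts:    31
#>   frames:   11717
#>   males:    6
#>   events:   137 (43 high / 94 low)
#>   exits:    8

cleaned <- clean_dataset(dataset)
cleaned$report
#> <cleaning_report>
#>   thresholds: hard > 0.5, soft > 0.25 body heights
#>   removed: 48   flagged: 91
#>   data loss: 0.4097% of 11717 frames | 0.08193% of 58585 keypoint records

rd <- relative_displacement(cleaned$dataset$tracks, cleaned$metrics)
high <- dataset$events[dataset$events$intensity_class == "high", ]
deltas <- peri_event_deltas(rd, high, window_spec(baseline = 10, post = 10))
group_statistic(deltas, dataset$metadata)
#> <group_statistic> statistic: delta_mean
#> # A tibble: 2 × 3
#>   status      grand_mean n_males
#>   <chr>            <dbl>   <int>
#> 1 owner         0.0849         3
#> 2 subordinate   0.000999       3

bootstrap_null(cleaned$dataset, "owner", "high", window_spec(10, 10),
               inference_config(reps = 1000, seed = 7), rd = rd)
#> <null_distribution> monte_carlo
#>   group: owner, class: high, baseline 10 + post 10
#>   observed delta_mean = 0.08489, null [-0.01044, 0.01104], p = 0.001998 (two_sided)
#>   1000 replicates over 3 individual(s)

bootstrap_null(cleaned$dataset, "subordinate", "high", window_spec(10, 10),
               inference_config(reps = 1000, seed = 8), rd = rd)
#> <null_distribution> monte_carlo
#>   group: subordinate, class: high, baseline 10 + post 10
#>   observed delta_mean = 0.00100, null [-0.00267, 0.00255], p = 0.4116 (two_sided)
#>   1000 replicates over 3 individual(s)
```

The generator gives owners (only) a startle pulse of 0.3 body heights,
and the analysis recovers exactly that contrast: the owners' group
`Δ_mean` of 0.085 lies far outside its bootstrap null band (smallest
attainable two-sided p at B = 1000 is 0.002), while the subordinate
group sits inside its band. `window_sweep()` repeats this per post size
4–50 and baseline 5–20, `leave_one_out()` checks male-level stability,
and `score_exits()` + `test_exit_status_effect()` run the bower-exit
contrast. `run_pipeline()` orchestrates all stages from one YAML
config with a single master seed and writes CSV/JSON outputs plus a
run manifest.

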