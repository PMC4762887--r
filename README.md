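# flypref

Quantifying two-choice sugar preference of walking *Drosophila* — and
explaining it with a four-state transition model.

## The problem

Hungry flies released into a circular arena (⊘ 76 mm) whose two halves are
coated with sucrose or water accumulate on the sugar side within tens of
seconds. The standard read-out is the preference index

```
PI = (N_sugar − N_water) / (N_sugar + N_water)
```

pooled over the 30–60 s window of a 1-minute recording. Two behavioural
channels drive the accumulation: flies *taste* the sugar and start feeding
(stopping on the sugar side), and sugar *suppresses locomotion* (they walk
more slowly there). `flypref` provides the complete computational chain for
this assay, for researchers analysing overhead video of multi-fly arenas:

1. **`synthetic_arena`** — a ground-truthed generator: correlated random
   walkers with side-dependent speeds and feeding-state dynamics, rendered
   as noisy grayscale frames (`simulate_agents()`, `render_frames()`,
   `write_frame_stack()`), so the tracker can be benchmarked without any
   real video.
2. **tracker** — per-frame segmentation by thresholding + binarized
   background subtraction + erosion/dilation (`binarize_and_clean()`),
   particle measurement and a likelihood classification of
   (bounding-box diagonal, eccentricity) that flags merged blobs
   (`score_likelihood()`), iterative local re-thresholding to split them
   with a 40-iteration cap (`resolve_merged()`), second-moment ellipse
   fitting (`fit_ellipses()`), and greedy closest-neighbour identity
   assignment across consecutive frames gated at ~7 mm and 90°
   (`match_frames()`, `track_stack()`).
3. **behaviour metrics** — `preference_index()`, `pooled_pi()`,
   `velocity_summary()`, PER fractions (`per_fraction()`) and logistic
   dose–response fits (`fit_sigmoid()`).
4. **preference model** — flies occupy four states (free to walk or feeding,
   on sugar or water) with reversible constant-rate transitions. With sugar
   affinity `A = k_Sin/k_Sout`, speed ratio `B = k_SW/k_WS` and water
   affinity `D = k_Win/k_Wout` the equilibrium preference is

   ```
   PI = ((1 + A) − B(1 + D)) / ((1 + A) + B(1 + D))
   ```

   (`equilibrium_pi()`, verified against the ODE system in
   `solve_transient()`). PER dose–response data are transformed into
   `A(conc)` (`per_to_affinity()`, calibrated by `calibrate_affinity()`),
   velocity data into `B(conc)` (`speed_ratio_from_velocity()`), and
   `predict_dose_response()` / `simulate_mutants()` produce predicted
   preference curves and theoretical single/double mutants.

## Worked example

```r
library(flypref)

cfg   <- arena_config(duration = 60)          # 76 mm arena, 10 fps
dyn   <- agent_dynamics()                     # A = 2, B = 0.5, D = 0.001
truth <- simulate_agents(dyn, cfg, n_flies = 15, seed = 1)

## render a 5 s excerpt and track it
stk    <- render_frames(truth[truth$frame <= 50, ], cfg, seed = 2)
tracks <- track_stack(stk, fps = cfg$fps)
tracks
#> fly_tracks: 748 detections over 50 frames, 731 track steps

## how well did the tracker do against the known ground truth?
ev <- evaluate_tracking(tracks, truth)
c(ev$identity_error_rate, ev$mean_orientation_error_deg, ev$mean_position_error_mm)
#> [1] 0.00000000 1.09046448 0.02127616

## behavioural read-out of the full simulated minute
counts <- count_sides(truth, cfg)
pooled_pi(counts, window = c(30, 60))
#> [1] 0.9262222

## ... which the model explains from the generating ratios
equilibrium_pi(model_ratios(A = 2, B = 0.5, D = 0.001))
#> [1] 0.7140409
```

The tracker mis-assigns no identities here, estimates body orientation to
about 1° and position to about 0.02 mm, and the 30–60 s pooled PI of a
single 15-fly simulation scatters widely around the model's equilibrium
value (0.71): a 15-fly, 30 s window is a very small sample, and here it
lands high at 0.93. Long-run occupancy of large populations converges to
the closed form (see the tests).

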