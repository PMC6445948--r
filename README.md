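# ivmax

Maximum sliding velocity of actin filaments in the *in vitro* motility
assay (IVMA), estimated from filament tip tracking data.

In the IVMA, myosin motors fixed on a cover slip propel fluorescently
labelled actin filaments; the filament sliding velocity is the assay's
readout and reflects myosin type, ATPase rate and motor density. Filament
movement is heterogeneous — runs at full speed alternate with slow phases
and stops — so the *maximum* velocity carries information that the usual
mean velocity blurs, particularly for regulated assays. Extracting it is
hard because displacement-based velocity signals are extremely noisy:
position errors of the tracker enter each frame-to-frame speed twice.

`ivmax` implements a three-stage analysis of tracked tip positions
`(track_id, frame, x, y)`:

1. **Signal reconstruction.** A forward Kalman filter with the
   constant-velocity state `α_t = (x_t, y_t, ẋ_t, ẏ_t)`,

   ```
   α_{t+1} = T α_t + H η_t        (state transition)
   z_t     = Z α_t + G ε_t        (measurement of x, y)
   ```

   is run over the measured positions; the reconstructed speed is
   `√(ẋ_t² + ẏ_t²)`. Filtering positions (rather than the scalar speed)
   also removes the upward bias that folded noise puts on raw speeds.

2. **Phase identification.** The reconstructed speed signal is smoothed
   with a 1D Gaussian (σ = 3 intervals), split at local maxima of the
   smoothed signal and at steepest-change points, and adjacent fractions are
   merged whenever a Welch t-test finds no significant difference
   (p > 0.05). Phases shorter than 10 frames (1 s at 10 fps) are discarded.

3. **Maximum velocity.** Phase mean velocities are pooled over all tracks
   of a sequence and sorted in decreasing order; the fastest phases are
   accumulated until they reach 10% of the total sum `v_sum = Σ v_i`, and
   their unweighted mean is the maximum velocity `v_max`.

The package also contains the benchmark used to select the reconstruction
filter — seven 1D filters (moving average, Gaussian, median,
Kolmogorov–Zurbenko, Savitzky–Golay, Spencer, Kalman) compared by the
coefficient of determination

```
R² = 1 − SSE_filter / SSE_total,
SSE_total = Σ (v_i − v_i,true)²,  SSE_filter = Σ (v_i,filtered − v_i,true)²
```

on simulated tracks with known ground truth — and two synthetic-data
generators: 2D velocity tracks (constant/periodic profiles, Gaussian and
impulsive noise) and a rendered IVMA image sequence (8-bit multi-page TIFF,
700 × 700 px, 30 elliptical filaments gliding tip-first with two speed
changes each, Gaussian intensity noise).

## Worked example

Simulate an image sequence with ground truth, then run the pipeline on the
tip tracks (pixel units, frame time units):

```r
library(ivmax)

sim <- simulate_image_sequence(image_sim_config(seed = 42))
tracks <- sim$tracks[c("track_id", "frame", "x", "y")]
res <- run_pipeline(tracks, calibration(pixel_size = 1, frame_interval = 1))
res
#> <ivma_pipeline_result> 30 tracks -> 88 phases; v_max = 7.588
glance(res$result)
#> # A tibble: 1 × 5
#>   v_max v_sum fraction n_selected n_phases_total
#>   <dbl> <dbl>    <dbl>      <int>          <int>
#> 1  7.59  415.      0.1          6             88
```

The 30 filaments produced 88 velocity phases whose velocities sum to
`v_sum = 415` px/frame; the six fastest phases reach 10% of that sum, and
their mean — `v_max = 7.59` px/frame — estimates the maximum sliding
velocity (the fastest ground-truth epoch in this sequence moves at
7.96 px/frame). The phase-velocity distribution shows what was selected:

```r
head(phase_velocity_distribution(res$phases), 3)
#> # A tibble: 3 × 6  (columns abridged)
#>   track_id start_frame end_frame duration_frames mean_velocity sd_velocity
#> 1 25                42        99              57          7.96      0.0413
#> 2 19                81        99              18          7.71      0.272
#> 3 8                  0        45              45          7.63      0.247
```

With a calibrated microscope, pass
`calibration(pixel_size = <µm/px>, frame_interval = <s/frame>)` and the
same numbers come out in µm/s. Real tracking data enter through
`read_mdf()` (MTrackJ data files) or `read_tracks_csv()`. A command-line
wrapper is installed as `exec/ivmax`
(`ivmax run --input tracks.mdf --out results/`, plus `simulate-tracks`,
`simulate-images` and `benchmark` subcommands).

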