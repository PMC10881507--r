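# cagetrack

Continuous 3D tracking of multiple individually identified animals in a
home cage, from two fused sensor streams: multi-view video detections and
lidar point clouds.

## The problem

Long-term behavioral monitoring of a marmoset family — several visually
identical animals, free-moving in an 820 × 610 × 1578 mm cage — defeats
every single-sensor approach. Video tracking loses animals that move
faster than the shutter or pass behind objects; lidar tracks fast motion
well but falsely detects marmoset-sized objects (tails, feeders, balls)
and cannot tell individuals apart; and any purely positional tracker
loses identity whenever the animals huddle and disperse. cagetrack
implements the three-part answer:

1. **Video-primary 3D tracking.** Per-camera body detections are
   associated across calibrated views by triangulation residual and
   triangulated (direct linear transform) into cage-frame positions.
2. **Lidar fallback.** Point clouds are background-subtracted (voxel
   model), clustered by Euclidean cluster extraction with body-size
   gates (extent within S1 = 100 mm to S2 = 500 mm), and tracked by
   serial-ID centroid assignment. When video loses an animal, the fused
   tracker switches to the lidar centroid nearest the last known
   position, and back to video when it re-detects — every output frame
   carries its source label (`video` / `lidar` / `missing`).
3. **Identity from intermittent faces.** Face-recognition events (time,
   position, predicted individual, confidence) attach to the nearest
   anonymous tracklet and label it by confidence-weighted windowed
   majority, so identities re-establish as soon as a face is seen after
   a huddle.

On top of the identified trajectories the package computes zone
occupancy, place-preference grids, inter-individual distance fractions,
and grooming bouts (Gaussian-smoothed detector frequency: 50 s window,
5 s slide, dual-camera average, threshold), scored against observers on
30-second units.

A full scene simulator (`simulate_scene()`, `family3_scene()`) generates
ground-truth trajectories with scripted huddles, grooming bouts and
off-cage excursions, and renders all four sensor streams with realistic
failure modes — so the entire pipeline is testable end to end with no
hardware and no data downloads.

## Worked example

```r
library(cagetrack)

# simulate 2 minutes of a three-animal family scene
scene <- family3_scene(horizon = 120, seed = 1)

# run the full pipeline on its sensor streams (never the hidden truth)
res <- run_pipeline(scene)
res
#> <pipeline_result> 145 tracklets, mean 2.3 s; sources v/l/m = 0.86/0.09/0.05

# how well did identity linking do against the ground truth?
rep <- id_switch_report(res$identified, scene$truth,
                        tick_rate = scene$tick_rate)
round(rep$correct_tick_fraction, 3)
#> [1] 0.995

# where did the adult male spend his time?
res$occupancy$A
#>           zone frames percent
#> 1  lower_floor    188    40.4
#> 2    lower_bed    147    31.6
#> 3 middle_floor      2     0.4
#> 4    upper_bed      2     0.4
#> 5        other    126    27.1
```

(Numbers here come from one run of this exact code; the same seed gives
the same ones.) The anonymous tracklets are deliberately short — the
tracker breaks a trajectory whenever two animals touch, because identity
is re-established from faces afterwards — while the *identified*
per-individual trajectories are continuous: 99.5 % of the labelled ticks
carry the correct individual in this run.  The occupancy table reads like
the field's standard ethograms: the adult male stayed in the lower cage
throughout (floor, lower bed and the adjoining front area).
`res$distances` holds per-tick pair distances; `distance_fractions()`
splits them at the customary 0.5 m / 1 m proximity thresholds.

A thin CLI wraps the same functions
(`inst/cli/cagetrack.R simulate | track | evaluate`).

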