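# cellcontacts

Quantify cell-cell interactions in time-lapse microscopy of migrating
epithelial cells, with or without an applied direct-current electric field
(electrotaxis).

Given per-frame integer label masks (e.g. Cellpose segmentations, one
positive label per cell), a pixel size and frame interval, and a schedule
of when the field was on, the package measures:

- **Kinematics** — per-cell velocities (forward difference, um/h), the
  directionality **Phi = (1/n) sum_i cos(theta_i)** of the population with
  respect to the field, speed against cell shape and size, and the
  perpendicular-velocity distribution before versus after a field
  reversal.
- **Contacts** — cell-cell contacts from direct pixel adjacency, their
  interface lengths, contact events (maximal runs of contact frames) and
  durations, and clusters (connected components of the contact graph) with
  their sizes and speeds.
- **Collision responses** — for each oriented contact (focal cell i,
  neighbour cell j) at frame t:

  - contact inhibition of locomotion,
    `CIL_ij(t) = unit(v_i(t+dt) - v_i(t)) . unit(x_i(t) - x_j(t))`,
    +1 when the focal cell accelerates directly away from its neighbour;
  - velocity alignment,
    `align_ij(t) = [cos(v_i(t+dt), v_j(t+dt)) - cos(v_i(t), v_j(t))] / 2`,
    +1 for a pair going from anti-aligned to aligned across the contact.

  Each contact is localized on the focal cell surface by projecting it
  onto the fitted moment-equivalent ellipse and measuring the angle
  **phi in [0, pi]** from the cell front (the short axis signed by
  velocity; these cells move along their short axis): 0 = front,
  pi/2 = side, pi = rear. Responses are aggregated into phi-by-
  neighbour-speed maps (slow < 50, fast > 100 um/h) and classified into
  the four-way stick/repel x align/scatter taxonomy.
- **Synthetic ground truth** — an agent-based simulator of persistent
  random walkers (von Mises polarity updates, optional electrotactic
  bias, elliptical bodies, hard-core exclusion) with tunable collision
  responses, rasterized into label movies, so the whole measurement chain
  is testable without microscopy data.

Mann-Whitney U tests (exact for small untied samples) back all two-sample
comparisons; p values are pointwise and uncorrected, and the summary
report says so.

## Worked example

```r
library(cellcontacts)
library(dplyr)

fx <- make_fixture("electrotaxis_basic", seed = 1)   # synthetic 5 h movie
fx$movie
#> <labeled_movie> 60 frames of 200x200 px, 2 um/px, dt = 5 min

res <- analyze_movie(fx$movie, field_schedule())
res
#> <movie_analysis> 720 track rows, 142 oriented contacts, 6 events, 138 samples (config 34bd5338)

res$direction |> filter(!is.na(phi)) |> summarise(mean_phi = mean(phi))
#> # A tibble: 1 x 1
#>   mean_phi
#>      <dbl>
#> 1    0.854

glance(res$map)
#> # A tibble: 1 x 4
#>   n_samples n_cells_labeled mean_cil mean_alignment
#>       <int>           <int>    <dbl>          <dbl>
#> 1        24               2   0.0866          0.137
```

The directionality of 0.85 says the simulated population migrates almost
perfectly along the field while it is on (the sign follows the scheduled
direction, so it stays positive across the 3 h reversal). The response map
summary shows 24 localized pairwise interaction samples inside the 1-3 h
analysis window with near-neutral mean responses — the
`electrotaxis_basic` preset programs no collision response, so only
persistence and geometry remain. `autoplot(res$map)` draws the CIL and
alignment heatmaps; `run_pipeline()` writes the full CSV/JSON/markdown
bundle, every artifact stamped with the configuration hash.

Real data enter the same way: `read_label_movie("masks.tif", pixel_size,
dt)` for persistent-label movies, or `link_tracks()` first when labels are
per-frame. A thin command-line wrapper lives in `inst/cli/cellcontacts.R`
(`simulate` and `run` subcommands).

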