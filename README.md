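# flashlag

Bayesian delay-compensated motion tracking and simulation of the
flash-lag effect (FLE).

Neural transmission delays mean the visual system only ever sees where a
moving object *was*, roughly 100 ms ago — yet a moving dot is perceived
ahead of a perfectly aligned flash. `flashlag` implements a state-space
model of this: a particle filter over position and velocity
$z_t = (x_t, y_t, u_t, v_t)$ that assimilates *delayed* frames and
compensates the known delay $\tau$ by motion extrapolation. The filter
keeps two layers,

- **source**: $p(z_{t-\tau} \mid I_{0:t-\tau})$, the classical
  predict/update recursion on the newest available (delayed) frame pair,
- **target**: $p(z_t \mid I_{0:t-\tau}) =
  \int p(z_t \mid z_{t-\tau})\, p(z_{t-\tau} \mid I_{0:t-\tau})\,
  dz_{t-\tau}$, the delay-compensated present-time estimate,

with a motion-coherency transition prior (transport + diffusion
$D_X, D_V$ + slow-speed damping $\gamma = (1 + D_V/\sigma_p^2)^{-1}$), a
motion-energy (template matched-filter) likelihood computed from the
frames, and equivalent "push" and "pull" orderings of the recursion. The
package also provides the synthetic stimuli (moving dot + flash on a
toroidal $256 \times 256 \times 100$ movie, standard / flash-initiated /
flash-terminated / motion-reversal conditions), a position-based
prediction (PBP) ablation with no predictive use of velocity, fixed-lag
backward smoothing (postdiction read-out), an exact grid-filter oracle,
and the standard read-outs: 50-bin spatial histograms, MAP positions,
precision (1/SD), flash-precision peak timing, the FLE lag, and parameter
sweeps. Everything downstream of the filter returns tidy tibbles, with
`tidy()`/`glance()`/`autoplot()` methods.

## Worked example

```r
library(flashlag)

movie <- render_movie(stim_params(), seed = 42)   # standard FLE display
movie
#> <fle_movie> 256 x 256 x 100 (standard, seed 42)

trace <- run_dmbp(movie, model_params(), seed = 43)
measure_lag(trace, movie)
#>    lag peak_frame dot_x flash_x flash_precision
#> 1 0.24         62  0.22   -0.02              25

1000 * flash_processing_delay(trace)
#> [1] 20

glance(trace)
#>   n_frames n_particles model mode tracking delay_frames mid_tracking_error
#> 1      100        2000  dmbp push    split           10              -0.05
```

At the frame where the flash posterior is most precise (frame 62), the
dot's estimated position (0.22) leads the flash estimate (−0.02, i.e. at
its true location) by 0.24 space units in this trial — close to the full
delay compensation $2V\tau = 0.2$ for a dot at nominal speed 1 ($= 2$
space units/s) and $\tau = 100$ ms. The flash-precision peak occurs 20 ms
(2 frames) after the delayed flash arrival in this trial; across trials
the mean is about one frame. The mid-trajectory tracking error of the
target layer (−0.05, about one histogram bin) shows the present-time
estimate following the physical dot position rather than the delayed one.
Multi-trial protocols are one call:

```r
run_condition("standard", n_trials = 20, base_seed = 0)      # one row/trial
fle_sweep("speed", values = c(0.5, 1, 2), n_trials = 20)     # lag vs speed
autoplot(trace)                  # space-time histograms, source vs target
```

A thin CLI over these functions ships in `inst/scripts/flashlag`
(`flashlag run --condition standard --ntrials 20 --seed 0 --out DIR`).

The methods vignette (`vignettes/flashlag-model.Rmd`) documents the model
assumptions, the likelihood and proposal design, every tunable parameter,
and known limitations.

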