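---
title: "Methods: arena tracking and the four-state preference model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: arena tracking and the four-state preference model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flypref)
```

# Overview

`flypref` quantifies two-choice sugar preference of walking *Drosophila*
from overhead video of a 76 mm circular arena, and interprets the result
with a four-state dynamic transition model. This vignette is the package's
account of its methods: the models, the parameters that matter, the
numerical choices, and what the synthetic benchmark does and does not show
about real data.

# The four-state model

A fly in the arena is in one of four states: free to walk on the sugar side
(FS), free to walk on the water side (FW), feeding on sugar (S), feeding on
water (W). All transitions are reversible with constant rates. Free flies
cross sides at rates $k_{SW}$ (sugar to water) and $k_{WS}$ (water to
sugar); feeding flies cannot cross. Feeding starts and stops at side-specific
rates $k_{Sin}, k_{Sout}$ and $k_{Win}, k_{Wout}$. The occupancy fractions
obey the linear system

$$\frac{d\,FS}{dt} = -(k_{SW}+k_{Sin})\,FS + k_{WS}\,FW + k_{Sout}\,S$$
$$\frac{d\,FW}{dt} = k_{SW}\,FS - (k_{WS}+k_{Win})\,FW + k_{Wout}\,W$$
$$\frac{d\,S}{dt} = k_{Sin}\,FS - k_{Sout}\,S, \qquad
  \frac{d\,W}{dt} = k_{Win}\,FW - k_{Wout}\,W$$

integrated by `solve_transient()` (deSolve, `lsoda`, rtol 1e-10); mass is
conserved to better than 1e-9.

Only three dimensionless ratios govern the stationary state: the sugar
affinity $A = k_{Sin}/k_{Sout}$, the speed ratio $B = k_{SW}/k_{WS}$ and
the water affinity $D = k_{Win}/k_{Wout}$. Side-crossing rates scale with
the walking speed on the side being left (a faster fly encounters the
midline more often), so $B$ equals the ratio of linear walking velocities
on the two sides and any shared proportionality constant cancels. At
stationarity the crossing flux balances ($FS\,k_{SW} = FW\,k_{WS}$) and
each feeding state balances against its free state ($S = A\,FS$,
$W = D\,FW$), giving $FS : FW : S : W = 1 : B : A : BD$ and the closed
form

$$\mathrm{PI}_{eq} = \frac{(1+A) - B(1+D)}{(1+A) + B(1+D)}.$$

Because this form was derived here from the stationarity structure rather
than transcribed, the package treats the ODE steady state as the authority:
the test suite requires agreement to 1e-6 over 100 random rate sets before
anything else uses the closed form. Limit semantics: $A = \infty$ (feeding
exit rate zero) gives PI = 1 for any finite $B$; $B = 0$ gives PI = 1;
$A = D$ with $B = 1$ gives PI = 0 exactly — no sugar signal through either
channel. $D$ defaults to 0.001: feeding on the water side is essentially
never observed, so it is pinned at an arbitrarily low positive value rather
than fitted.

```{r ode-check}
r <- transition_rates(k_sw = 0.25, k_ws = 0.5, k_sin = 0.4, k_sout = 0.2,
                      k_win = 2e-4, k_wout = 0.2)
c(ode = tail(solve_transient(r, duration = 4000)$pi, 1),
  closed = equilibrium_pi(ratios_from_rates(r)))
```

## From measurements to ratios

**Affinity.** Tarsal proboscis-extension (PER) responses to sucrose
recapitulate the tendency to start feeding. PER fractions (0/1 scores,
triplicate presentations, `per_fraction()`) are fitted with a logistic in
$x = \log_{10}$ concentration (mM) with parameters *slope* and
*thrd_PER* (`fit_sigmoid()`). The fitted curve is then mapped onto the
affinity scale by `per_to_affinity()`:

$$A(x) = c\,\frac{p(x)}{1 - p(x)}, \qquad
  p(x) = \mathrm{logit}^{-1}\!\big(\mathrm{slope}\,(x - (\mathrm{thrd\_PER}
  + \mathrm{thrd\_shift}))\big)$$

The odds transform is the simplest map carrying $[0,1]$ onto $[0,\infty)$
with the required boundary semantics — $A = 0$ when feeding entry never
occurs and $A = \infty$ when feeding exit never occurs — and uses exactly
two correction factors for the differing conditions of the PER and arena
experiments: `thrd_shift` shifts the threshold along the concentration axis
(PER is measured on water-satiated, restrained flies at mM doses; arena
preference saturates near molar doses, and the default shift of 3.1 log10
units is of the right size for that gap) and `c` rescales the odds. Default
corrections are `c = 0.83`, `thrd_shift = 3.1`; `calibrate_affinity()`
refits both by bounded least squares against control preference data
(`optim` L-BFGS-B on `(log c, thrd_shift)`, three fixed starts to avoid
local minima — a cheap safeguard for a 2-parameter surface).

**Speed ratio.** Linear velocity is assumed sigmoidal in concentration,
anchored at the measured velocities with no sugar and with 2 M sucrose;
`speed_ratio_from_velocity()` interpolates
$B(\mathrm{conc}) = 1 + (B_{2M} - 1)\,p(\mathrm{conc})/p(2\,\mathrm{M})$
with a logistic $p$ (default slope 2 per log10 unit, threshold 100 mM).
The anchor at 2 M is exact by construction; between the anchors the shape
is an assumption, not a measurement.

**Mutant dissection.** `simulate_mutants()` silences the channels one at a
time: affinity mutant $A = D = 0.001$, suppression mutant $B = 1$, double
mutant both. Only the double mutant has PI $\equiv 0$; each single mutant
retains preference through the surviving channel.

# The tracker

Frames are grayscale, dark flies on a light arena. Per frame:

1. **Segmentation** (`binarize_and_clean()`): binarize at a user threshold
   (default 0.5 on the unit scale), subtract the binarized empty-arena
   background, then one erosion and one dilation (3×3 box, radius
   configurable; the structuring element is a package choice — radius 1
   removes single-pixel sensor noise without eroding a 6-px-wide body).
   Contacting pixels form one particle; connectivity is 8-way (diagonal
   contact merges), implemented as a union-find pass over EBImage's
   4-connected labels.
2. **Measurement** (`measure_particles()`): area, centroid, bounding-box
   diagonal, and eccentricity of the equal-second-moment ellipse.
   Particles under 3 px are sub-resolution debris and are dropped.
3. **Likelihood classification** (`score_likelihood()`): a robust Gaussian
   reference (median/MAD, SD fallback when quantized diagonals tie) over
   (bbox diagonal, eccentricity); particles whose squared robust z-scores
   exceed the chi-squared(2) quantile at 1 − 0.01 are "low" — merged blobs
   or badly thresholded flies. With under 4 particles or zero spread the
   classifier degenerates and everything is classed high, with a warning.
4. **Merged-blob resolution** (`resolve_merged()`): the fly count in a low
   particle is estimated as area / mean single-fly area (rounded, min 1);
   the particle's padded bounding box is re-binarized at thresholds stepped
   down by 1/40 of the local intensity range until the local count matches,
   with at most 40 iterations; failure excludes the particle from the frame
   (no detections). Stricter thresholds shrink blobs toward the dark body
   cores, which separate before the rims do.
5. **Ellipse fit** (`fit_ellipses()`): the equal-second-moment ellipse per
   particle; centroid in arena mm (origin at centre, y up), orientation of
   the major axis in [0, 180) — a body *axis*, not a direction, so all
   angle arithmetic is the minimal signed mod-180 difference in (−90, 90].
6. **Identity assignment** (`match_frames()`): greedy global
   closest-neighbour pairing between consecutive frames — repeatedly take
   the minimum centroid distance pair and retire both members — gated at
   7 mm displacement and 90° axis rotation; gate-violating pairs are
   rejected with both members reported unmatched. Distance ties break by
   lowest index, so tracking is deterministic. Velocities follow as
   `v = |Δx| · fps`, `w = Δθ · fps` (`compute_kinematics()`).

The pipeline deliberately maintains identity only across consecutive frame
pairs: the behavioural read-outs (linear and absolute angular velocity,
side counts) need nothing longer, and long-range track stitching across
occlusions is out of scope.

# The synthetic arena

`simulate_agents()` runs the four-state dynamics spatially: free agents are
correlated random walkers (heading diffuses by `turn_sd` degrees per step,
default 10° at 10 fps) at a side-dependent speed; feeding agents are
stationary, so side crossing is an emergent property of walking rather than
a simulated rate. State switches are sampled per step with probability
$1 - e^{-k\,\Delta t}$, exact for single transitions at these rates. The
wall reflects specularly, preserving step length. An optional
startle multiplier emulates the high-activity transient just after
introduction (default off). For a velocity-jump walker the stationary free
density on each side scales as 1/speed, so the emergent crossing-rate ratio
equals the speed ratio — which is why the agent population converges to the
same equilibrium PI as the well-mixed ODE, and the package tests exactly
that (200 agents × 10⁴ steps, agreement within 3 Monte-Carlo standard
errors computed over independent flies, since frames within a fly are
autocorrelated).

Default study conditions: 76 mm arena, 10 fps (frame rate is a free
parameter; 10 fps resolves ~0.5 mm steps at typical speeds), 15 flies,
`speed_water` 5 mm/s and `speed_sugar` 2.5 mm/s (hungry-fly walking speeds;
2 M sucrose roughly halves speed, B = 0.5), `k_sin` 0.2/s and `k_sout`
0.1/s (feeding bouts of ~10 s, A = 2), `k_win/k_wout` = 0.001 = D.

`render_frames()` draws each agent as a filled ellipse (2.2 × 0.9 mm, a
typical adult body) at 0.15 mm/px with additive Gaussian noise (SD 0.03 on
the unit intensity scale). Body intensity grades from a dark core (0.08) to
a lighter rim (0.4): real bodies absorb most strongly at the centre, and
this gradient is what makes merged blobs separable at a stricter threshold.
Flies closer than about a minor axis overlap into one connected blob by
construction — no explicit merge switch.

What the generator does *not* emulate: wing and leg morphology, shadows and
reflections, uneven illumination, climbing flies on the Fluon-coated wall,
grooming postures, and body-size variation. Tracker accuracy measured on
these synthetic frames is therefore an upper bound on real-video accuracy:
it validates the algorithmic chain (segmentation, splitting, fitting,
association) rather than robustness to photometric nuisance.

# Numerical choices and degenerate inputs

- Frames whose flies are all excluded yield an undefined PI and are dropped
  from pooling, not imputed; `pooled_pi()` errors if the 30–60 s window is
  empty.
- A centroid exactly on the side boundary counts neither side (a
  zero-measure event; avoids double counting).
- `fit_sigmoid()` refuses flat responses (slope unidentifiable) and flags a
  fitted threshold outside the data range as extrapolated.
- `equilibrium_pi()` handles $A = \infty$ and $B = 0$ as explicit limits,
  not large floats.
- PNG round trips quantize intensities to 1/255; all tolerance-bearing
  tests run on in-memory frames.

# Benchmark problem sizes

The shipped benchmark (`benchmark_tracker()`, used by
`scripts/acceptance.R`) runs two 15-fly, 5 s videos — about 1,450
consecutive-frame fly pairs and 1,500 ground-truthed detections — and the
occupancy cross-check uses 200 agents for 10⁴ steps with a 20% burn-in.
These sizes give stable estimates (identity error varies by well under
0.1 percentage points across seeds) while keeping a full run in tens of
seconds.

# Known limitations

- The likelihood reference is per-frame; a frame consisting mostly of
  merged blobs would bias the single-fly reference and the area-based count
  estimates.
- Greedy closest-neighbour matching is not globally optimal for dense,
  fast-moving scenes; at arena densities (15 flies in 45 cm², ~0.5 mm
  steps) it coincides with the optimal assignment in practice, and the test
  suite checks that agreement on small random scenes.
- The equilibrium analysis assumes a well-mixed population; spatial
  structure (wall-hugging, local crowding) enters only through the
  agent-based cross-check.
- Calibration assumes the PER sigmoid shape transfers to the arena up to a
  threshold shift and an odds rescaling; systematic shape differences
  between restrained-fly PER and free-walking feeding initiation would be
  absorbed into, and distort, the fitted corrections.
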