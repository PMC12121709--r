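---
title: "Methods: simulating and decoding 3D motion direction from fMRI responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and decoding 3D motion direction from fMRI responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereomotion)
```

## The problem

When an object moves toward or away from an observer, the two retinae receive
distinct motion signals: binocular disparity changes over time, the two eyes
see opposite horizontal motion (an interocular velocity difference), and
monocular perspective cues appear — looming size, density change, and radial
optic flow. Human fMRI work decodes the direction of such motion-in-depth
(toward vs away) from multivertex response patterns in visual cortex, and asks
whether a region's decodable signal reflects the *retinal* stimulus or the
*perceived* 3D motion. The critical manipulation is a 90° rotation of each
eye's image about fixation: it preserves monocular motion energy exactly but
turns the stereoscopic stimulus into transparent 2D motion, abolishing the
motion-in-depth percept. A region encoding retinal motion decodes the rotated
stimulus as well as the original; a region encoding the percept does not.

`stereomotion` implements this entire experiment as a tested simulation
pipeline: a binocular stimulus engine, a synthetic cortical-surface BOLD
generator with population-receptive-field (pRF) structure, the single-trial
amplitude extraction and SVM decoding procedure, coarse-scale retinotopic-bias
diagnostics, and exact nonparametric group tests. Everything is generated in
code; no scanner data are required.

## Stimulus engine

The stimulus is a field of 80 black and white dots (0.16° diameter at the
fixation plane) inside an annular aperture of inner radius 0.25° and outer
radius 8°, viewed at 880 mm. Four cue conditions carry the toward/away signal:

* **stereoscopic** — each dot's monocular images translate horizontally at
  1.2°/s in opposite directions in the two eyes, so binocular disparity
  (right-eye minus left-eye azimuth) changes at 2.4°/s. Dot size is constant.
  Toward motion drives the disparity more crossed (more negative): the
  left-eye image moves rightward, the right-eye image leftward.
* **perspectiveL / perspectiveR** — dots translate along the depth axis at
  51.83 mm/s in world units and are projected to a single eye; the other eye
  sees a blank field. Looming/receding size, density change and radial flow
  follow from the projection.
* **combined** — the same world motion projected to both eyes, yielding
  geometrically consistent perspective and stereoscopic cues.

Two printed speeds (51.83 mm/s world, 1.2°/s retinal) are not mutually
derivable from the viewing geometry, so the engine treats retinal speed as
authoritative for stereoscopic frames and world speed for perspective and
combined frames; both are carried in `motion_params()`. The interocular
distance is not part of the stereoscopic specification (it is given directly
in retinal units) and only enters the combined-condition projection; the
default is 63 mm and configurable. A dot whose cyclopean eccentricity leaves
the annulus is redrawn uniformly inside it with fresh (zero) disparity — dots
appear and disappear within the aperture, so no uniform motion enters from any
edge. The rotated control rotates both eyes' retinal coordinates 90°
counter-clockwise (the sense is configurable; only multiples of 90° are
allowed so the rotation is numerically exact and preserves per-frame monocular
speeds to the bit).

Retinal coordinates are azimuth (positive rightward) and elevation (positive
upward) in degrees; polar angle is measured counter-clockwise from the right
horizontal meridian in (−180°, 180°].

```{r disparity}
trial <- generate_trial("stereoscopic", "toward", seed = 1)
fit_disparity_rate(trial)   # -2.4 deg/s: crossed disparity growing
```

## Synthetic vertex populations and the encoding equation

`sample_vertices()` draws cortical-surface vertices for four regions of
interest — V1, MT, MST and FST — with pRF eccentricity (truncated gamma on
[0, 10°], region-specific shape), polar angle (uniform, with an optional
horizontal-meridian over-representation factor), and pRF variance explained
(beta distributed). Each vertex responds to trial $t$ with amplitude

$$A_{v,t} = \beta_0 + g_{ecc}\,(e_v - \bar e) + g_{rad}\,\mathbb{1}[HM_v] +
d_{eff}(t, v)\,\bigl(s_v + g_{int}\,(e_v - \bar e)\bigr)$$

where $e_v$ is eccentricity, $\bar e$ the population mean, $HM_v$ indicates a
pRF within ±30° of the horizontal meridian, and $s_v$ is the vertex's signed
direction sensitivity. The coefficients inject the three coarse-scale biases
under study: an eccentricity gradient ($g_{ecc}$, the "edge effect"), a
horizontal-meridian BOLD offset ($g_{rad}$, radial bias), and an
origin-of-motion interaction ($g_{int}$).

The effective direction drive $d_{eff}$ implements the central functional
contrast. For `retinal_2d` vertices it is ±1 according to the true stimulus
direction on *every* trial — coherent retinal motion distinguishes the two
labels in all conditions, including the rotated stereoscopic control (rotation
preserves retinal motion energy). For `percept_3d` vertices it follows the
observer's percept: ±1 when a motion-in-depth percept exists, 0 when it does
not. Percepts come from `perceived_direction()`: perspective and combined
trials are veridical for everyone; unrotated stereoscopic trials are veridical
for *stereo-pros* and an uninformative coin flip for *stereo-strugglers*;
rotated stereoscopic trials yield no percept for anyone. Report lapses apply
at the button-press stage only.

The ROI presets encode the qualitative pattern the simulation is designed to
reproduce, not any empirical magnitudes: V1 has a strong eccentricity
gradient and a weak radial BOLD offset; MST a positive radial BOLD offset; MT
no radial BOLD offset but a horizontal-meridian *decodability* bias (its
$s_v$ magnitudes are amplified near the HM); FST flat biases. V1, MT and MST
are `retinal_2d`; FST is `percept_3d`. Because MT's HM gain inflates its
effective signal power, FST's sensitivity SD is set higher (0.09 vs 0.05) so
that stereoscopic decoding in FST matches or exceeds MT — the sign pattern
that motivates the presets. With these defaults a 120-vertex ROI decodes at
roughly 60–90% correct over a 10-run session, leaving headroom in both
directions for sensitivity tests.

## BOLD simulation

`simulate_run()` builds each 360-volume run (TR = 1 s) as the convolution of
the trial-amplitude impulse train (40 trials, 1 s events at 9 s spacing) with
a canonical double-gamma HRF (response peak 6 s, undershoot 16 s,
peak:undershoot 6:1, unit peak — the averaging window, not the HRF, is what
the downstream analysis prescribes, so the canonical shape is a free choice),
plus:

* linear drift (0.5 peak-to-peak) and a slow sinusoid (amplitude 0.3, period
  120 s, random phase);
* six motion regressors (standardized smooth random walks) with per-vertex
  loadings (SD 0.03);
* a smooth global confound common to all vertices (loading 0.1);
* AR(1) noise (lag-1 coefficient 0.3, marginal SD 0.8).

The noise magnitudes were calibrated once so that default-SNR decoding lands
mid-range, and are not revisited. The returned nuisance channels are the six
motion regressors plus the global signal (the mean over vertices of the
simulated series).

## Single-trial extraction

`preprocess_run()` applies the pipeline in a fixed order: (1) high-pass
filtering by projection onto a discrete-cosine basis, removing all components
with period ≥ 40 s (exact DC removal, no edge ringing; a regression test pins
the stage order); (2) nuisance regression of the 6 motion channels + global
signal with an intercept; (3) peristimulus z-normalization — for each lag
*n* = 1…9 TRs after onset, the values at onset + *n* are standardized across
the run's 40 trials per vertex; (4) averaging of the 6th–9th post-onset TRs
("sixth to ninth" read 1-based and inclusive: 5–8 s post-onset, four
samples). Ten runs assemble into the 400-trial × vertex session matrix with
50 trials per direction × cue condition.

Two analysis paths share this machinery. The **decoding path** uses the full
pipeline. The **BOLD-amplitude path** (`znorm = FALSE, global = FALSE`) skips
z-normalization — which standardizes away exactly the per-vertex response
scale that the bias analyses measure — and global-signal regression, which
absorbs spatially coherent amplitude structure such as a shared eccentricity
gradient. Degenerate lag SDs (< 1e−12) yield zeros with a warning rather than
NaN.

## Decoding

`decode_direction()` uses a linear SVM (C = 1, features standardized with
training-fold statistics only; kernel and C configurable). Each of the
`n_boot` bootstrap iterations draws a balanced 10:90 test:train split (equal
toward/away counts in the test set) and records test accuracy; a matched
shuffled-label null retrains on the same split with permuted *training*
labels (test labels intact). The defaults mirror the experimental procedure
(5,000 bootstraps); tests run at 30–200 with correspondingly widened
tolerances. Perspective-cue accuracy is the element-wise average of the
left-eye and right-eye bootstrap distributions.

## Coarse-scale bias diagnostics

`filter_vertices()` keeps pRFs with eccentricity in 0.2–8° and variance
explained > 5%. `split_eccentricity()` divides them at 4° into central
[0.2°, 4°) and edge [4°, 8°] groups — a vertex at exactly 4° goes to the edge
group (the two printed intervals share the endpoint; the tie rule is
documented and configurable). `split_polar()` classes vertices within ±30° of
either horizontal meridian as HM (both meridians: the wedge is geometrically
two-sided). `bold_group_means()` and `bold_eccentricity_fit()` quantify the
BOLD-level biases; the eccentricity fit offers a mixed-effects route
(fixed eccentricity slope, by-participant random intercepts and slopes) and a
per-participant-slope fallback tested against zero — both must agree in sign
and significance on well-powered simulations, and the package's own
inferential guarantees rest on the nonparametric tests.
`equated_subroi_decoding()` equates vertex counts by subsampling the larger
group to the smaller (500 draws by default) before decoding each group, and
reports the accuracy difference in percentage points. Any group with fewer
than two usable vertices is skipped with a warning — the generic form of the
data-driven exclusion that small edge groups force in practice.

## Group statistics

`wilcoxon_signed_rank()` and `mann_whitney_u()` are implemented from first
principles with exact small-sample p-values: full enumeration of all $2^n$
sign assignments (signed-rank, n ≤ 15) or all $\binom{n+m}{n}$ group
assignments (rank-sum, n + m ≤ 12), handling ties through average ranks and
half-counted pairs; beyond the exact range a normal approximation with tie
and continuity corrections takes over. Two-sided p-values throughout; zero
differences are dropped before ranking (the standard convention — the
procedure is undefined if all differences are zero). `mixed_model_contrast()`
delegates the accuracy ~ cue × ROI contrast with a participant random
intercept to a REML fitter (lme4/lmerTest) at contract level.

## Orchestration

`experiment_config()` + `run_experiment()` reproduce the full synthetic
experiment: 10 participants (5 stereo-pros, 5 strugglers; 7 complete the
rotated-control session), 10 runs each, per-ROI decoding for main and control
sessions, BOLD bias diagnostics, observer classification, and group tests,
all derived from one master seed (`child_seed()` gives each stage its own
stream, so runs are bitwise reproducible). Observer classification is made
testable with an explicit rule: a participant whose stereoscopic-cue accuracy
exceeds the upper end of the binomial 95% interval around chance for their
trial count is a stereo-pro, otherwise a stereo-struggler; participants with
no stereoscopic responses are excluded with a log entry. Configurations
round-trip through YAML; report bundles are validated against a JSON schema
shipped with the package and stamped with a configuration hash.

## What the tests do and do not show

The test suite exercises the pipeline at reduced problem sizes chosen for
determinism and reasonable runtime: decoding calibration uses 50 no-signal
datasets at 200 bootstraps; bias recovery uses ~10⁴ amplitude samples and a
2,000-vertex gradient simulation; the rotation-dissociation check simulates 7
stereo-pro participants × 2 ROIs × 2 sessions at 120 vertices and 60
bootstraps. The dissociation cohort is all stereo-pros deliberately: the FST
rotation effect is a property of percept-tuned populations *given a percept*;
strugglers have no stereoscopic percept in either session and would dilute
the paired contrast without testing the mechanism.

The generator emulates event timing, pRF structure, hemodynamics,
autocorrelated noise, nuisance processes and observer heterogeneity. It does
not emulate spatial correlation between neighboring vertices, pRF size (only
center position), magnitude-accurate biases, scanner artifacts, eye
movements, or attention. Passing tests therefore demonstrate that the
analysis code is correct and well calibrated under the stated generative
model — not that any particular empirical effect size in real cortex is
reproduced. The group-level numbers from real participants are outside what a
simulation can or should reproduce.
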