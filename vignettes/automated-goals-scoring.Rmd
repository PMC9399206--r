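---
title: "Automated GOALS scoring from instrument motion: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated GOALS scoring from instrument motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Surgical skill in laparoscopic wet-lab training is conventionally graded by
expert raters with the Global Operative Assessment of Laparoscopic Skills
(GOALS): five items — depth perception, bimanual dexterity, efficiency,
tissue handling, autonomy — each on a 1–5 Likert scale, totalling 5–25.
Expert rating is expensive and slow. When the tips of the instruments are
tracked by a motion-capture system, their kinematics carry much of the same
information: skilled operators move faster and more dynamically, along
shorter paths, with fewer unnecessary grasp cycles. `lapgoals` implements
the full chain from raw tip trajectories to an estimated GOALS score, and a
validation protocol that quantifies how well the estimate matches the mean
of two human raters.

Two wet-lab drills are modelled: a tissue-dissection task using grasping
forceps, scissors and a clip applier (`task1`), and a parenchymal-suturing
task using right and left needle holders (`task3`). For the suturing task
the tissue-handling item is dropped (totals 4–20), since the drill is about
needle and thread control.

## Trajectory model and units

A session is a set of per-instrument, uniformly sampled time series: 3-D
tip position, attitude (roll/pitch/yaw), gripper opening angle, and an
in-view flag marking when the instrument is inserted and tracked. Internal
units are millimetres, seconds and radians everywhere; the CSV readers
convert declared header units (cm, degrees) on ingestion, so no scale
factor survives into the analysis code. The sampling rate is data carried
per session, not a constant; the synthetic generator defaults to 120 Hz,
a typical optical-capture rate.

## Smoothing and differentiation

Raw tip tracks are smoothed with a Savitzky–Golay filter, which fits a
polynomial of order $p$ in a sliding window of $w$ samples and evaluates
the fit — and its first three derivatives — at the window centre. The
defaults are $w = 21$ samples and $p = 3$: order 3 is the minimum for
which the third derivative (jerk) is defined, and 21 samples at ~100 Hz
(≈ 0.2 s) suppresses tremor-band noise while leaving purposeful motion
intact. Both are configurable in `pipeline_config()`.

Edge handling is *shrink-to-valid*: a sample is valid only when its entire
centred window lies in one contiguous in-view run. The alternative
(mirror or polynomial edge padding) fabricates data exactly where the
derivative estimates are least constrained, and jerk averages are very
sensitive to such artefacts; masking is the conservative choice. The cost
is the loss of half a window at each end of every in-view run.

## The metric catalogue

Every metric is computed per instrument from the smoothed series and named
`<prefix>-<suffix>` with prefixes G (grasper), S (scissors), C (clip
applier), R/L (needle holders); session-level metrics (Time, BD, ROB,
RPLB, ADB, ADBO) carry no prefix. In brief:

* **PL** — path length: summed Euclidean steps between adjacent valid
  samples. **V, A, J** — time-averaged norms of the 1st–3rd derivatives.
  **VR** — speed range.
* **Idle/Low/Middle/High/Very_high** — fraction of samples in speed bands
  split at 5/25/75/150 mm/s (config defaults; not prescribed by any
  published source).
* **DPL, DV** — displacement and speed projected on the instantaneous
  port-to-tip axis. The projection axis is the physical sheath axis
  imposed by the trocar, recomputed per sample, rather than a fixed
  principal axis: it is the only axis with a physical interpretation of
  "depth".
* **NOC** — complete open→close gripper cycles counted by a two-threshold
  hysteresis automaton (0.35/0.15 rad), so jitter smaller than the
  hysteresis band cannot fabricate cycles. **AGRA** — mean opening angle.
* **Roll/Pitch/Yaw** — circular means; **AL-Roll**, **AL-PitchYaw** —
  angular path lengths with shortest-arc wrapping across ±π.
* **WA** — working area, taken as the *convex-hull volume* of the valid
  tip positions. The published abbreviation ("working area") does not fix
  a definition; a volume is the natural 3-D extent measure and is
  rotation-invariant.
* **Close/Near/Far** — fraction of samples within 20 mm / 20–50 mm /
  beyond 50 mm of the target structure polyline (only when geometry is
  available; the 20 mm bound follows the "close zone < 2 cm" convention,
  the 50 mm bound is a config default).
* **AIT** — mean time from an insertion (out-of-view→in-view edge) until
  the tip first moves faster than the idle threshold. Zero insertions
  flag the metric missing rather than zero.
* **BD** — fraction of overlapping time both tips move above the idle
  threshold; **ROB/RPLB** — order-invariant min/max ratios of the two
  instruments' NOC and PL; **ADB** — mean tip-to-tip distance; **ADBO** —
  the same restricted to ±0.25 s around either instrument's gripper
  events.

Several of these operational definitions (BD, ROB, RPLB, ADBO, AIT, WA,
the band thresholds) are reconstructions from abbreviation expansions, not
published formulas; the metric manifest (`metric_manifest()`) flags each
metric accordingly, and every definition lives in one registry so a
corrected definition is a one-line change.

### Numerical note: hull volumes

No qhull binding is assumed: the hull is an incremental algorithm written
here. Smooth trajectories are adversarial for naive incremental hulls
(sliver facets accumulate until the face list explodes), so the
implementation deduplicates points and applies a deterministic joggle of
relative magnitude 1e-9 — the standard general-position defence — before
inserting points in shuffled order with unit-normal visibility tests.
Volumes are exact to ~1e-8 relative, verified in the test suite against an
independent implementation.

## Normalisation and feature selection

All metrics are normalised by the robust Z-score
$z_i = (x_i - x_m)/\mathrm{NIQR}$, where $x_m$ is the median and
$\mathrm{NIQR} = 0.7414\cdot\mathrm{IQR}$ rescales the interquartile range
to a standard-deviation equivalent under normality. Quantiles use linear
interpolation (R type 7). Metrics with zero IQR are flagged degenerate and
yield missing values rather than infinities.

For each GOALS item, metrics whose Spearman correlation with the item's
mean score strictly exceeds 0.4 in absolute value are selected. The
hypothesis-driven manual curation that a rater team would apply on top of
the automatic screen is supported as data (per-item add/remove override
files, see `read_selection_overrides()`), not as logic, so the automatic
screen stays reproducible.

Normalisation is fitted on training folds only and applied to test folds.
A `paper_faithful = TRUE` switch instead normalises once on the whole
table before splitting — the simpler protocol sometimes seen in applied
work — but the leak-free variant is the default. After normalisation,
missing feature values are imputed at the training median (z = 0).

## Regression and grid search

Four regressors estimate each target: RBF-kernel support vector
regression (SVR), SVR on principal-component scores (PCA-SVR), ridge
regression (RR, closed form with an unpenalised intercept), and partial
least squares regression (PLSR). Default grids: SVR cost
{0.1, 1, 10, 100} × ε {0.5, 0.1, 0.01} × kernel width
{0.01, 0.1, 1/p, 1}; PCA-SVR additionally components {2, 3, 5, 8}; RR
α log-spaced 1e-3…1e3; PLSR components 1–8. All grids are config
overridable. Hyperparameters are chosen by mean MAE over a plain
(unstratified) inner 10-fold CV; ties go to the simpler model — fewer
components, larger penalty, smaller cost — implemented by candidate
ordering, so the first minimum wins deterministically.

Raw predictions can leave the score scale, so they are clipped: items to
[1, 5], totals to [5, 25] (dissection) or [4, 20] (suturing).

The total score is predicted by a dedicated regressor trained on the
metrics selected against the total. Summing per-item models is a
reasonable alternative (and can be assembled from per-item results), but
a direct model is the default: it optimises the quantity actually
reported.

## Validation protocol

Accuracy is estimated by nested, repeated, stratified k-fold CV. Per
repetition: a fresh outer 10-fold partition, stratified by binning the
total score at its quartiles into 4 groups and dealing each shuffled
group round-robin across folds (with a carried-over deal position, so
fold sizes differ by at most one). Within each outer fold, normalisation
and grid search see the training part only. Clipped test predictions are
pooled over the outer folds into one MAE per repetition — pooling, rather
than averaging fold MAEs, because MAE is defined over subjects. The
default is 100 repetitions; the packaged tests and acceptance script use
10 so a full run fits comfortably on one CPU, and the repetition count is
an explicit config field.

Seeds: the master seed feeds one draw of child seeds — one per repetition
for partitioning and one per (repetition, fold, algorithm) for the inner
CV — from an indexed table created up front, so every run is exactly
reproducible and auditable from the master seed alone.

Algorithms are compared across the per-repetition MAE distributions by a
tie-corrected Kruskal–Wallis test plus all pairwise two-sided
Mann–Whitney U tests with the normal approximation (appropriate at 100 —
or 10 — repetitions; exact enumeration is available for small counts and
is used as the test oracle).

Interrater agreement between the two raters is summarised by Spearman's ρ
per item and for the total; the mean of the two raters is the regression
target throughout.

## The synthetic study generator

Because no motion recordings ship with the package, a generator produces
sessions whose construction encodes the observed direction of skill
effects: cruise speed rises with skill (25 + 45·skill mm/s), detour
waypoints, pause time, gripper cycles, tremor amplitude and
post-insertion dwell all fall with skill. Trajectories are minimum-jerk
segments between waypoints laid along a synthetic target polyline,
resampled at 120 Hz, with band-limited tremor and scripted insertion
episodes; minimum-jerk interpolation is chosen precisely so that the jerk
metric is finite and skill-sensitive. Two raters score a latent item value
1 + 4·clamp(skill + jitter) with per-rater bias (±0.25) and noise
(σ = 1.0 Likert points), rounded and clamped. With 90 sessions these
defaults put the two-rater total-score Spearman ρ in the mid-0.8s,
matching the agreement level typically reported for expert GOALS raters;
per-item agreement runs lower (≈ 0.5) because single items have only five
levels.

The generator is a test harness, not a model of surgeons. It emulates:
monotone skill→kinematics relations, rater noise and bias, insertion
episodes, task geometry. It does not emulate: instrument exchanges,
tracking dropouts mid-gesture, tissue interaction forces, learning within
a session, or raters who disagree systematically about what skill is.
Passing the end-to-end test therefore shows that the pipeline recovers a
recoverable signal under realistic noise — not that any particular
accuracy will be achieved on real recordings.

## Problem sizes and runtime choices

The shipped tests run the full pipeline on a 90-session study (mirroring
a realistic cohort) with 10 CV repetitions, and the structural protocol
checks on 90 sessions with 5 repetitions; synthetic drill durations are
roughly 10–60 s per session depending on skill. These sizes keep a
complete run on one CPU in the minutes range while leaving every
statistical property testable; all of them are configuration, not code.

## Known limitations

* Metric definitions flagged `reconstructed` in the manifest may differ
  from the original instrumentation's unpublished formulas.
* The depth axis requires a port position; sessions without one lose DPL
  and DV. Zone metrics require target geometry.
* PLSR is fitted via `mixOmics::pls`; its component cap is
  min(features, n − 2).
* The generator's rater model is symmetric-noise; real rater pairs can be
  biased in item-specific ways that stratified CV cannot detect.
* With fewer than ~40 sessions the outer quartile stratification
  degenerates gracefully (groups smaller than the fold count) but the
  MAE distributions become noisy; the protocol refuses only below
  `k_outer` sessions.
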