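---
title: "Screening for Parkinson disease from cursor tracing and keyboard tapping: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for Parkinson disease from cursor tracing and keyboard tapping: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(pdtrace)
```

## The screening problem

Parkinson disease (PD) impairs fine limb movement: rest tremor in the 4–6 Hz
band, bradykinesia, and reduced movement precision are all visible in how a
person moves a cursor and taps keys. A structured web test can capture this
with no special hardware: the participant traces three on-screen ribbons
(a straight line, a sine wave, an Archimedean spiral) with a mouse or
trackpad while the client logs the cursor every 500 ms, and then answers
three blocks of ten visual key prompts of increasing randomness (one constant
key, two alternating keys, a fresh random key per prompt) while the client
logs every press and its latency.

`pdtrace` implements the full analysis side of such a test as a reproducible
pipeline: the stimulus geometry, a validated session-log data model, a
generative simulator of PD-like and control-like sessions, a 28-feature
motor-behavior extractor, and a repeated train–test evaluation protocol with
importance-based feature selection. Because no participant-level data from
the motivating study are publicly deposited, every quantitative claim the
package makes is made on synthetic cohorts whose generative model is
described — and whose limitations are stated — below.

## Stimulus geometry

Stimuli are defined as fractions of the participant's screen, never in
absolute pixels, so the test occupies the same share of any display. For a
screen of width $W$ and height $H$ pixels (web convention: origin top-left,
$y$ grows downward):

* **Line** — horizontal segment from $(mW, bH)$ to $((1-m)W, bH)$ with
  margin $m = 0.1$ and vertical anchor $b = 0.5$.
* **Sine** — $y(x) = bH - aH \sin\!\big(2\pi p\,(x - x_0)/(x_1 - x_0)\big)$
  over the same $x$-range, amplitude $a = 0.2$, periods $p = 2$.
* **Spiral** — Archimedean $r = b_s\theta$, $\theta \in [0, 2\pi k]$ with
  $k = 3$ turns, centered on the screen; $b_s$ is chosen so the outermost
  radius plus the ribbon half-width equals $\min(W, H)(0.5 - m)$, i.e. the
  ribbon exactly respects the margin.

Each centerline is wrapped in a ribbon of half-width $0.025\,H$. The shape
proportions (amplitude, period count, turn count, ribbon width) are not
dictated by any published protocol; they were fixed once to visually match
the proportions of the motivating test's screenshots and are all
configurable through `path_spec()`.

### Deviation and membership conventions

The capture client logs only whether the cursor was inside the ribbon, plus
its coordinates; the analysis must therefore define "inside" itself. Two
conventions are implemented:

* **band** (default): for line and sine, a *vertical* band —
  `vertical_deviation()` returns $y_s - y_c(x_s)$ at the sample's horizontal
  position (clamped to the path's $x$-range, since a web test cannot prevent
  overshoot), and the sample is inside iff $|d| \le$ half-width. For the
  spiral, a *radial* band: `radial_deviation()` converts the sample to polar
  coordinates about the spiral center and takes
  $\min_k |r_s - b_s(\theta_s + 2\pi k)|$ over arm indices with angles inside
  $[0, 2\pi k_{\max}]$, with an additional guard that the sample lie within
  1.5 half-widths of the sampled centerline (this protects the spiral-center
  degeneracy, where all arm angles collapse and a radial criterion alone
  would admit points far from the drawn curve).
* **euclidean**: true Euclidean distance to the centerline polyline.

The band convention is cheap, monotone in tremor amplitude, and matches a
client that logs a vertical deviation for the line. The two conventions
coincide exactly for the horizontal line (within its $x$-range) and differ
near the ribbon boundary for curved shapes by the metric itself: a vertical
band is wider than a Euclidean band wherever the centerline is steep (the
sine's steepest slope is $2\pi a p H/(x_1-x_0) \approx 2.5$, so a vertical
half-width of 20 px corresponds to a Euclidean half-width of about 7 px
there). For this reason all oracle-equivalence checks in the test suite
compare the *euclidean* mode against an independent dense nearest-point
brute force; the band mode is checked against closed forms and against the
euclidean mode on the line, where they must agree. Which convention the
original web client used is unknowable from the outside, so the choice is a
configuration option (`metric` argument), not a hidden assumption.

Numerical choices: centerlines are sampled at 512 points by default
(≥ 256 enforced), 1024 for trace generation and 2048 for Euclidean
membership; arclength is cumulative chord length. Coordinates are
canonicalized to 2 decimal places, which bounds every geometric identity in
the tests by the rounding grid (≈ 0.01 px) plus oracle discretization.

## The session log

A session is one participant's complete record: demographics (only the
self-reported PD status is mandatory; age, gender and race may be
"unspecified", serialized as `null`), the device's screen geometry, the
three mouse trials in canonical order and the three keyboard trials in
canonical order. The JSON serialization is canonical — sorted keys, integer
timestamps, 2-decimal coordinates — so writing is a fixed point and
`read_session(write_session(s))` is the identity; a JSON-Schema document
ships in `inst/extdata/session.schema.json`.

The keyboard prompt semantics are a design decision the data format forces:
a prompt window runs from onset until the prompted key is pressed or a
5000 ms timeout elapses; every press of a different key inside the window is
a *false press*; a prompt is *resolved* (correctly pressed) if the prompted
key arrived before timeout, and its *response time* is that first correct
press's latency. This reconciles the coexistence of a false-press count with
a correct-press count below 10 in the feature set. Response-time means are
taken over resolved prompts only, with the resolved count surfaced
separately; a level with zero resolved prompts yields `NA` sentinels (with a
warning) that downstream modeling imputes by train-set medians rather than
dropping the participant.

`recompute_inside_flags()` rebuilds every membership flag from geometry,
making the pipeline robust to whether the original client judged membership
per-sample or post hoc; it is idempotent and reports how many flags changed.

## The synthetic cohort generator

The generator exists so that every downstream stage is testable without
participant data. It encodes the qualitative contrast reported for real
sessions — PD-like participants trace *faster but less precisely* and
respond *more slowly, more variably, and with more false presses* — as a
two-group parametric model:

* **Tracing.** A trial's duration is $T = s^{-1} e^{\varepsilon}$ seconds
  with speed $s$ (fraction of path length per second) and
  $\varepsilon \sim N(0, c^2)$. At each sample time $t$ (500 ms grid) the
  cursor sits at the centerline point at arclength fraction $\min(t/T, 1)$,
  displaced along the *local path normal* by
  $A \sin(2\pi f t + \varphi) + N(0, \sigma_j^2)$ with tremor amplitude $A$,
  frequency $f = 5$ Hz, uniform random phase $\varphi$ per trial, and white
  jitter $\sigma_j$. Sampling stops at the first sample reaching the path
  end. Displacement along the normal (rather than plain vertical) lets one
  model serve all three shapes; for the line it coincides with vertical
  displacement.
* **Tapping.** Prompts resolve with probability $1 - p_{\text{timeout}}$;
  resolved response times are lognormal$(\mu, \sigma)$ truncated at the
  timeout via the inverse CDF; false presses per prompt are
  Poisson($\lambda$), each with a key different from the prompted one and a
  uniform time inside the window.

A note on sampling: a 4–6 Hz tremor is far above the 1 Hz Nyquist limit of
500 ms sampling, so the oscillation is *aliased* — at the sample times it
acts as structured deviation noise, which is exactly what a real 500 ms log
of a tremulous trace contains. Modeling it as an explicit sinusoid keeps the
amplitude parameter physically interpretable while being faithful to the
capture rate.

The group defaults live in one shipped file,
`inst/extdata/default_cohort.yaml`, not in code. PD-like: $A = 12$ px,
$\sigma_j = 3$ px, $s = 0.12$/s, $c = 0.35$, median RT 700 ms with
$\sigma = 0.45$, $\lambda = 0.6$, $p_{\text{timeout}} = 0.08$. Control-like:
$A = 2$ px, $\sigma_j = 1$ px, $s = 0.08$/s, $c = 0.2$, median RT 450 ms
with $\sigma = 0.25$, $\lambda = 0.05$, $p_{\text{timeout}} = 0.01$. No
per-group deviation or timing summaries are publicly available to calibrate
against, so these values were chosen once for clear group separability at
plausible magnitudes (a 12 px tremor envelope against a 20 px ribbon
half-width; sub-second response times typical of prompted tapping) and are
deliberately *not* fitted to any reported classification accuracy.
Demographic marginals (age brackets, gender, race per group) follow the
published cohort's distribution tables but are cosmetic: they never touch
motor generation.

Determinism: the cohort seed only allocates one derived substream seed per
session, so a session's content depends on its index and the cohort seed,
never on how many sessions precede it.

**What passing tests do and do not show.** The simulator emulates
oscillatory imprecision, a speed/precision trade-off, and heavy-tailed
response behavior. It does *not* emulate device heterogeneity beyond screen
size (trackpad vs mouse dynamics, pointer acceleration, keyboard layouts),
learning or fatigue across trials, non-stationary or intention tremor,
pauses, or deliberate corrections. A protocol that separates these synthetic
groups demonstrates that the pipeline is correct and sensitive to the
encoded effects — it says nothing about real-world screening accuracy, which
only a deposited clinical cohort could establish.

## The 28 features

The extractor emits 17 baseline features in 4 categories — straight-line
stability, curved-shape stability, response speed/accuracy, false presses —
plus 11 derived transforms, 28 in total, enumerated by `feature_registry()`:

* **Line (9):** mean, absolute-maximum, net, total-absolute and
  mean-absolute signed vertical deviation; trace time; trace time divided by
  screen width; membership percentage and count.
* **Sine and spiral (4 each):** trace time, width-normalized trace time,
  membership percentage and count.
* **Keyboard (11):** per-level false-press totals and their grand total;
  per-level mean response time; correct count divided by mean response time
  in seconds for the constant and alternating levels; raw correct count for
  the random level and its per-unit-time analogue.

Three conventions are decisions, recorded in the registry documentation
because the feature names alone underdetermine them: the "maximum" deviation
is the maximum of absolute values (it dominates both tails, and only the
net/total/mean variants are listed in signed/absolute pairs); "with respect
to window width" divides by screen width in pixels; "with respect to the
average time taken" divides the resolved-prompt count by the mean response
time in seconds. Note that because the simulator's tracing speed is defined
per unit *path length*, trace time is invariant to screen rescaling and the
width-normalized time scales as $1/W$ — the normalization removes the device
dependence of the *path length in pixels*, which is its purpose on real
heterogeneous devices.

The published six-feature screening model names two aggregates that are not
single registry rows — the average false-press count over the three tapping
trials and the total constant-key response time. `final_model_features()`
materializes them as the monotone transforms `kb_false_total / 3` and
`10 * kb_rt_mean_constant` (a 10-prompt trial), which leaves every
tree-based model's behavior unchanged.

## The evaluation protocol

`screening_protocol()` chains the three modeling stages:

1. **Ranking.** An extremely randomized trees ensemble (random split
   thresholds, no bootstrap — `ranger` with `splitrule = "extratrees"`,
   `replace = FALSE`, `sample.fraction = 1`, 500 trees) is fitted on the
   full, median-imputed matrix; features are ranked by impurity importance
   normalized to sum to 1, ties broken by registry order. Ranking on the
   full data mirrors the protocol being reproduced; because it lets label
   information from future test splits into the selection step, a
   leakage-safe alternative is to rank inside each training split before
   calling `evaluate_features()` — the functions compose either way.
2. **Selection.** `select_top_k()` keeps the first $k$ ids (default 6).
3. **Evaluation.** 20 rounds; each round draws a fresh 80:20 split from a
   round-specific derived seed, imputes by *train-set* medians, fits the
   configured family, and scores the held-out set: AUC from the continuous
   scores, balanced accuracy (mean per-class recall — robust to class
   imbalance) and F1 with PD as the positive class at threshold 0.5.
   Means and SDs are reported across rounds and are recomputable from the
   per-run table (`tidy()`).

Splits are stratified by default — a deliberate deviation worth explaining:
with a 13/18 cohort of 31, an unstratified 20% test set is regularly
single-class, which makes AUC undefined and balanced accuracy degenerate.
A flag (`stratified = FALSE`) restores plain random splits; in that mode a
single-class test split records an NA AUC with a warning and a single-class
*training* split falls back to a constant classifier, never a crash.
A constant classifier's balanced accuracy is exactly 0.5 on any two-class
test set, which the suite uses as a floor check.

Four model families are supported, named for what they are: a probability
random forest (`ranger`), a regression tree on 0/1 labels whose continuous
output is thresholded at 0.5 (`rpart` — "decision tree regression" taken
literally), a support vector classifier with RBF kernel and Platt
probabilities (`e1071::svm`), and a single-hidden-layer perceptron on
standardized inputs (`nnet`, size 8, decay 0.01, logistic output).
Hyperparameters are the implementing libraries' conventional defaults,
echoed into every report and artifact so results are self-describing; no
hyperparameter search is performed. `single_feature_sweep()` runs the same
protocol once per feature and returns one row per registry feature, in
registry order.

## Reporting and the pipeline

`summarize_demographics()` rebuilds the cohort description tables: counts
and integer-rounded percentages per age bracket (40–49 … 80–90, with
out-of-range ages bucketed as "other" under a warning), gender and race,
split overall / PD / non-PD. All percentages are taken relative to the
*overall* cohort size, so the PD and non-PD shares of a row sum to the
overall share; exact fractions accompany the rounded integers.
`plot_traces()` reconstructs any session's trials — ribbon, centerline,
sampled polyline, inside/outside samples — deterministically.

`run_pipeline()` executes the whole chain under one seed and writes the
cohort, feature matrix, ranking, metrics, demographic tables, figures and a
manifest of MD5 content hashes; two runs at one seed are byte-identical,
which the test suite asserts file-by-file.

## Problem sizes

The package's own verification uses: 200-point random fields per shape for
geometry oracle equivalence (with an extra near-ribbon cloud so both
membership labels are well represented); 1000 prompts for the lognormal and
Poisson checks (3-standard-error bands); 100 trials per tremor level for the
deviation monotonicity curve; cohorts of 200 (100/100) for the
strong-effect and null protocol checks; 20 seeded repetitions for the
planted-signal ranking check; and 40-session pipelines for the end-to-end
determinism check. These sizes give the stochastic checks comfortable
margins while keeping a full run of the suite on one CPU in the order of a
minute.

## Known limitations

* The band membership convention is one of several defensible readings of
  an inside/outside log; analyses sensitive to the boundary should compare
  both conventions (the `metric` argument exists for exactly that).
* Simulator parameters are chosen for separability, not fitted to clinical
  data; synthetic performance numbers must not be read as screening
  accuracy.
* The default ranking stage sees all labels (protocol fidelity over
  leakage hygiene); use per-split ranking for honest small-sample error
  bars.
* Response-time features exclude unresolved prompts, which conditions on
  responding; cohorts with very high timeout rates will have optimistic
  response-time features and informative missingness that median imputation
  flattens.
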