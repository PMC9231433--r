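---
title: "Hands-free wheelchair interfaces: models, signals and assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hands-free wheelchair interfaces: models, signals and assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(handsfree)
```

`handsfree` models a sensing platform in which a user with severe mobility
impairment steers a power wheelchair through one of three hands-free input
channels. This vignette explains the models behind each channel, the
tunable parameters and their defaults, what the synthetic signal
generators do and do not emulate, and the numerical and design choices
made where the problem left them open.

## The head channel

### Tilt from gravity

A head-mounted 3-axis accelerometer at rest measures only gravity, so head
inclination can be recovered from the direction of the measured vector:

$$\theta_x = \arctan\frac{a_x}{\sqrt{a_y^2 + a_z^2}}, \qquad
  \theta_y = \arctan\frac{a_y}{\sqrt{a_x^2 + a_z^2}},$$

in degrees, each confined to $[-90^\circ, +90^\circ]$. Only the direction
of $(a_x,a_y,a_z)$ matters, so the estimate is invariant under positive
rescaling — sensor gain and the unit of acceleration drop out. Two
degenerate cases are handled explicitly: a zero denominator yields
$\pm 90^\circ$ by the numerator's sign (the limit of the arctangent), and
an all-zero vector raises an error rather than silently reporting a pose —
a free-falling or disconnected sensor has no defined inclination. The
degree conversion uses the exact $180/\pi$.

The static-gravity assumption is the model's main simplification: during
brisk head motion the accelerometer also measures linear acceleration,
which this estimator misattributes to tilt. The intended motions —
deliberate, held tilts — make this acceptable; gyroscope fusion is out of
scope.

### The cubic dead-zone map

Tilt sensors are sensitive, and slight involuntary head movements must not
move the chair. Each angle therefore passes through a cubic curve into the
joystick-replacement voltage:

$$v = \operatorname{clamp}\!\big(m\,(\theta - r)^3/s + v_{\mathrm{ref}}\big),$$

clamped to $[0, 5]$ V with the rest voltage $v_{\mathrm{ref}} = 2.5$ V.
The cube is flat around its centre, producing a "dead zone" at rest, and
rises steeply past a threshold, so motion starts softly. Parameters, all
user-adjustable:

| parameter | default | meaning |
|---|---|---|
| `m`, `n` | 2.5 | slope factors per axis (dimensionless) |
| `r` | 0° | centre of the quasi-linear zone |
| `s` | 27000°³ | scale; larger values flatten the curve |
| `v_ref` | 2.5 V | rest voltage |
| `dead_zone_deg` | 10° | threshold for discrete direction classification |
| `invert_x`, `invert_y` | `FALSE` | per-axis sign flip |

The defaults were chosen once so that a 30° tilt saturates the output
($2.5 \cdot (30/30)^3 + 2.5 = 5$ V), a comfortable head excursion, and so
that within $\pm 5^\circ$ of rest the output stays within 12 mV of
$v_{\mathrm{ref}}$ — effectively still. The map is applied to the
*inclination angles in degrees*; the alternative reading (applying it to
raw acceleration values) was rejected because the dead-zone description is
stated in terms of threshold head angles, and angle units make `r` and
`dead_zone_deg` directly interpretable. The per-axis inversion flags exist
because users differ in whether tilting down or up should mean forward.

Discrete classification (for logging and interface comparison) calls a
pose `neutral` when both centred angles are inside the dead zone and
otherwise lets the dominant axis decide — the larger absolute centred
angle, with an exact tie going to the x-axis so the rule is deterministic.

## The eye channel

### Conditioning

Two infrared reflectance sensors produce 0–5 V outputs sampled at 50 Hz.
Classification operates on fixed non-overlapping windows of
$\mathrm{round}(50 \times 1.5) = 75$ samples per channel. Each channel is
conditioned by two first-order IIR filters, smoothing first, baseline
removal second:

* **Exponential moving average** $y(n) = w\,x(n) + (1-w)\,y(n-1)$, default
  $w = 0.2$ — a memoryless-cheap low-pass that suppresses sensor noise.
* **DC blocker** $y(n) = x(n) - x(n-1) + \alpha\,y(n-1)$, default
  $\alpha = 0.95$ — removes the large reflectance baseline (ambient light,
  skin tone, sensor placement) that would otherwise dominate the gesture
  transient. $\alpha$ sets the corner frequency and must lie in $(0,1)$
  for stability.

Neither filter's coefficients were prescribed, so the defaults are
conventional choices: $w = 0.2$ smooths over roughly five samples (0.1 s),
and $\alpha = 0.95$ puts the high-pass corner near 0.4 Hz at 50 Hz — below
the gesture transients, above drift. Initial conditions default to
$y(-1) = 0$ and, for the DC blocker, $x(-1)$ equal to the first sample, so
a constant input is rejected exactly from the first sample with no
start-up transient.

### The classifier

Gestures {open, close, left, right} are classified by a two-layer
feed-forward network: 10 hidden neurons, 4 output neurons. Everything
beyond that topology was an open choice, resolved as the conventional
pattern-recognition recipe: the input encoding is the concatenated
filtered samples, left channel then right (150 features), standardized per
feature with training-set statistics that are stored in the model; the
hidden layer uses tanh; the output layer is a softmax, so scores are
nonnegative and sum to one; the loss is cross-entropy; the optimizer is
full-batch gradient descent with a fixed step (0.3) and a fixed epoch cap
(500). Weights initialize from seeded Gaussian draws, so a (dataset,
seed) pair reproduces the model bit for bit. Exact score ties break to the
earliest label in the fixed order (open, close, left, right). The training
set of 200 windows — 50 per gesture — mirrors the acquisition protocol the
platform uses, with a stratified 20% holdout for the reported accuracy.

A deliberately naive, loop-by-loop forward pass serves as the test oracle
for the vectorized implementation, and classification on windows the
generator labels provides the end-to-end accuracy check.

### From gestures to commands

Consecutive classified windows form ordered pairs; exactly four pairs
command motion — (left,left) → left, (right,right) → right,
(right,close) → forward, (left,close) → backward — and every other pair is
a no-op that resets the decoder, so stray classifications cannot move the
chair. Idle windows (no classification) are tolerated within a pair up to
`timeout_windows` (default 3, i.e. 4.5 s); beyond that the pending gesture
expires. The pairing, the timeout and the choice of non-overlapping rather
than sliding windows are design decisions of this package; only the
four-pair command table itself is fixed.

## The voice channel

The grammar is a small deterministic state machine over eight words.
Attention words arm a mode — `move`: timed 1 s, `go`: timed 2 s, `run`:
continuous; orientation words (`forward`, `backward`, `left`, `right`)
emit the drive command with the armed mode; `stop` clears everything and
halts. Two deliberate leniencies: an orientation word with nothing armed
is silently ignored (a spurious recognizer output must not move the
chair), and a second attention word replaces the first (the user can
correct themselves). Session playback deactivates timed commands after
their duration and lets any new command supersede the active one, which is
what "continuously until another command is received" requires. Acoustic
recognition itself is out of scope; the synthetic token stream models
recognizer failure with injectable per-token drop and confusion
probabilities.

## Synthetic signals

The generators exist so the full pipeline is testable with no hardware:

* **IMU traces**: for a scripted pose sequence, the noiseless sample is the
  unit gravity vector $(\sin\theta_x, \sin\theta_y,
  \sqrt{1-\sin^2\theta_x-\sin^2\theta_y})$, which the tilt estimator maps
  back to the scripted angles exactly; poses ramp linearly over 0.2 s and
  per-axis Gaussian noise (default $\sigma = 0.02$ g) is added. The model
  is static gravity only, consistent with the estimator's assumption — it
  does not emulate linear acceleration, vibration or gyroscope error, so
  passing round-trip tests say nothing about dynamic-motion robustness.
* **Gesture windows**: baseline 2.0 V plus a slow drift (0.001 V/sample),
  a Gaussian pulse of ±0.8 V (width 15 samples, centred at sample 37), and
  Gaussian noise ($\sigma = 0.05$ V). The classes differ by pulse signs:
  left gaze deflects the left channel up and the right down, right gaze
  the mirror image, a blink deflects both up, open eyes are baseline only.
  These template numbers are this package's invention — chosen once to
  resemble IR-oculography transients with a comfortable but not extreme
  signal-to-noise ratio (pulse ≈ 16× the noise σ) — and which sensor
  responds positively to which gaze is an arbitrary, configurable
  convention. Real recordings add ambient-light sensitivity, blink/gaze
  coupling and inter-session drift that the generator does not model, so
  the ≥95% synthetic accuracy is a property of the pipeline, not a claim
  about field performance.
* **Voice streams**: scripted tokens with independent per-token drop and
  uniform in-vocabulary confusion.

Every generator is a pure function of its inputs and a seed; one master
seed fans out to per-consumer sub-seeds through a fixed affine hash
modulo $2^{31}-1$ (`derive_subseed`), so a single integer reproduces a
whole session.

## The simulator and the safety gate

The chair is a unicycle: $\dot\theta = \omega$, $\dot x = v\cos\theta$,
$\dot y = v\sin\theta$, integrated at `dt` (default 0.1 s) with the
heading updated before the position in each step. The two voltages map
linearly and oddly about 2.5 V to $v$ and $\omega$ (defaults: 1 m/s and
1 rad/s at full scale); which channel drives which axis is a wiring
convention behind a swap flag. Unicycle rather than two-wheel-speed
kinematics suffices for skills-course geometry, since the voltages already
encode speed and turn rate; dynamics (mass, slip, ramps) are out of scope.

The anti-collision module is modelled as a forward detection cone of
half-angle 30° and range 1.2 m: if any obstacle's *boundary* (centre
distance minus radius) lies inside, positive $v$ is forced to zero while
turning and reversing stay available — the sensors face forward only, and
inhibiting only forward motion leaves the user able to escape. Full-stop
versus forward-only inhibition was an open question; forward-only was
chosen because a chair that cannot reverse away from an obstacle is
trapped by it.

## Wheelchair Skills Test scoring

The assessment encodes the 15-skill capacity sheet. Each skill scores 2
(completed safely), 1 (completed with difficulty) or 0 (failed/aborted);
total capacity is $100 \cdot \sum \text{scores} / (2 \cdot 15)$. The
displayed value *truncates* to one decimal — 26/30 prints as 86.6, not
86.7 — because that is the convention the reference totals follow
(86.66…→ 86.6, 66.66… → 66.6); the exact value is retained alongside. The
denominator generalizes to $2n$ for other sheet sizes. Four reference
sheets (two subjects × head/voice interfaces) ship as plain-text CSVs and
reproduce totals of 93.3, 63.3, 86.6 and 66.6 percent:

```{r}
vapply(example_sheets(), function(s) total_capacity(s)$display, character(1))
```

## Numerical choices, degenerate inputs, problem sizes

* Angle tolerance in tests is $10^{-9}$ degrees for algebraic identities
  and $10^{-6}$ for generator round trips; filter recursions are checked
  to $10^{-9}$ against hand-unrolled values and an independent recursive
  filter.
* Heading is normalized to $(-\pi, \pi]$ after every step.
* Empty traces pass through the filters as empty outputs (not errors);
  an all-zero acceleration vector, out-of-vocabulary words and labels,
  malformed sheets and unordered token streams raise classed errors.
* Model serialization writes doubles at maximum JSON precision, which
  round-trips to within one unit in the last place — classifications are
  unaffected.
* Test and reproduction runs use the study-scale problem sizes throughout:
  200-window datasets (50 per class), 75-sample windows, five dataset
  seeds for the accuracy summary, and closed-loop runs of 30–80 steps.

## Known limitations

The eye channel is trained and evaluated on synthetic waveforms; the head
channel ignores linear acceleration; the voice channel starts at the token
level, after acoustic recognition; the simulator is kinematic only; and
the WST module reproduces scoring arithmetic, not the clinical protocol.
These bounds mirror the platform's intended use here: a reproducible
software test bed for interface logic, not a substitute for trials with
end users.
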