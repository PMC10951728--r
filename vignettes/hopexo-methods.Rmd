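---
title: "Methods: joint-mechanics decomposition for full-leg exoskeleton hopping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint-mechanics decomposition for full-leg exoskeleton hopping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hopexo)
```

`hopexo` quantifies how a passive, full-leg, parallel-elastic exoskeleton
assists the ankle, knee and hip during stationary bilateral hopping. This
vignette is the package's own account of the models it implements, the
choices behind every tunable number, what the synthetic-data generator does
and does not emulate, and the known limitations.

## 1. Spring models

### Parametric profiles

The exoskeleton 'legs' are characterized mechanically by their secant
stiffness at a reference compression of 0.10 m (about the centre-of-mass
displacement of a contact phase at 2.4 Hz). Within that constraint the
*stiffness profile* — how tangent stiffness evolves with compression — is
free, and it is what distinguishes degressive (DG), linear (LN) and
progressive (PG) springs. The canonical family is a power law through the
origin pinned at the secant point:

$$F(d) = F_\mathrm{ref}\,\left(\frac{d}{d_\mathrm{ref}}\right)^{q},
\qquad d \ge 0,$$

with $q<1$ degressive, $q=1$ linear and $q>1$ progressive. Stored energy at
the reference compression has the closed form
$E = F_\mathrm{ref} d_\mathrm{ref}/(q+1)$, so the equal-secant energy ratio
of any profile relative to the linear one is $2/(q+1)$, inverted by
`calibrate_exponent()`. The default exponents are calibrated from the
published energy comparisons for this class of device — a DG spring storing
36% more energy than an equal-secant LN spring and 186% more than a PG
spring — giving $q_\mathrm{DG} = 0.47$ and $q_\mathrm{PG} = 3.21$:

```{r}
calibrate_exponent(1.36)        # degressive
calibrate_exponent(1.36 / 2.86)  # progressive, from the 186% excess
round(100 * (stored_energy(spring_profile("degressive", 844), 0.1) /
             stored_energy(spring_profile("linear", 844), 0.1) - 1))
```

Springs measured on a materials testing machine can be supplied as
tabulated profiles (`spring_profile_table()`, `read_spring_table()`); these
use monotone piecewise-linear interpolation and refuse to extrapolate
beyond the tabulated range, because a leaf or coil spring's behaviour
outside its measured stroke is not defined by the data.

### Hysteresis

A real spring returns less energy than it stores. The package models this
with a single parameter, `hysteresis_fraction` $h \in [0, 1)$: the
unloading branch is the loading branch scaled by $1-h$ in force. Because
the work integral is linear in force, this makes the returned energy
*exactly* $(1-h)$ times the stored energy while preserving the branch
shape — the simplest law satisfying the energy budget. (Scaling force by
$\sqrt{1-h}$, a plausible alternative, would violate that budget: energy
scales linearly, not quadratically, with a force-axis scaling.) Loss
magnitudes per spring kind were not republished with the device
description, so $h$ defaults to 0 and is configurable rather than
asserted.

### Mass prescription

Device stiffness is prescribed in proportion to body mass. The default
constant is the mean of per-participant calculated stiffness over mass in
the 14-row reference cohort (`participant_reference()`), about
0.1330 kN m⁻¹ kg⁻¹ for both springs summed; the coarser published figure
(≈ 0.132) can be supplied via `prescription_model(constant = )`. The
per-row table values derive from per-participant inputs that were not
published to full precision, so a single proportional constant reproduces
them only to within a few hundredths of a kN/m — the acceptance suite
records this exactly.

## 2. The synthetic hopper

No public motion-capture dataset accompanies this protocol, so the package
ships a generator whose outputs exercise every pipeline stage and whose
internal quantities double as ground truth.

**What it emulates.** Stationary bilateral hopping at 2.4 Hz with a 0.26 s
contact per hop, markers at 200 Hz and per-leg GRFs at 1000 Hz, 20 hops per
trial. The summed vertical GRF during contact is a pulse
$F(t) = F_\mathrm{peak}\sin^{\gamma}(\pi t/t_c)$ whose peak follows from
impulse balance (cycle-mean force equals body weight); the centre of mass
follows from twice-integrating net force on a point mass; and the planar
toe–ankle–knee–hip chain is posed every sample so the hip tracks the centre
of mass, with the required leg shortening distributed across the joints.
With the default pulse shape $\gamma = 2.7$ the peak summed vGRF is
≈ 2.34 kN and the contact-phase CoM drop ≈ 11 cm for a 66 kg hopper —
inside the envelope this protocol produces in people. $\gamma$ is
configurable and makes no claim to reproduce human pulse shapes.

Key construction choices:

- **Forefoot contact.** The toe marker is the fixed contact point and the
  centre of pressure, matching hopping on the metatarsals and the
  exoskeleton's shoe mount position.
- **Joint amplitude weights.** `joint_amplitude_weights` (default
  ankle/knee/hip = 0.4/0.4/0.2) set the share of total joint *angular
  excursion* each joint absorbs; the flexion parameter that realizes a
  given leg shortening is solved per sample (bisection to 1e-13 m).
- **Aerial extension dip.** At toe-off the chain reaches its base pose
  while still extending; the generator lets the leg extend smoothly beyond
  the base pose in the air (push-off through the toes) along a quadratic
  slope-matched to the contact-phase flexion rate at both events. Marker
  trajectories are therefore velocity-continuous across contact
  transitions, which keeps the 20 Hz zero-phase filter from ringing at
  touchdown — without it, parameter-recovery errors concentrate at the
  transitions.
- **Mirrored legs.** Bilateral symmetry: each leg carries half the summed
  pulse; left and right markers differ only by independent noise (and the
  mediolateral offset written to TRC files).
- **Exoskeleton.** Attachment markers default to the hip joint centre and
  the toe. The rest length is sized to the extended on-toes pose, so
  compression starts at the instant of ground contact; displacement is
  clamped at zero when the attachment distance exceeds the rest length
  (the plates cannot stretch the spring). Ground truth records spring
  displacement, force, line of action, per-joint moment arms and moments.
  The exoskeleton 'leg' mass defaults to 1 kg — a plausible figure for a
  fibreglass/aluminium assembly, but unvalidated.
- **Fore–aft force.** Identically zero (the resultant GRF in hopping is
  ~99% vertical); the channel exists in the data format.

**What it does not emulate** — and hence what passing tests do *not* show
about real data: soft-tissue artefact and interface energy loss,
three-dimensional and frontal-plane motion, segment-inertia-consistent
GRFs (forces derive from point-mass dynamics; the inverse-dynamics
recovery tolerance of 5% documents the gap), pulse-shape variability,
balance corrections, and above all *adaptive human behaviour* — the way
people re-coordinate joints under assistance is exactly what experiments
exist to measure, and no generator parameter stands in for it.

## 3. Pipeline numerics

- **Filtering.** Zero-phase (forward–backward) Butterworth, effective
  order 4 realized as two passes of order 2, cutoff 20 Hz for markers and
  GRFs alike, reflection padding of at least three filter lengths. Gain at
  the cutoff is 0.5 (two −3 dB passes); phase handling is the biomechanics
  norm.
- **Contact events.** Summed vGRF ≥ 20 N marks contact (`>=` on onset, `<`
  on offset, so an exact-threshold plateau starts a contact); runs shorter
  than 10 ms are debounced; partial leading/trailing cycles are dropped. A
  trial of $n$ hops beginning mid-air yields $n-1$ complete onset-to-onset
  cycles. Detected contact times are threshold-referenced: for soft pulse
  shapes (large $\gamma$) they are visibly shorter than the full-force
  contact, as with real force plates.
- **Analysis grid.** All kinetics are computed on the 200 Hz marker clock;
  the 1000 Hz forces are low-passed and decimated (integer ratio
  enforced). Time-normalized curves use 101 points (0–100%).
- **Kinematics.** Single-point joint centres at the markers; pelvis taken
  as vertical above the hip. Angles are inter-segment angles, increase =
  extension/plantarflexion, straight knee = 180°, anatomical ankle = 90°.
  Velocities and accelerations by central differences on filtered signals.
- **Inverse dynamics.** Bottom-up Newton–Euler over foot, shank, thigh
  with Winter-style anthropometrics (mass fractions 0.0145/0.0465/0.100;
  CoM fractions 0.50/0.433/0.433; radius-of-gyration fractions
  0.475/0.302/0.323), stored as a named table (`"winter"`) so the choice
  is explicit and swappable. The exoskeleton 'leg' mass is carried as a
  point mass at the foot attachment; its hip-attachment share rides on the
  waist harness, proximal to every joint analysed, and so never enters the
  recursion. In 2D, resolving moments "in the proximal segment's frame"
  reduces to the single sagittal component, reported under the
  extensor/plantarflexor-positive convention. A centre of pressure outside
  the foot warns but does not fail, since real COP estimates wander at low
  force.
- **Exoskeleton decomposition.** The spring force is axial between the
  attachments (low-friction pin joints); its moment about each joint is
  the planar cross product of the joint-to-attachment vector with the
  force, each joint treated independently. The loading/unloading branch
  switches on the sign of the displacement rate, holding the previous
  branch at zero rate. The sign convention resolves through the
  alternating rotational senses of the zig-zag chain: a line of action
  anterior to the ankle gives a plantarflexor (positive) moment, anterior
  to the knee an extensor moment, posterior to the hip a flexor (negative)
  moment. MTU series are exact residuals, so MTU + exo = overall at
  machine precision by construction.
- **Positive power.** Trapezium integration of the positive part with the
  threshold at exactly 0 W; a sign change between samples contributes its
  positive triangular sub-area via the interpolated zero crossing, which
  removes grid dependence. Per-leg integration precedes the two-leg sum;
  the analysis window defaults to the trailing 20 complete cycles.
- **Spring-power consistency check.** `exo_power_check()` compares the
  summed per-joint exoskeleton average positive power with the spring's
  delivered average positive power ($F_\mathrm{exo}$ times the rate of
  spring length change, positive part). For exact attachment geometry the
  two are identical, so the check carries a 2% relative slack for
  discretization and filtering; inflated moment arms (for example doubled)
  exceed the bound by construction. The identity also only bounds the sum
  when every joint's exoskeleton power shares the sign timing of the
  spring's — with the default hip-centre attachment the hip term vanishes
  and the bound is tight.
- **Alternative decomposition.** `analysis_config(exo_method =
  "grf_subtraction")` implements the comparison mode that subtracts the
  axial exoskeleton force from the measured GRF, re-runs inverse dynamics
  for the MTU moments directly, and reports the exoskeleton contribution
  as the residual. With the foot attachment at the centre of pressure the
  two methods agree closely; the mode exists to quantify that agreement,
  not as the default.

## 4. Statistics

`rm_anova()` implements the classical one-way within-subject
decomposition, $F = MS_\mathrm{condition} / MS_{\mathrm{condition}\times
\mathrm{participant}}$ with df $(k-1,\ (k-1)(n-1))$ — identical to the
mixed-model (participant-random-effect) ANOVA for a complete balanced
design, which the function requires explicitly (no silent imputation).
Post hoc inference is all $k(k-1)/2$ paired t-tests with the Sidak
adjustment $p_\mathrm{adj} = 1-(1-p)^m$, gated by default on a significant
main effect at $\alpha = 0.05$ (the gate can be disabled). Sphericity
corrections are not applied by default, matching standard practice when
none are reported for this design. Zero-variance paired differences are
flagged and given exact p-values (1 for identically zero differences, 0
otherwise) rather than an undefined t statistic.

`emit_cohort(outcomes_only = TRUE)` draws participant × condition outcome
tables from an additive random-effect model; under zero condition effects
this provides the null simulation for checking the ANOVA's type-I error at
scale without simulating full marker/GRF cohorts.

## 5. Problem sizes

The test and acceptance workloads use 10–20-hop trials (≈ 2000–8000
marker samples), one noiseless and one 1 mm-noise exoskeleton trial for
parameter recovery, and 400 replicates of the 14 × 4 null cohort for the
type-I-error check; the whole suite runs in well under a minute. These
sizes were chosen because every property being checked (impulse balance,
filter gains, recovery errors, rejection rates) is already stable at this
scale.

## 6. Known limitations

- The pipeline is strictly sagittal-plane; frontal-plane exoskeleton
  moments (real for laterally mounted springs) are out of scope.
- The foot is one rigid segment, which is known to overestimate ankle
  excursion and power in rigid footwear.
- The rigid-interface assumption (no soft-tissue displacement) makes
  estimated exoskeleton contributions upper bounds for real devices.
- Threshold-referenced contact times and hop heights are measurement
  conventions, not true contact boundaries; for soft force pulses the two
  differ by tens of milliseconds, and the package reports the convention a
  force plate would.
- The exoskeleton moment arms are computed per leg from that leg's own
  attachment markers; no mirroring or averaging across legs is applied.
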