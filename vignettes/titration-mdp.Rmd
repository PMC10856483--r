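---
title: "Titration as a Markov decision process: models, rules, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Titration as a Markov decision process: models, rules, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`paptitrate` models attended overnight PAP-and-oxygen titration for
obstructive sleep apnea with hypoxemia and chronic hypercapnia. This
vignette explains the models and the design decisions behind them: how a
night is discretized, how the rule-based policy encodes the protocol, what
the MDP layer computes, what the synthetic patient generator does and does
not emulate, and the numerical conventions throughout.

## The session data model

A `titration_session` holds a vitals time series at integer seconds
(airflow amplitude in [0, 1.5], SpO2 %, transcutaneous pCO2 mmHg, optional
respiratory and heart rate), a piecewise-constant device schedule over
half-open intervals `[t_start, next)`, and a respiratory-event table. One
hertz is sufficient resolution for event scoring, since a scoreable event
lasts at least 10 s; channels sampled faster in hardware are expected to be
down-averaged on export. Device settings are constrained to clinical
ranges: CPAP 4-20 cmH2O; EPAP >= 4 cmH2O with an IPAP-EPAP differential of
4-10 cmH2O (the usual bounds for bi-level titration); oxygen in integer
steps of 0-5 L/min, matching concentrator practice. Overlapping events are
merged on ingest with a warning rather than rejected, since scorer exports
commonly contain boundary overlaps.

## Event scoring

No single scoring definition is universal, so the thresholds are explicit
configuration: apnea is a >= 90% drop of airflow from baseline for
>= 10 s, hypopnea a >= 30% (but < 90%) drop for >= 10 s accompanied by a
>= 3% desaturation within 30 s of the event end. The baseline is the
median airflow over the preceding 120 s *excluding* samples already inside
a candidate event, and is frozen at run entry for the duration of a
candidate run; without the exclusion, long event clusters drag the
baseline down and truncate subsequent events. The AHI counts apneas and
hypopneas together; a flag excludes hypopneas for laboratories that score
them separately.

## State discretization

Each 300-s epoch maps to one of 18 composite states over the three
controlled conditions: apnea (any scored event overlapping the epoch),
SpO2 band, and pCO2 trend. The band boundaries mirror the protocol's
wording: "at least 89%" is satisfied at exactly 89 (closed lower bound),
and the taper trigger "exceeds 92%" requires strictly more than 92. The
pCO2 trend compares the epoch mean against a session baseline (mean of the
first 10 min) because the protocol's "5-unit increase" names no reference;
a rolling 30-min reference is available as an alternative for long drifts.
The FALLING band (2 mmHg below reference) exists for state-space symmetry
only — no protocol rule keys on it. Five-minute epochs balance reaction
time against vitals noise, and make epochs near-steady-state for the
simulator's relaxation time constants (60 s for SpO2, 300 s for pCO2).

## The rule-based policy

`decide_action()` is a deterministic cascade, highest priority first:

| Rule | Condition | Action |
|------|-----------|--------|
| R1 | pCO2 rising, O2 flowing | taper O2 |
| R2 | SpO2 > 92%, O2 flowing | taper O2 |
| R3 | apnea on CPAP below 15 cmH2O | pressure +1 |
| R4 | apnea on CPAP at >= 15 cmH2O, or with intolerance | switch to bi-level |
| R5 | apnea on bi-level | IPAP +1 (EPAP follows at max differential) |
| R6 | no apnea, SpO2 < 89%, pCO2 not rising | O2 +1 (capped) |
| R7 | CPAP intolerance without apnea | switch to bi-level (or pressure down, per config) |

CO2 safety outranks oxygenation because supplemental oxygen can depress
ventilatory drive in hypercapnic patients; airway patency outranks oxygen
because apneas corrupt both signals. Every decision carries the fired
rule's identifier and a human-readable rationale — explainability is a
design requirement, not an afterthought. Non-HOLD actions are rate-limited
to one per 300 s so each step's effect is observable before the next.
Intolerance is an input flag (simulator draw or operator annotation); no
measurable criterion for it exists, so it is not inferred from vitals. On
a switch to bi-level, EPAP starts at the apnea-elimination pressure when
known, otherwise at the current CPAP level (floored at 4 cmH2O), IPAP at
EPAP + 4, and the oxygen flow carries over unchanged — the least-surprise
choice. Where the protocol leaves the intolerance response ambiguous
(lower pressure vs switch), the default is the switch, exposed as
`policy_config(intolerance_action=)`.

## The MDP layer

Transition probabilities are estimated from observed `(state, action,
next state)` triples of treatment records — never by live exploration,
which is not an option with patients. Additive smoothing (`alpha = 1` by
default) regularizes sparse records; `alpha = 0` is an audit mode in which
never-observed (state, action) pairs stay missing and any attempt to use
one raises an error naming the pair, surfacing exactly where the record
base is too thin. Rows are row-stochastic to 1e-12 after smoothing.

The objective is the probability of reaching the target state within a
horizon, with the target forced absorbing (without absorption the reach
probability is ill-defined). Policy evaluation is the linear backward
recursion; optimization is value iteration, exact for finite horizons and
iterated to a sup-norm tolerance of 1e-10 for the infinite horizon (the
value sequence is bounded in [0, 1] and monotone, so it converges). Ties
between actions are broken by the fixed declared action order, making the
optimized policy reproducible bit-for-bit. There are no per-step rewards
or costs: the paper-thin reward structure (1 at absorption) keeps the
optimized quantity interpretable as a probability. The test suite checks
both operations against independent oracles — explicit enumeration over
all state paths, and exhaustive enumeration of all time-varying policies
on instances small enough to enumerate (up to 750 policies per instance) —
to 1e-12.

## The synthetic patient generator

No raw titration time series are published for this population, so the
package carries a generative model rich enough to exercise every other
module. It is deliberately the simplest structure that reproduces the
directional clinical findings; it is *not* a mechanistic cardiopulmonary
model (no gas-exchange ODEs, no chemoreflex loop, no sleep staging).

A phenotype is drawn per patient: hypercapnia class (normocapnic < 45,
moderate 45-55, severe > 55 mmHg, in 2:8:4 proportions), baseline SpO2
(truncated normal 79.7 +/- 7.72% on [60, 100]), baseline pCO2 (53 +/- 8
mmHg truncated to the class interval), untreated AHI (61.8 +/- 29.1
events/h on [10, 130]), an apnea threshold pressure U(8, 14) cmH2O, a
comfort pressure U(6, 12) cmH2O, and sensitivity parameters: CO2 retention
per L/min of oxygen (substantial in hypercapnic classes, near zero in
normocapnic), CO2 retention per cmH2O of fixed pressure above comfort
(about half of normocapnic/moderate patients, essentially absent in the
severe class), and CO2 clearance per cmH2O of pressure support.

The night evolves at 1-s steps. Events arrive as a Poisson process whose
intensity is the untreated rate scaled by a logistic in (threshold -
pressure); the logistic scale (0.5 cmH2O per logit) gives the sharp
clinical transition from frequent events to none within ~2 cmH2O, and the
intensity is dead-time-corrected so the realized untreated event rate
matches the nominal AHI even though arrivals pause during events. pCO2
relaxes (tau = 300 s) toward a setpoint that is linear in oxygen flow,
fixed-pressure excess over comfort (gated off under pressure support,
where active ventilation dominates), and pressure-support differential.
SpO2 relaxes (tau = 60 s) toward a setpoint with a blunted oxygen response
(1.5%/L — typical of hypoventilation-driven hypoxemia), a modest
apnea-resolution gain (1%), a graded pressure-support gain (1%/cmH2O of
differential), and an exhale-phase penalty of fixed pressure above comfort
(0.5%/cmH2O, CPAP only); events superimpose 4-8-point desaturation dips
that develop fast (tau = 15 s) and resolve at the normal time constant.
Cohorts under the protocol controller start the night on 1 L/min of
oxygen, as a long-term home-oxygen population would.

These coefficients were chosen so that the cohort-level *directional*
pattern of the reference correlation table emerges: pCO2 falls with IPAP
in most bi-level patients, strong positive SpO2-pressure correlations are
more frequent under bi-level than under CPAP, and about half of the
patients starting below 55 mmHg show positive CO2-pressure coupling under
CPAP. What passing these tests shows is that the pipeline recovers such
structure when it exists; it does not validate the generator against real
physiology, and real recordings bring artifacts (probe drops, body-position
effects, sleep-stage dependence, mask leak) the generator does not emulate.

The closed loop scores events from the simulated airflow itself (a
trailing 420-s window per epoch), so controller behavior reflects what a
scorer would see, not the generator's ground truth; the ground-truth event
log is stored separately in each session for calibration tests.

One phenotype-level predicate deserves note: "admits the oxygenation
target" (used when judging whether the controller *should* have reached
SpO2 >= 89%). The taper rules cap a patient's sustainable oxygen at the
largest flow whose steady-state CO2 load — oxygen retention plus
fixed-pressure retention at the working pressure, which the apnea ramp
settles near the threshold pressure — stays at least 1 mmHg (the CO2
process's epoch-mean fluctuation scale) below the 5-mmHg taper trigger.
A phenotype admits the target when its apnea-free steady-state SpO2 at
that flow reaches 89%. Bi-level support only improves both sides, so the
predicate is conservative.

## Cohort analysis

Pearson correlations pair epoch-mean pCO2 and SpO2 with the pressure
covariate of each modality segment (CPAP pressure, or IPAP under
bi-level). Correlation against a constant series is an error, never a
silent zero; segments with constant pressure or fewer than three epochs
are omitted with a warning. The strong/weak boundary is |r| >= 0.5 with a
closed boundary — the unique simple threshold consistent with the
reference table's published strong-correlation counts (a coefficient of
exactly 0.50 counts as strong) — and is configurable. "Initial pCO2 below
55 mmHg" is read as the union of the normocapnic and moderate strata, and
55.0 exactly falls in the upper stratum. Summary statistics use n-1
standard deviations, linear-interpolation quartiles, and a paired t test
for per-subject deltas; when only printed group summaries are available,
`t_from_summary()` computes the Welch statistic with Welch-Satterthwaite
degrees of freedom directly from means, SDs and sizes. The reference
table is transcribed verbatim, including one bi-level coefficient
(-0.44) that is weaker than the accompanying prose suggests; the
transcription is kept faithful and the affected count is simply not
asserted.

## Problem sizes and reproducibility

The packaged tests exercise: 14-patient cohorts of 10-h nights at 1 Hz
under the closed-loop controller (about a minute of compute, shared across
test files); 100 random MDP instances of up to 5 states x 3 actions x
horizon 4 for the path-enumeration oracle and 100 instances sized for
exhaustive policy enumeration; 200 trajectories x 50 epochs for
transition-estimation consistency (total-variation < 0.05 per row); and
10,000-rollout Monte-Carlo checks against exact reach probabilities. Every
stochastic step is seeded; identical seeds give bit-identical sessions,
cohorts and reports. `scripts/acceptance.R --seed N` regenerates all
headline numbers from scratch.

## Known limitations

- The 18-state space is a coarse discretization; within-epoch dynamics are
  invisible to the policy, and the published expert graph this mirrors may
  be coarser or finer.
- The policy engine is a faithful encoding of one protocol, not a learned
  controller; its thresholds are configuration, not fitted parameters.
- Transition models fitted from protocol-driven records inherit the
  protocol's action distribution: off-policy (state, action) pairs are
  poorly observed, which is exactly what the `alpha = 0` audit mode makes
  visible.
- The simulator's linear setpoints and logistic event rate are a
  calibration target for pipelines, not a physiological claim; effect
  sizes between modalities are realistic in direction, not magnitude.
- No central-vs-obstructive event discrimination, arousal scoring, sleep
  staging, or mask-leak modeling.
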