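---
title: "Closed-loop reinforcement-learning calibration of TENS sensory feedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop reinforcement-learning calibration of TENS sensory feedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tenscal)
```

## The calibration problem

Transcutaneous electrical nerve stimulation (TENS) can restore
somatosensory feedback by evoking sensations referred to the foot when a
peripheral nerve (peroneal, tibial or sural) is stimulated at the ankle.
Before such feedback is usable, every subject needs a *characterization*:
finding the pulse amplitude (PA, mA) and pulse width (PW, µs) pairs that
evoke a somatotopic, comfortable sensation at two target intensities — a
*low* level (just perceivable, about 2 on a 0–10 scale where 10 is pain)
and a *high* level (clearly strong, about 8). Frequency (50 Hz) and train
duration (2 s) stay fixed; only PA and PW are searched, over a
16 × 54 grid (1–16 mA by 1 mA, 70–600 µs by 10 µs).

The perception threshold follows the Weiss–Lapicque strength–duration
law, `I_th(PW) = rheobase * (1 + chronaxie / PW)`, and both rheobase and
chronaxie vary with fiber diameter, electrode placement, age and
pathology (polyneuropathy elevates thresholds substantially), so no fixed
parameter pair works across subjects. The package automates the search
with two Deep Q-Network (DQN) agents — one per target level — chained
into a closed loop with the subject.

## The Markov decision process

**States.** The subject's answer has three components: perceived
intensity (not perceived / low / high / too high), type (uncomfortable /
comfortable) and location (not somatotopic / somatotopic). Of the 16 raw
combinations, all not-perceived answers collapse into one state (type and
location of an unfelt sensation are meaningless), leaving 13 states.
`encode_state()` fixes a canonical id scheme (0 = not perceived, 1–12 the
perceived combinations); the *desirability* of a state is level-specific
and lives in `state_ordering()`, which ranks states by intensity first
(the target class on top, too-high always the worst perceived class),
then location, then type. Keeping the encoding level-independent and the
ranking level-specific lets both agents share one state vocabulary —
a single bijection cannot simultaneously realize two different
desirability orders.

**Actions.** Nine parameter deltas: PA −1/0/+1 mA crossed with PW
−10/0/+10 µs, clamped at the grid bounds. Mixed moves let the agent take
coarse (amplitude) or fine (width) steps in charge `Q = PA·PW`.

**Rewards.** A discrete nonlinear table per level: zero at not-perceived,
increasing positive values over the target-intensity block (+0.2 / +0.4 /
+0.6 / +1 along the ranking), increasing negative values for the
wrong-but-safe intensity (−0.1 … −0.4) and for the too-high block
(−0.6 … −1). Two numeric choices matter and are deliberate:

* *Unit scale.* With discount γ = 0.99 a reward plateau of +10 puts the
  optimal action value near 1000; at the configured learning rate (1e-4)
  the critic cannot reach that scale within a desk-scale training budget,
  and the small hold-versus-drift value gap at the target state is
  swamped. Dividing the table by ten preserves every ordering constraint
  and keeps values in a range the critic reaches quickly. The table is
  config-overridable.
* *Zero pivot.* Not-perceived is deliberately neutral: safer than any
  too-high state, less attractive than any target state.

## The simulated-subject environment

Training against humans is infeasible, so the offline environment is
data-driven: three predictors fitted on a trial dataset (one row per
delivered stimulus with the subject's answer and covariates):

1. **Intensity** — ordinary least squares on the 4-level intensity code
   with a `PA × PW` interaction plus gender, weight, nerve and neuropathy
   covariates; the continuous prediction is rounded and clamped to
   {0,…,3}. Covariates must enter because episodes simulate *different*
   subjects.
2. **Type** — a majority-vote ensemble of 30 KNN classifiers (k = 5),
   each on a random feature subspace of size ⌈√p⌉; an even split resolves
   to *comfortable* (an optimistic tie is safer for exploration than a
   punishing one).
3. **Location** — Gaussian-process regression on the 0/1 somatotopy
   label with an exponential kernel
   `k(x, x') = σ_f² exp(−‖x−x'‖/ℓ) + σ_n² δ` (σ_f = 1, ℓ = median
   pairwise distance, σ_n² = 1e-4), the posterior mean clamped to [0, 1]
   and thresholded at 0.5.

Features are z-scored with training statistics before the KNN and GP
steps. Inference is pure, so for fixed covariates the whole grid's states
are tabulated once (`env_state_table()`) and training steps are lookups.

## Agent and training loop

The critic is a fully connected 3–40–30–9 ReLU network: the three state
components scaled to [0, 1] in, one Q-value per action out. The network,
backpropagation and Adam optimizer are implemented directly on base
matrices — at ~1 700 parameters a deep-learning framework would be
overhead. Training follows the standard DQN recipe: ε-greedy behaviour
(ε from 1, multiplied by 0.995 per learning step), a 10 000-transition
circular replay buffer, one mini-batch (64) critic update per environment
step, soft target-network updates (τ = 1e-3), γ = 0.99, learning rate and
L2 penalty 1e-4. Episodes start from the smart initialization of a
randomly drawn cohort subject and end on a too-high report (failure,
terminal) or at 100 steps (truncation, non-terminal for bootstrapping).

Two training choices depart from common defaults, both forced by the
tiny recurring state space:

* **ε floor 0.1** (not 0.01). With only 13 distinct states the buffer
  otherwise fills with a single greedy action per state, the alternatives'
  value estimates go stale, and the argmax at the crucial target state
  (hold versus drift, a small true gap) becomes noise.
* **Evaluation-based checkpoint selection.** The returned critic is not
  the last iterate: continued training under function approximation
  measurably degrades an already-good policy (policy churn), and the
  ε-noisy training return is a poor selector. Every 25 episodes the
  current greedy policy is rolled out deterministically from the rule
  initialization of every cohort subject, and the snapshot with the best
  mean episode return is kept. An `avg_reward_stop` threshold on the
  training return is also available and stops training outright.

Offline testing is greedy (ε = 0): per simulated subject, episodes run
until the parameter pair is unchanged for five consecutive iterations
(convergence) or a step cap; an episode is correct when its final state
has the target intensity. The default test design runs five episodes per
subject — one from the smart initialization exactly, four from small
seeded jitters of it (±2 amplitude steps, ±5 width steps), emulating
session-to-session starting variation while staying within the
initialization regime the protocol prescribes.

## Closed-loop calibration and baselines

`run_calibration()` chains the two agents. The low phase initializes at
the minimum-charge low-labeled dataset row matching the subject's gender
and nerve (safety first); the high phase initializes from the dataset's
low-to-high pairing when the converged low pair matches a recorded one
exactly, else from the low pair itself. Every delivered train is counted.
Online termination adds two safety rules to the convergence window: abort
after 3 consecutive too-high reports, and abort when the last 8 delivered
pairs contain at most two distinct values — the state-aliased greedy
policy can enter a two-point cycle across an intensity band narrower than
its step, and more stimulation cannot break the cycle. A previous
session's result can seed re-calibration directly (day-2 rule).

Two scripted baselines mirror non-adaptive practice. The brute-force
ramp (BFA) starts at the dataset's cheapest low-eliciting charge and
sweeps PW upward at fixed PA (PA incremented, PW reset, when the array is
exhausted), accepting the first low-and-somatotopic stimulus, then
repeats from that point for the high target; it cannot decrease charge,
so a start above the target band fails by construction. The naive
protocol ramps PA at a fixed 200 µs width until a perceived somatotopic
sensation, then ramps PW for the low and high targets in turn.

## The synthetic cohort generator

Virtual subjects answer deterministically from their strength–duration
curve: drive `d = (PA − I_th(PW)) / ((pain_margin − 1)·rheobase)` maps to
a 0–10 rating (`10·d`, clamped), and rating bands give the intensity
class — below 0.5 not perceived, to 5 low, to 9 high, above 9 too high —
anchoring the level-2 and level-8 targets inside the low/high bands. Type
and location are charge bands derived from the subject's own
psychometrics at a 300 µs reference width: comfort up to near-pain charge,
somatotopy from just-above-threshold to well-past-pain charge. The
in-loco component grows with drive at a small slope. Optional Gaussian
rating jitter and label-flip noise are available (defaults off, so oracle
tests are exact; the same stimulus always gets the same answer through a
per-stimulus seed).

The default cohort reproduces the reference composition — 27 men, 22
women, trials split 552/108/228 across peroneal/tibial/sural — with
log-normal rheobase (nerve-specific means 2.0/2.8/2.4 mA, CV 0.25,
women ×0.9), log-normal chronaxie (250 µs, CV 0.3), uniform pain margin
(2.5–3.5) and per-gender weights. Neuropathic subjects carry a ×2
rheobase, targeting the roughly doubled thresholds reported for
polyneuropathy. Trial generation emulates mapping sessions: amplitude
sweeps at sampled widths from below threshold to just past pain. Each
subject stores its ground-truth pairs — the minimum-charge somatotopic
point of each target class, i.e. the just-perceivable somatotopic
sensation and the onset of the strong band — for oracle-based testing.

What the generator does *not* emulate: within-session threshold drift and
adaptation, electrode repositioning between days, non-monotone or patchy
somatotopy, inter-rater wording differences, and report noise correlated
with intensity. Tests passing on this generator therefore show the
machinery is correct and the closed loop converges under clean monotone
psychometrics; they do not certify performance on human subjects.

## Numerical choices and degenerate inputs

Charge is `PA·PW/1000` µC; the unit conversion lives in one place.
Greedy ties break to the lowest action index. Single-class classifier
targets fall back to constant predictors with a warning. Off-grid
stimuli are validation errors everywhere; action application clamps at
the grid bounds instead (the boundary absorbs the move). The GP solve
adds σ_n² to the kernel diagonal for conditioning. All randomness is
seeded and threaded explicitly: cohort sampling, trial generation,
subspace draws, network initialization, exploration and test jitters are
bit-reproducible.

## Problem sizes

The shipped analyses use desk-scale sizes chosen to keep a full
reproduction comfortable on one core: 1 200 training episodes per agent
at up to 100 steps, the 49-subject / 888-trial
default dataset, five greedy test episodes per subject, and a 15-nerve
(5 × 3) noiseless benchmark cohort for the method comparison. The
benchmark's nonparametric statistics mirror the study design: a
Kolmogorov–Smirnov normality screen (reported, never acted on), a
Friedman omnibus across methods paired by subject × nerve, pairwise
Wilcoxon signed-rank post-hocs at the Bonferroni-corrected 0.05/6 ≈
0.0083 level, and Mann–Whitney for independent healthy-versus-neuropathic
contrasts.

## Known limitations

The agents observe only the 13-state sensation code, not the current
parameters: policies cannot condition on grid position, which produces
the two-point cycles addressed by the stall rule and limits how precisely
the converged charge can sit inside wide intensity bands. Too-high states
are terminal during training, so their action values are never learned
and online visits to them rely on the safety rules. The environment's
linear intensity head cannot represent saturating psychometrics exactly
(about 60–70 % four-class agreement when fitted to a single subject's
dense noiseless trials); it is a population-level surrogate, which is all
offline training needs. Human-subject quantities — wall-clock mapping
times, expert-condition comparisons — are outside what a simulation can
reproduce; `proxy_time()` is an explicitly labeled linear proxy.
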