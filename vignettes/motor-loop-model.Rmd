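---
title: "A basal-ganglia / cerebellum motor-learning loop: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A basal-ganglia / cerebellum motor-learning loop: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`motorloop` simulates a systems-level account of motor learning in which two
learning systems divide the labour of reaching: a cortex–basal-ganglia loop
*selects* a discrete motor program ("concrete action") for a desired hand
position, and a cerebellar network *fine-tunes* that program by small graded
corrections. Both systems set the parameters of brainstem central pattern
generators (CPGs) that drive a four-degree-of-freedom arm (shoulder pitch,
yaw, roll, elbow). This vignette documents the model equations as the
package implements them, every tunable constant with its default and
provenance, the numerical choices, and what the simulated experiments can
and cannot show.

## The plant: per-joint CPGs and the arm

Each joint has an independent CPG with three layers. The rhythm-generation
layer has two Rowat–Selverston-style cells (extensor and flexor), each with
a membrane potential $V$ and a lumped slow current $q$:

$$\tau_m \dot V = -(V - A_f \tanh((\sigma_f/A_f)V) + q - i),\qquad
  \tau_s \dot q = -q + \sigma_s (V - E_s),$$

with $\tau_s = 20\,\tau_m$. The injected current drives the two cells
reciprocally ($i = +i_{inj}$ for the extensor cell, $-i_{inj}$ for the
flexor cell). This half-centre organisation is a design choice of the
package: with identical drive to both cells, both converge to the same
attractor and the time-averaged joint angle collapses to the reference
angle for every parameter set, leaving the arm without a movement
repertoire; the reciprocal drive makes $i_{inj}$ a smooth, graded
controller of the extensor–flexor balance.

The pattern-formation and motor-neuron layers are logistic readouts,

$$PF = \sigma\!\big(\alpha_0\,\alpha_{PF}\,(I_{PF} - (\theta_0+\theta_{PF}))\big),
 \qquad MN = \sigma\big(5\,(I_{MN} - 0.5)\big),$$

with normalised inputs $I_{PF} = (W_{rg}\,RG + \sum_j W_j S_j)/(n+1)$ and
$I_{MN} = (W_{pf}\,PF + \sum_k W_k S_k)/(n+1)$. The model runs open loop,
so the sensory terms $S$ are implemented but default to none. The joint
angle is $U = Amp\,(MN_E - MN_F) + U_{ref}$, bounding the excursion to
$\pm Amp$ radians.

Six parameters per joint are adapted by the upstream systems and clamped to
their admissible intervals: $\tau_m \in [5,15]$ ms,
$\sigma_f, \sigma_s \in [5,10]$, $i_{inj} \in [-4,4]$,
$\alpha_0, \theta_0 \in [0.001,2]$. The fixed constants are $A_f = 5$,
$\alpha_{PF}=1$, $\theta_{PF}=0$, $W_{rg}=W_{pf}=1$, $Amp=5$. The
slow-current reversal $E_s$ and the initial conditions have no published
value; the defaults ($E_s = 0$, $V_e(0)=0.1$, $V_f(0)=-0.1$, $q(0)=0$)
give a clean all-zero fixed point at zero drive and break the
extensor–flexor symmetry deterministically.

**Movement readout.** A movement integrates the four CPGs with explicit
Euler at $dt = 1$ ms for 200 ms and reads each joint angle as the mean of
$U$ over the final 100 ms. Two measurements drove this choice. First, the
instantaneous final-step angle of an oscillating CPG is a phase-sensitive,
effectively discontinuous function of the parameters (median displacement
0.17 workspace units for parameter perturbations of 2% of range) — no
gradient-free learner can climb such a landscape, while the time-averaged
angle is locally smooth (median 0.003 at 0.5% perturbations). Second, the
readout window covers the *ballistic* phase of the half-centre excursion,
before the slow potassium current equilibrates: this is where the
extensor–flexor asymmetry, and hence the arm's workspace, is largest. A
longer movement read in the settled phase shrinks the producible workspace
to a ~0.25-radius neighbourhood of the rest posture, which is incompatible
with the task's minimum goal distance of 0.5. Convergence of the Euler
readout is guarded by a step-halving test.

Wrist position follows from four homogeneous transforms with link offsets
0.05, 0.22 and 0.16 (dimensionless link-length units); the rest posture
(all angles zero) is at $(-0.38, 0, -0.05)$ and every reachable point has
norm at most 0.43.

## The basal ganglia: novelty-gated action selection

The motor loop is a rate model (Euler, $dt=1$ ms, $\tau = 10$ ms,
rate = positive part of the membrane potential) with one discrete channel
per concrete action through striatum D1 → SNr → thalamus → motor cortex,
plus a premotor input population of 200 cells with Gaussian spatial tuning
over the workspace. Published constants: loop weights 0.8 (striatum→SNr),
0.6 (SNr→thalamus), 1.0 (thalamus→cortex), 0.5 (cortex→striatum feedback);
baselines 0 (striatum), 1.1 (SNr), 0.9 (thalamus), 0.1 (dopamine).

At rest the SNr fires tonically at 1.1, the thalamus at
$0.9 - 0.6 \times 1.1 = 0.24$. The motor-cortex baseline is not published;
the package sets it to $-0.26$, just below the tonic thalamic drive, so
the resting cortex is silent. This is required for the published selection
rule to function at all: a goal is presented for 200 ms and if no cortical
channel exceeds 0.05 a *random* action is activated — with a zero cortex
baseline the cortex rests at 0.32 and the random-exploration branch could
never fire. The winning (or random) channel is then clamped to rate 1 for
150 ms while the parameter populations settle. Clamping is exclusive: the
other channels' rates are forced to zero, so the decoded parameters are
those of one action, not a mixture (without this the goal input keeps
competitor channels active and contaminates the readout by tens of
degrees). The selection argmax uses rates averaged over the final 50 ms of
the window rather than a single noisy step.

Each action projects with fixed random weights to 24 value-tuned
populations (21 cells per CPG parameter, preferred values tiling the clamp
interval); the parameter value is the activity-weighted mean of preferred
values. The raw Uniform(0,1) weights are sharpened (raised to the 8th
power) before row normalisation: with near-uniform weights every action
decodes to the interval midpoint and the action repertoire collapses to a
single movement.

**Plasticity.** Premotor→striatum weights follow a three-factor rule: the
positive-clipped correlation between premotor and striatal rates (relative
to population means, with a post threshold of 0.1), multiplied by the
phasic dopamine deviation through slopes $K_b$ (positive) and $K_d$
(negative), minus an activity-dependent normalisation
$\alpha_j (r_j - \bar r)^2$; weights are floored at zero. The dopamine
cell relaxes toward $P \max(0, 1 - \sum w^{DA} r) + 0.1$, where $P$ gates
learning after a movement; striatum→dopamine weights grow at rate
$3 (DA - B_{DA}) (r - \bar r)^+$. Because those inhibitory weights grow
each time an outcome is re-achieved, the phasic burst collapses with
repetition — dopamine signals the *novelty* of the achieved movement, not
reward.

Calibrated learning constants (none published): $K_b = 10$, $K_d = 5$,
$\alpha_j = 0.1$, $\tau_w = 100$ ms, $\tau_{DA} = 10$ ms, membrane noise
Uniform($\pm 0.01$). The premotor tuning uses two widths: sensed outcomes
are bound with $\sigma_g = 0.10$ workspace units, goal queries use
$\sigma_{g,sel} = 0.20$. With a single width either selection cannot
generalise to goals that fall between stored outcomes (narrow) or the
act-and-sense bindings blur together and discrimination collapses (wide);
the asymmetry — sharp writing, broad reading — resolves both.

**Act-and-sense pretraining.** Before any task, the loop explores: an
action is activated (by default at random, matching the published training
block; the goal-driven sub-threshold rule is available as an option),
executed, and the *achieved* position is then encoded in the premotor
input while the dopamine gate opens for 100 ms — binding the outcome to
the action that produced it. Training stops when a randomly chosen past
outcome re-selects its producing action three times in a row (probes start
after five trials per action). Random activation matters: with purely
goal-driven exploration, late-explored actions bind under an
already-suppressed dopamine signal and retrieval becomes unreliable.

## The cerebellum: node-perturbation reservoir

A 400-unit recurrent network, $\tau \dot x = -x + J r + B u$,
$r = \tanh x$, with goal-identity inputs $u$ (one cell per motor goal,
weights Uniform($\pm0.2$)) and initial recurrent weights N(0, 0.05). A
trial starts from activations Uniform($\pm 0.01$), presents the goal input
for 200 ms, then runs 200 ms with the input off; the output is the mean
rate of 24 designated output cells over the silent phase. Perturbation
learning: units receive additive kicks Uniform($\pm A$); a per-synapse
eligibility trace accumulates
$e_{ij} \mathrel{+}= (r_j(t-1)\,(x_i(t) - \bar x_i))^3$ (running average
$\bar x$: 5-ms EMA), and at trial end
$\Delta J = -\eta\, e\, \bar E\, (E - \bar E)$ with a per-goal error
baseline $\bar E$ (EMA with coefficient 0.2, initialised to the first
observation): perturbations whose trace coincides with a better-than-usual
aiming error are reinforced.

Two numerical decisions make this rule usable:

* **Perturbation rate.** $f = 9$ is read as a *network-wide* rate (events
  per second), i.e. each unit is kicked with probability $f\,dt/(1000 N)$
  per step — a few large single-neuron kicks per trial, classic node
  perturbation with clean per-kick credit. Read per neuron, every unit is
  kicked ~3.6 times per trial (~1400 events), the rule degenerates into
  REINFORCE over 160,000 simultaneous dimensions, and measured learning is
  flat over thousands of trials at any step size.
* **Update cap.** The cubed deviations reach $~10^7$ for $A = 20$, so a
  raw update rails every weight to its bound in one trial. Each synapse's
  per-trial change is capped at `delta_max` ($10^{-3}$); the cube then
  acts as a soft selector of perturbed synapses. Weights are additionally
  clipped to $|J| \le 1$, far above their initial scale.

In the full model the outputs are additive corrections to the selected
action's parameters, scaled per parameter by `output_gain` (0.25) times
half the clamp width. The published description scales by the half width
itself; at that gain a single perturbation event injects tens of degrees
of movement noise into every baseline, swamping the adaptation
phenomenology, so the gain is calibrated down and config-exposed. In
cerebellum-only mode outputs map affinely onto the clamp intervals; a
direct variant reads the first four outputs as joint angles with no CPGs.

## Experiments

**Goals** are sampled by executing random clamped parameter sets and
keeping hand positions at least 0.5 from the rest posture — goals are
therefore *producible by some motor program*, not merely inside the
workspace (goals drawn from random joint angles are almost never
producible, and the learning problem would have no solution). The
act-and-sense loop gives such positions their meaning.

**Reaching** cycles 2 or 8 goals; the pretrained loop supplies one cached
action per goal (the published speed-up; the full closed-loop selection is
available) and the cerebellum learns from the Euclidean goal distance.

**Visuomotor rotation.** After a baseline block on two goals, the
*displayed* endpoint is rotated 45° about the axis given by the cross
product of the two goal positions; the arm itself is never touched. The
rotation is anchored at the initial hand position, so the projected
angular error of the first perturbed movement equals the imposed rotation
plus the baseline residual (anchored at the origin, the error vertex is
off-axis and the first-trial error would deviate arbitrarily from 45°).
Three conditions follow the classic protocol: `rotation` (no information),
`rotation_plus_strategy` (two trials after onset, the motor goal is
replaced by the counter-rotated goal — a distinct goal input with its own
error baseline — and reset at the end of the perturbed phase, the rotation
disappearing ten trials later), and `strategy` (instruction without
perturbation). Cerebellar learning always uses the *aiming* error — the
displayed endpoint against the current motor goal — which is what produces
the paradoxical drift under instruction and the aftereffects; basal-ganglia
novelty learning only ever sees achieved outcomes.

Training goal pairs must pass a baseline-competence screen: the selected
action (plus the current cerebellar contribution) must aim within
`competence_deg` (12°) of the goal, and in strategy-bearing conditions the
counter-rotated targets must pass the same screen. This mirrors the human
protocol, where subjects demonstrate baseline competence before the
perturbation and the experiment presumes the re-aiming target is
reachable; without the screen, repertoire gaps (a 60-action library is
sparse) dominate the measured errors. The screening probes' selections are
reused as the cached actions so the screen and the run cannot disagree.
The acceptance protocol additionally excludes models whose pretraining
fails its convergence criterion, as failed-baseline subjects are excluded.

**Variability sweeps** rerun the rotation condition over grids of $A$ and
$f$ and summarise adaptation speed as trials until the 10-trial moving
average of the absolute angular error first halves from its
post-onset level, censored at the phase length.

## Desk scales, determinism, and what the tests show

All experiments run at desk scale: a 60-action library (30 where a
spec-scale pretraining check is replicated; the published condition is
120), 30/60/30-trial adaptation schedules instead of 100/200/90,
400–600-trial reaching runs instead of tens of thousands, and 2–5 seeds.
These sizes were chosen once so that the full suite runs on a single CPU;
thresholds are never adjusted to them, and majorities scale
proportionally with seed counts.

One global seed fans out into independent named streams (goal sampling,
action library, loop noise, reservoir), so ablating the cerebellum leaves
every other component's draws untouched — ablation comparisons share all
other randomness by construction. All compiled simulation code draws from
R's RNG.

Known limitations, found and measured during development rather than
assumed:

* The reconstructed perturbation learner, in its best calibration,
  descends at roughly $10^{-4}$ error units per trial and plateaus at a
  noise floor; the published figures imply a much faster implicit process.
  Consequently, the variability sweep's trials-to-half-error statistic is
  usually censored at desk scale, and slow-adaptation effects (drift,
  aftereffects) are a few degrees rather than tens.
* The 8-goal vs 2-goal instability contrast does not reproduce: at desk
  scale both goal counts show a modest noise-driven rebound of comparable
  size, rather than an interference-driven divergence specific to the
  larger goal set. The update cap that makes learning possible also tames
  the runaway that the contrast requires.
* An untrained reservoir's outputs are ~0.26 in magnitude, not near zero:
  the unit-spectral-radius recurrent matrix carries the input transient
  through the readout window via its slow modes.
* The synthetic goal generator emulates target positions only; it has no
  analogue of biomechanical variability, execution noise, or trial-to-trial
  kinematic structure of human reaching. Tests that pass on it show that
  the implemented mechanisms produce the claimed phenomenology under the
  model's own assumptions, not that they fit human kinematic data.
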