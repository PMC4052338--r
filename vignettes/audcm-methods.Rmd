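---
title: "Modelling place-of-articulation effects in the auditory cortex network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling place-of-articulation effects in the auditory cortex network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(audcm)
```

## What this package models

`audcm` is a simulation and analysis pipeline for a question in speech
perception: how does the place of articulation (PoA) of a stop consonant —
alveolar (/d/, /t/) versus bilabial (/b/, /p/) — modulate the interplay of
the left and right auditory cortices (AC) and the left planum temporale
(PT)? The package implements the full analysis chain for a blocked
consonant–vowel (CV) syllable listening experiment at the region-of-interest
(ROI) level:

1. **Experimental design**: five runs of 220 volumes at TR = 2 s. Each run
   holds three 20-s ON blocks for each of the four PoA × VOT cells
   (voice-onset time short/long), interleaved 1:1 with 16-s OFF blocks.
   Blocks contain ten 700-ms syllable trials with random inter-trial
   silences that make each block span exactly 20 s; one trial per block is a
   monaural target trial (10% of trials) that keeps attention engaged and is
   modelled as a nuisance.
2. **Neural model**: a deterministic bilinear dynamical system over five
   nodes (left/right medial and lateral AC, left PT),
   \[ \dot z = \Big(A + \sum_j u_j B_j\Big) z + C u, \]
   where \(A\) (Hz) is the fixed coupling, each \(B_j\) the change in
   coupling induced by modulator \(u_j\) (here the centered PoA contrast),
   and \(C\) routes the driving "phonetic input" (a boxcar over every
   non-target trial) into the four AC nodes.
3. **Observation model**: node activity convolved with a canonical
   double-gamma hemodynamic response (peak 6 s, undershoot 16 s, dispersions
   1 s, ratio 6, 32-s kernel), sampled on the volume grid. The same kernel
   drives the GLM, keeping the two analyses consistent.
4. **Inference**: MAP estimation under Gaussian priors with a Laplace
   approximation to the log model evidence ("free energy"), fixed- and
   random-effects Bayesian model selection (BMS) over a sixteen-model space,
   and Bayesian model averaging (BMA).
5. **Univariate statistics**: a parametric GLM (phonetic input plus
   PoA/VOT/interaction modulators), one-sample group contrasts, and a
   2×2×2×2 repeated-measures ANOVA (hemisphere × ROI × PoA × VOT) with
   Greenhouse–Geisser correction and Fisher LSD post hocs.

No empirical imaging data ship with the package: the `synthetic_data`
functions generate multi-subject ROI datasets from a known ground truth so
that every downstream stage can be validated by recovery.

## The connectivity rule and the model space

Each AC node connects reciprocally to its within-hemisphere neighbour
(medial ↔ lateral), to its homolog in the other hemisphere, and to the left
PT — but not to the non-homolog AC of the other hemisphere. On five nodes
this yields exactly 16 permitted directed connections:

```{r mask}
mask <- build_connectivity_mask()
sum(mask)
```

The PoA modulation space places the modulator on exactly one permitted
connection per model, giving one member per connection:

```{r space}
space <- enumerate_poa_models(mask)
length(space$members)
head(member_labels(space))
```

This "one modulated connection per model" reading is a design choice: it is
the only partition that produces exactly sixteen models from the sixteen
permitted connections. Self-connections are excluded from the count; the
sixteen are inter-regional. The exploratory VOT space is obtained by
`enumerate_poa_models(mask, modulator = "vot")`.

## Priors, parameterization, and the inverter

Free parameters are the unmasked off-diagonal entries of \(A\)
(\(\mathcal N(0, 0.25)\)), the single unmasked \(B\) entry per member model
(\(\mathcal N(0, 0.25)\)), the four input weights (\(\mathcal N(0, 1)\)),
and the self-connections, parameterized as \(-0.5\,e^{\theta}\) Hz with
\(\theta \sim \mathcal N(0, 0.0625)\) so that self-decay — and with it the
stability of the uncoupled system — is structural. These are
weakly-informative values in the style of standard dynamic-causal-modelling
priors; the analysis they support is insensitive to moderate changes.

The state equation is integrated with fixed-step 4th-order Runge–Kutta at
dt = TR/16 = 0.125 s, treating inputs as constant within a step. Because
the inputs take only a handful of distinct values, each step is an affine
map that the compiled backend caches per unique input value — algebraically
identical to stepwise RK4 but two orders of magnitude faster, which is what
makes full 16-model × 10-subject recovery studies affordable. A
step-halving test keeps the solver honest.

Inversion is damped Gauss–Newton (Levenberg) ascent on the Laplace free
energy \(F = \text{accuracy} - \text{complexity}\): accuracy is the Gaussian
log-likelihood at the posterior mode with per-node noise variances profiled
at their ML values (floored at 1e-8 to keep noiseless fixtures finite), and
complexity is the KL divergence from the Gaussian posterior to the prior.
Per-run baseline columns (intercept + indicators for runs 2..R) are
projected out of data and predictions, mirroring the GLM's treatment of the
concatenated runs. Candidate steps are screened with a one-forward-pass
approximation (curvature frozen at the expansion point, bias-corrected by
the most recent screen-versus-full mismatch); a screened candidate is then
re-evaluated exactly, and only steps that increase the exact free energy
are accepted — so the free-energy trace is non-decreasing by construction.
Optimization starts at the prior means, stops when an accepted step gains
less than 1e-4 nats or after 128 iterations, and doubles the damping on
every rejection. The inverter is deterministic.

Temporal autocorrelation is handled in the simulator but deliberately *not*
in the likelihood (independent Gaussian noise per node): a stated
simplification that biases evidences slightly but affects all sixteen
members equally.

## The synthetic ground truth

`scenario_poa_inhibition()` builds a preset whose sign pattern matches the
effect the pipeline is designed to recover: positive coupling within and
between the ACs, right-to-left flow between the lateral nodes with an
inhibited left-to-right back connection, excitatory forward connections
from all ACs to PT with inhibitory PT feedback, driving input (0.4 Hz) to
the four AC nodes, and a negative PoA modulation (default −0.4 Hz) of the
right-lateral-AC → PT connection. Magnitudes (0.2–0.4 Hz) are typical
effective-connectivity scales; they were fixed once when the preset was
written.

Per subject, free parameters are jittered with sd 0.05 Hz (resampled up to
ten times if the jittered system is unstable at the observed modulator
extremes). Noise is AR(1)-filtered Gaussian (ρ = 0.3) plus a slow cosine
drift (300-s period, amplitude equal to the noise sd) that the 256-s
high-pass filter must remove. SNR is defined on the volume grid as the sd
of the noise-free stimulus-locked signal over the noise sd; the default of
2 is a realistic ROI-level figure. What the simulator does **not** emulate:
spatial structure and ROI selection noise, physiological (cardiac or
respiratory) noise, motion, nonlinear hemodynamics, and task-level
modulation of the input beyond the single bilinear term — so passing
recovery tests demonstrates internal consistency of the pipeline, not
validity for any particular empirical dataset.

One consequence worth knowing: under this single-modulator ground truth,
inhibiting R-lateral-AC → PT during alveolar blocks *disinhibits* the AC
nodes (less PT feedback), so alveolar blocks evoke larger AC responses,
while in PT itself the lost direct drive and the extra AC input nearly
cancel. An empirical PT activation increase for alveolar syllables would
require an activation effect beyond this one connection.

## Model selection and averaging

Fixed-effects BMS sums log-evidences over subjects and applies a softmax
under a uniform model prior; random-effects BMS estimates population model
frequencies with the variational Dirichlet scheme and reports expected
frequencies and exceedance probabilities (Monte-Carlo with an internal
fixed seed, so results are reproducible). Random effects is the default
for group inference; with ten subjects it is markedly more robust here,
because single-subject evidences occasionally prefer the *reciprocal*
(PT → R-lateral-AC) connection — a known direction ambiguity of
hemodynamically observed bilinear systems — and fixed-effects sums are
dominated by such extremes. Family comparison aggregates evidence mass per
family (log-sum-exp within, softmax across) and serves the
fully-connected-versus-reduced \(A\)/\(C\) pre-analyses. BMA averages
posterior means weighted by model probability (optionally sampling from
the Gaussian posteriors); a connection absent from every member is exactly
zero.

## The univariate arm

The design matrix contains the HRF-convolved phonetic input, the three
convolved mean-centered modulators (PoA = +1 alveolar / −1 bilabial,
VOT = +1 long / −1 short, interaction = product; centering precedes
convolution), a separate target regressor, four run-baseline indicators,
and a discrete-cosine basis (constant included) spanning fluctuations
slower than 1/256 Hz. Rest is implicit baseline, so the phonetic beta is
an increase over rest. With balanced designs the ±1 coding makes the
modulators exactly orthogonal to the phonetic input at micro-time.
Condition responses are reconstructed by inverting the coding
(cell = phonetic + p·poa + v·vot + pv·inter) for the four AC nodes, and
the ANOVA works effect-by-effect from orthonormal contrast scores, which
makes the Greenhouse–Geisser epsilon exactly 1 for the all-two-level
design and equates every main-effect F with a squared paired t. Serial
correlation is ignored in the GLM (the noise is near-white after
high-pass filtering in the simulator). Fisher LSD post hocs are
uncorrected pairwise paired t tests on marginal means.

## Problem sizes used in validation

The shipped validation experiments use: parameter recovery with 10
subjects × 5 runs and the full 16-model space (the averaged estimates
correlate with the generating values); model recovery with 10 replicate
experiments of 10 subjects each at 2 runs per subject — two runs keep a
replicate affordable while leaving group BMS enough evidence; and the
ANOVA power study with 10 subjects × 2 runs × 20–25 replicates. Unit tests
run on a reduced one-run design (one block per cell, 80 volumes).

## Known limitations

* The likelihood ignores temporal autocorrelation and uses ML point
  estimates of the noise variances rather than a full hyperprior.
* The observation model is linear (canonical HRF); a balloon-model
  extension point exists in the interface (`hrf` arguments) but no
  nonlinear hemodynamics are implemented.
* Direction ambiguity between reciprocal connections limits single-subject
  model identification; group random-effects BMS mitigates but does not
  remove it.
* Voxel-level inference (cluster statistics, cytoarchitectonic masks) is
  out of scope; all spatial claims live at the ROI level, with the five
  MNI peak coordinates carried as metadata only
  (`auditory_node_coords()`).
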