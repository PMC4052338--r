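# audcm

Effective-connectivity modelling of the auditory cortex during
consonant–vowel syllable perception.

## The problem

When listeners hear stop-consonant syllables, the place of articulation
(PoA) of the consonant — alveolar (/d/, /t/) versus bilabial (/b/, /p/) —
modulates how strongly processing lateralizes to the left hemisphere, and
how the left planum temporale (PT) interacts with the left and right
auditory cortices (AC). `audcm` implements the full region-of-interest
analysis chain for a blocked CV-syllable listening experiment, for
methodologists who want to study that chain's behavior on data with known
ground truth:

* a blocked design generator (5 runs × 220 volumes at TR = 2 s; 12 ON
  blocks of 20 s per run, one per PoA × VOT cell × 3, interleaved with
  16-s OFF blocks; 10 × 700-ms trials per block, one monaural target trial
  per block);
* a five-node bilinear dynamic causal model
  `ż = (A + Σⱼ uⱼBⱼ) z + C u` over left/right medial and lateral AC and
  left PT, observed through a canonical double-gamma HRF;
* model inversion by damped Gauss–Newton ascent on the Laplace free energy
  `F = accuracy − complexity` under Gaussian priors;
* the 16-model PoA-modulation space induced by the
  neighbor + PT + homolog connectivity rule, with fixed- and
  random-effects Bayesian model selection and Bayesian model averaging;
* a synthetic multi-subject data generator (subject-jittered parameters,
  AR(1) noise, slow drift, target SNR) with known ground truth;
* the univariate arm: parametric GLM (phonetic input + PoA/VOT/interaction
  modulators, 256-s discrete-cosine high-pass), one-sample group
  contrasts, and the 2×2×2×2 repeated-measures ANOVA
  (hemisphere × ROI × PoA × VOT) with Greenhouse–Geisser correction and
  Fisher LSD post hocs.

See `vignettes/audcm-methods.Rmd` for the model, priors, and numerical
choices.

## Worked example

Simulate a small group from the preset ground truth (PoA inhibits the
right-lateral-AC → PT connection by 0.4 Hz), invert the 16-model space,
and select/average:

```r
library(audcm)

gt <- scenario_poa_inhibition(strength = 0.4, snr = 2)
ds <- generate_group(gt, n_subjects = 4, master_seed = 11, n_runs = 2)

space <- enumerate_poa_models(build_connectivity_mask())
ev <- dcm_group_evidence(ds, space)
sel <- bms(ev$log_evidence)           # random-effects by default
sel
#> <bms_result> mode rfx, winner model 15 (pP = 0.1605)
member_labels(space)[sel$winner]
#> [1] "R-lateral-AC->L-PT"
avg <- bma(ev$fits, sel)
round(avg$B$poa["L-PT", "R-lateral-AC"], 3)
#> [1] -0.06
```

The winner is the generating model (modulation of R-lateral-AC → PT): its
expected frequency (0.16) is the largest of the sixteen. The
model-averaged modulation carries the generating sign but is strongly
shrunk, because random-effects weights spread mass over the fifteen
non-modulating members whose B entry for this connection is zero — with
ten subjects and five runs the probability mass concentrates and the
estimate moves toward the generating −0.4 Hz (the packaged recovery
experiment reaches a true-versus-estimate correlation of about 0.95 over
all 41 free parameters).

The univariate arm on the same dataset:

```r
fits <- lapply(ds$subjects, function(s)
  fit_glm(s$ts, build_design_matrix(s$design)))
cells <- condition_responses_group(fits)
rm_anova(cells)[1:4, c("effect", "F", "df1", "df2", "epsilon", "p")]
#>       effect         F df1 df2 epsilon           p
#> 1 hemisphere  3.179089   1   3       1 0.172596942
#> 2        roi  1.813797   1   3       1 0.270759003
#> 3        poa 43.237898   1   3       1 0.007155609
#> 4        vot  2.336150   1   3       1 0.223865558
```

Here PoA is the dominant factor: alveolar blocks disinhibit the AC nodes
(the modulation removes excitatory drive to PT, which feeds back
inhibition), so the PoA main effect is significant even in this small
demonstration group. Every 2-level within-subject effect has
Greenhouse–Geisser epsilon exactly 1 and F equal to the squared paired t.

A full end-to-end run (simulate → GLM/ANOVA → 16 DCM fits per subject →
BMS → BMA → report bundle) is one call:

```r
res <- run_end_to_end(validate_config(list(n_subjects = 2, n_runs = 1,
                                           snr = 4, seed = 33,
                                           out_dir = "demo-out")))
```

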